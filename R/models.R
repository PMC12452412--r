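# Classifiers: quadratic-kernel SVM (SMO dual solver), narrow feedforward
# neural network (1 hidden layer, trained with SGD + momentum), and a kNN
# preset.  Labels follow the cohort convention asthma = 1 (positive class),
# healthy = 2.

#' Quadratic-kernel SVM configuration
#'
#' Kernel `K(x, z) = (1 + x.z)^2` (polynomial order 2, kernel scale 1, on
#' standardized inputs), box constraint C = 1.
#'
#' @param C box constraint (> 0)
#' @param tol SMO stopping tolerance on the KKT gap
#' @param max_iter SMO iteration cap
#' @return a `qsvm_config`
#' @export
qsvm_config <- function(C = 1, tol = 1e-3, max_iter = 100000L) {
  stopifnot(C > 0, tol > 0, is_count(max_iter))
  structure(list(type = "qsvm", C = C, order = 2L, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = c("qsvm_config", "model_config"))
}

#' Narrow neural network configuration
#'
#' One hidden layer of 10 ReLU units, softmax output, mini-batch SGD with
#' momentum 0.9, learning rate 0.01, 30 epochs, batch 128; training is
#' seed-deterministic.
#'
#' @param hidden_units hidden-layer width (10 narrow, 100 wide)
#' @param learning_rate SGD step size
#' @param max_epochs training epochs
#' @param batch_size mini-batch size
#' @param momentum momentum coefficient
#' @param seed RNG seed for init and shuffling
#' @return an `nnn_config`
#' @export
nnn_config <- function(hidden_units = 10L, learning_rate = 0.01,
                       max_epochs = 30L, batch_size = 128L, momentum = 0.9,
                       seed = 1L) {
  stopifnot(is_count(hidden_units), learning_rate > 0, is_count(max_epochs),
            is_count(batch_size), momentum >= 0, momentum < 1)
  structure(list(type = "nnn", hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = c("nnn_config", "model_config"))
}

#' k-nearest-neighbour preset configuration
#'
#' @param k neighbour count (1 = fine kNN)
#' @param metric distance metric
#' @return a `knn_config`
#' @export
knn_config <- function(k = 1L, metric = c("euclidean", "manhattan")) {
  structure(list(type = "knn", k = as.integer(k), metric = match.arg(metric)),
            class = c("knn_config", "model_config"))
}

quad_kernel <- function(A, B) (1 + A %*% t(B))^2

#' Train a quadratic-kernel SVM
#'
#' Solves the soft-margin dual by SMO with kernel `(1 + x.z)^2`.  Decision
#' values are positive for the positive class (label 1, asthma); swapping the
#' two class labels flips every decision value's sign.
#'
#' @param x numeric matrix of standardized training features
#' @param labels labels with exactly two distinct values; the smaller value
#'   is the positive class
#' @param config a [qsvm_config()]
#' @return a `qsvm_model` with support vectors, dual coefficients and bias
#' @export
train_quadratic_svm <- function(x, labels, config = qsvm_config()) {
  x <- as.matrix(x)
  classes <- sort(unique(as.vector(labels)))
  if (length(classes) != 2L) stop("training set must contain two classes")
  y <- ifelse(labels == classes[1], 1, -1)
  K <- quad_kernel(x, x)
  sol <- smo_solve(K, y, config$C, config$tol, config$max_iter)
  if (!sol$converged)
    warning("SMO did not reach tolerance within ", config$max_iter, " iterations")
  sv <- which(sol$alpha > 1e-12)
  structure(list(config = config, classes = classes,
                 sv = x[sv, , drop = FALSE],
                 coef = sol$alpha[sv] * y[sv], b = sol$b,
                 iterations = sol$iterations),
            class = "qsvm_model")
}

#' @export
predict.qsvm_model <- function(object, newdata, ...) {
  f <- as.numeric(quad_kernel(as.matrix(newdata), object$sv) %*% object$coef +
                    object$b)
  list(score = f,
       class = ifelse(f > 0, object$classes[1], object$classes[2]))
}

relu <- function(z) pmax(z, 0)

#' Train the narrow neural network
#'
#' @param x numeric matrix of standardized training features
#' @param labels labels with exactly two distinct values (smaller value =
#'   positive class)
#' @param config an [nnn_config()]
#' @return an `nnn_model` with the weight matrices
#' @export
train_narrow_nn <- function(x, labels, config = nnn_config()) {
  x <- as.matrix(x)
  classes <- sort(unique(as.vector(labels)))
  if (length(classes) != 2L) stop("training set must contain two classes")
  n <- nrow(x); d <- ncol(x); h <- config$hidden_units
  Y <- cbind(as.numeric(labels == classes[1]), as.numeric(labels == classes[2]))
  set.seed(config$seed)
  W1 <- matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h)  # He init
  b1 <- numeric(h)
  W2 <- matrix(rnorm(h * 2, sd = sqrt(2 / h)), h, 2)
  b2 <- numeric(2)
  vW1 <- W1 * 0; vb1 <- b1; vW2 <- W2 * 0; vb2 <- b2
  lr <- config$learning_rate; mom <- config$momentum
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- x[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      A <- relu(sweep(Xb %*% W1, 2, b1, "+"))
      Z <- sweep(A %*% W2, 2, b2, "+")
      Z <- Z - apply(Z, 1, max)
      P <- exp(Z) / rowSums(exp(Z))
      if (any(!is.finite(P))) stop("NaN loss at epoch ", epoch)
      G <- (P - Yb) / length(idx)             # d(cross-entropy)/dZ
      gW2 <- t(A) %*% G; gb2 <- colSums(G)
      dA <- G %*% t(W2) * (A > 0)
      gW1 <- t(Xb) %*% dA; gb1 <- colSums(dA)
      vW2 <- mom * vW2 - lr * gW2; W2 <- W2 + vW2
      vb2 <- mom * vb2 - lr * gb2; b2 <- b2 + vb2
      vW1 <- mom * vW1 - lr * gW1; W1 <- W1 + vW1
      vb1 <- mom * vb1 - lr * gb1; b1 <- b1 + vb1
    }
  }
  structure(list(config = config, classes = classes,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2),
            class = "nnn_model")
}

#' @export
predict.nnn_model <- function(object, newdata, ...) {
  A <- relu(sweep(as.matrix(newdata) %*% object$W1, 2, object$b1, "+"))
  Z <- sweep(A %*% object$W2, 2, object$b2, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z) / rowSums(exp(Z))
  list(score = P[, 1],  # probability of the positive class
       class = ifelse(P[, 1] >= 0.5, object$classes[1], object$classes[2]))
}

train_knn <- function(x, labels, config = knn_config()) {
  structure(list(config = config, x = as.matrix(x),
                 labels = as.vector(labels),
                 classes = sort(unique(as.vector(labels)))),
            class = "knn_model")
}

#' @export
predict.knn_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  tr <- object$x
  D <- if (object$config$metric == "euclidean") {
    outer(rowSums(newdata^2), rowSums(tr^2), "+") - 2 * newdata %*% t(tr)
  } else {
    apply(tr, 1, function(r) colSums(abs(t(newdata) - r)))
  }
  k <- object$config$k
  score <- apply(D, 1, function(d) {
    nb <- object$labels[order(d)[seq_len(k)]]
    mean(nb == object$classes[1])
  })
  list(score = score,
       class = ifelse(score >= 0.5, object$classes[1], object$classes[2]))
}

#' Train any configured classifier
#'
#' Dispatch helper used by the CV driver and the CLI.
#'
#' @param x standardized feature matrix
#' @param labels class labels
#' @param config a `model_config` ([qsvm_config()], [nnn_config()],
#'   [knn_config()])
#' @return fitted model object
#' @export
train_classifier <- function(x, labels, config) {
  switch(config$type,
         qsvm = train_quadratic_svm(x, labels, config),
         nnn = train_narrow_nn(x, labels, config),
         knn = train_knn(x, labels, config),
         stop("unknown model type: ", config$type))
}

#' Predict with a fitted classifier
#'
#' @param model fitted model from [train_classifier()]
#' @param x feature matrix
#' @return list with `score` (continuous, larger = more positive-class) and
#'   `class`
#' @export
predict_classifier <- function(model, x) predict(model, x)
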