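---
title: "Classifying asthma from lung sounds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying asthma from lung sounds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, the tunable parameters, the synthetic
cohort, and the numerical and design choices behind `lungsoundr`. It states
no empirical result that the test suite does not itself compute.

## The problem and the pipeline

In controlled asthma, spirometry and auscultation are frequently normal,
yet airway narrowing leaves an acoustic trace: narrowband, musical wheeze
components (roughly 100–1000 Hz) superimposed on expiratory breathing
noise. The pipeline classifies 3-second lung-sound segments as asthma
(label 1, the positive class) or healthy (label 2):

segment → 14 mean MFCCs + 1 TQWT energy summary → ReliefF top-10 →
quadratic SVM / narrow neural network → participant-level stratified
10-fold cross-validation.

With the default cohort design (120 participants × 6 sites × 15 s) this
yields 30 segments per participant, a 3600 × 15 feature matrix, and
3240/360 train/test segments per fold.

## Feature extraction

**MFCC.** Each segment is cut into non-overlapping 30 ms frames (within
the conventional 20–40 ms range for short-term spectral analysis; 100
frames per 3-s segment at 4 kHz). Per frame: Hamming window, DFT power
spectrum, M = 20 triangular Mel filters between 0 Hz and Nyquist
(area-normalized: each filter's weights sum to 1), log energies
$S_m = \log(\sum_k |X[k]|^2 H_m[k] + \varepsilon)$ with
$\varepsilon = 10^{-12}$, then the unnormalized cosine transform
$C(n) = \sum_{m=1}^{M} S_m \cos(\pi n (m - \tfrac12)/M)$ for
$n = 1..14$, and finally the per-coefficient mean over frames.

Two consequences worth noting. First, the DC term $n = 0$ is excluded:
$C(0)$ is just the sum of the log energies, i.e. overall gain, and gain is
carried by the wavelet energy feature instead; this also makes every
retained coefficient exactly invariant to waveform amplitude scaling
(a gain shifts all $S_m$ equally, and the cosine sum of a constant over
the half-integer grid vanishes — asserted in the tests). Second, the log
floor $\varepsilon$ makes digital silence well-defined: constant
$S_m = \log\varepsilon$, hence all coefficients exactly zero.

Framing is non-overlapping by default (hop = frame length), extending the
segment-level "no overlap, no windowing" convention down to frames; both
the hop and the window are configurable.

**TQWT.** The tunable Q-factor wavelet transform is realized as the
standard iterated two-channel oversampled filter bank in the frequency
domain with unitary DFTs: stage scaling factors $\beta = 2/(Q+1)$ and
$\alpha = 1 - \beta/r$, Daubechies transition function
$\theta(\omega) = \tfrac12(1+\cos\omega)\sqrt{2-\cos\omega}$, which
satisfies $\theta(\omega)^2 + \theta(\pi-\omega)^2 = 1$. The bank is
therefore a tight frame: reconstruction is exact to machine precision and
the summed sub-band energy equals the input energy (both are asserted over
a (Q, r, J) grid in the tests — the "transform-dependent energy constant"
is exactly 1 here). Defaults Q = 1, r = 3, J = 8: Q = 1 suits
transient-plus-oscillatory biomedical audio, and 8 levels span the wheeze
band at 4 kHz sampling. Sub-band lengths are anchored to the input length
(`2*round(alpha^j * n/2)`) so rounding does not accumulate; a J too deep
for the signal length errors with the feasible maximum.

The default combined feature uses the single scalar summary
$\log(E_{total} + \varepsilon)$; mode `"full"` exposes the complete
per-band descriptor set — energy, mean, population variance,
energy-normalized Shannon entropy ($p_j(n) = s_j(n)^2/E_j$, so $p$ is a
probability vector for any sign pattern; entropy of an all-zero band is
defined as 0), peak amplitude, and the center-frequency bookkeeping
formula $f_j = f_{low} + (f_{high}-f_{low})/2^j$. That formula is kept
verbatim for feature parity with its source even though it differs from
the transform's analytic band centers; `tqwt_band_edges()` exposes the
true supports for diagnostics.

One property of the oversampled construction deserves emphasis: for any
redundancy $r \ge 2$, $(1-\beta) < \alpha^2$, so no band except the first
has a unit-gain ("flat") region in its overall response. A pure tone
therefore generically splits its energy between two adjacent overlapping
bands; only in band 1's flat region does a single band capture essentially
all of it. The tone-localization tests reflect this.

## Feature selection

ReliefF with every sample as an anchor (m = n), k = 10 nearest hits and
misses per anchor, Manhattan distance on range-normalized features,
index-order tie-breaking (determinism). Weights lie in [−1, 1]; a feature
constant across samples scores exactly 0. The published design states
k = 10 once; it is read as both the neighbor count and the selection size,
kept as two independent knobs here. Inside cross-validation, both the
standardizer (z-scores) and the ReliefF ranking are refitted on the
training rows of each fold — whether the original analysis selected inside
or outside CV is not stated, and the leakage-free variant is the
defensible default. The top-k sweep (`topk_accuracy_sweep()`) and
permutation importance (`permutation_importance()`) reproduce the standard
diagnostics for the choice of k.

## Classifiers

**Quadratic SVM.** Kernel $K(x,z) = (1 + x \cdot z)^2$ on standardized
inputs (polynomial order 2, kernel scale 1, box constraint C = 1). The
soft-margin dual is solved by SMO with second-order (maximal-gain) working
-set selection; stopping tolerance $10^{-3}$ on the KKT gap, iteration cap
100 000. On inseparable data (e.g. the label-permuted null) the cap can be
reached before the gap closes; the incumbent solution is returned with a
warning — the decision boundary at that point is stable to far better than
the chance-level accuracies being measured there. The tests verify the
solver against an independent `quadprog` dual solution on small toys where
the kernel matrix is positive definite (unique dual), to $10^{-6}$ on
decision values, and via the classic XOR separability check.

**Narrow neural network.** One hidden layer of 10 ReLU units, softmax
output, cross-entropy loss, mini-batch SGD with momentum 0.9 (the
conventional value for this optimizer; the source design leaves it
unstated), learning rate 0.01, 30 epochs, batch 128, He initialization.
Training is seed-deterministic: identical seeds give bit-identical
weights. A "wide" preset (100 units) and a kNN preset (k = 1, Euclidean)
exist as configuration presets only.

**Evaluation.** Folds are assigned to participants (seeded shuffle within
class, round-robin), never to segments, so all 30 segments of a
participant stand or fall together — the guard against identity leakage.
Metrics (accuracy, precision, sensitivity, specificity, F1, as percent)
are computed from the fold-aggregated confusion matrix, with per-fold
panels and fold means alongside; ROC uses raw SVM decision values (AUC is
rank-based; no probability calibration) with trapezoidal AUC, and the PR
curve uses interpolation-free step summation.

## The synthetic cohort: what it emulates, and what a green test shows

No recordings of the source study are available, so the generator is the
package's test bed. Per participant (stream derived deterministically from
the master seed and the participant id — regeneration is byte-identical):

- breathing rate 15 breaths/min jittered ±10%, random phase per site;
- **healthy**: Gaussian noise band-passed to 60–1200 Hz (raised-cosine
  band edges), amplitude-modulated by the breathing envelope
  $\sin^2(2\pi t/T)$ — one inspiratory and one expiratory hump per cycle;
- **asthma**: the same, plus 1–3 wheeze components with per-participant
  frequencies drawn from 100–1000 Hz, present only in the expiratory
  half-cycle (raised-cosine onset/offset), amplitude tracking the
  breathing envelope, with slow sinusoidal frequency modulation (±8%,
  0.2–0.6 Hz) emulating the pitch glide of real wheezes;
- wheeze power is calibrated against the realized expiratory background
  power to a configurable SNR (default 0 dB; −Inf disables it), split
  across components; 16-bit PCM WAV output, peak-normalized to 0.9.

Two generator decisions came from explicit failure analysis. A wheeze of
*constant* amplitude inside the expiratory gate has locally unbounded SNR
wherever the breathing envelope passes through zero, which lets the log-Mel
features detect even a −30 dB wheeze through near-silent frames — hence
the envelope-tracking amplitude, which keeps the local wheeze-to-background
ratio at its nominal value everywhere. And a perfectly stationary pure
tone repeated over 90 s is far more detectable than a physiological
wheeze; the ±8% frequency glide removes that excess coherence. With both
in place, the end-to-end acceptance tests show the intended dose-response:
both classifiers above 90% accuracy at 0 dB SNR, collapse below 65% at
−30 dB, and chance on a participant-level label permutation.

What a green suite does **not** establish: the synthetic model contains no
heart sounds, crackles, device coloration, room acoustics, or
participant-level covariates (age, BMI, sex), and its noise floor is
stationary within a site. Accuracy numbers on synthetic cohorts
characterize the pipeline, not clinical performance; the published
clinical accuracies are not reproducible from this repository and are not
asserted anywhere in the tests.

## Quality control

The segment QC mirrors "spectral analysis" exclusion without a published
criterion: reject if the clipped-sample fraction exceeds 1% or if less
than 50% of periodogram energy falls inside the analysis band (default
60–1200 Hz). Both thresholds are configurable and deliberately inert on
clean synthetic audio, so the printed segment counts (30 per participant,
3600 total) are preserved; the filter is idempotent.

## Numerical choices and degenerate inputs

- Log floors: $10^{-12}$ in the Mel energies and the TQWT scalar —
  silence maps to finite features (MFCCs exactly 0).
- TQWT requires even-length inputs (3-s segments at integer sample rates
  are even); odd lengths error rather than silently pad.
- ReliefF ties break on the lower feature index; constant features score 0
  and contribute no distance.
- Standardization of a constant column centers it and flags it rather
  than dividing by zero.
- Metric panels report NA where a denominator is zero (e.g. precision with
  no positive predictions) instead of an arbitrary value.
- All randomness flows from explicit seeds: cohort streams from
  (seed, participant id), fold plans, NN init/shuffling, permutation
  importance.

## Known limitations

- The SMO solver precomputes the full kernel matrix (O(n²) memory; ~84 MB
  at n = 3240) — appropriate at this design size, not for much larger
  corpora.
- The CLI writes models with `saveRDS()`; artifacts are runtime outputs,
  not distribution files.
- The import path for external corpora (e.g. public respiratory-sound
  databases) is limited to mono 16-bit PCM WAV plus the manifest CSV
  convention; multi-channel or compressed audio is out of scope.
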