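---
title: "Bispectrum texture analysis of EEG: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectrum texture analysis of EEG: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

bispeeg implements a complete diagnostic-style classification chain for
two-class EEG problems (here: normal vs. autism spectrum disorder labels):

    band-pass -> fixed-length segments -> bispectrum magnitude image
    -> 18 texture features -> LSDA reduction -> Welch t-test selection
    -> cross-validated classification

This vignette explains the statistical model behind every stage, the
tunable parameters with their defaults and units, and the design decisions
that were genuinely open, so a reader can judge what the pipeline does and
does not establish.

## Why the bispectrum

The power spectrum of a signal discards all phase information: two signals
whose Fourier components have identical magnitudes but different relative
phases have the same power spectrum. The bispectrum

$$B(f_1, f_2) = E[X(f_1)\, X(f_2)\, X^*(f_1 + f_2)]$$

is the lowest-order spectral statistic that retains phase structure. Its
key property is sensitivity to *quadratic phase coupling* (QPC): if three
oscillations at $f_1$, $f_2$ and $f_1 + f_2$ satisfy
$\phi_3 = \phi_1 + \phi_2$, the triple product has constant (zero) phase
across estimation blocks and survives averaging, producing a peak at
bifrequency $(f_1, f_2)$. If $\phi_3$ is independent, the triple product's
phase is uniform across blocks and the average converges to zero. For
Gaussian processes the bispectrum is identically zero, so any persistent
structure in it reflects non-Gaussian, nonlinear signal generation — the
motivation for applying it to EEG, where coupling between oscillatory
rhythms is a plausible physiological discriminant.

`estimate_bispectrum()` uses the direct (FFT, block-averaged) estimator:
the segment is cut into overlapping blocks; each block is mean-removed,
Hann-tapered and FFT'd; triple products are averaged over blocks on the
half-grid $f_1, f_2 \in [0, f_s/2]$ (bins beyond the FFT length wrap
modulo $N$, the standard convention for the outer region of the square).
Defaults: block length 512 samples, 50% overlap, `nfft = 512`, Hann taper.
With the default 5519-sample segments this yields 20 averaged blocks — a
variance reduction that keeps the downstream texture features stable while
retaining ~1 Hz bifrequency resolution at 500 Hz sampling. The estimator
satisfies $B(f_1,f_2) = B(f_2,f_1)$ exactly and scales as amplitude cubed;
both are enforced by tests, and the estimator is checked bit-level (1e-10
relative) against a naive triple-product oracle computed with an explicit
DFT matrix.

`principal_domain_mask()` provides the non-redundant triangle
$0 \le f_2 \le f_1$, $f_1 + f_2 \le f_s/2$. Features are computed from the
full symmetric half-grid by default — magnitude plots of bispectra are
conventionally displayed as squares, and the symmetric redundancy is
harmless to min-max-quantized texture statistics — with the triangle
available through `bispectrum_config(use_principal_domain = TRUE)`.

## From bispectrum to texture

`magnitude_image()` compresses $|B|$ with `log1p` (bispectrum magnitudes
span many decades; without compression a single dominant peak collapses
the quantization) and min-max quantizes to `G = 64` gray levels:
`pixel = floor(G (m - min)/(max - min))` clamped to `G - 1`, constant
input mapping to zero. 64 levels balance run-length statistics against
sparsity of the 257 x 257 grid. With linear scaling the quantized image is
exactly invariant to overall signal amplitude; with `log1p` it is
approximately so.

Eighteen features are extracted per image (`extract_features()`):

* **Seven histogram measures** on the G-bin gray-level distribution $p$:
  Shannon entropy $-\sum p \log_2 p$; Rényi entropy of order
  $\alpha = 2$; a two-parameter Kapur entropy with orders
  $(\alpha, \beta) = (0.5, 0.7)$; min-entropy $-\log_2 \max p$ (the
  Rényi order-$\infty$ limit, exposed as "max entropy"); quadratic (Vajda)
  entropy $\sum p(1-p)$; a Yager-style fuzziness complement
  $1 - \sum |2p - 1| / G$; and log-energy $\sum \log_2(p^2 + \epsilon)$
  with $\epsilon = 10^{-12}$ guarding empty bins. The exact orders and
  definitional variants of the less standard measures are configurable
  (`entropy_config()`) because the field uses several inequivalent
  definitions under the same names; the defaults above are the package's
  declared, tested interpretation.
* **Eleven gray-level run-length (GLRLM) features** — SRE, LRE, GLN, RLN,
  RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE — in the classical
  Galloway/Chu/Dasarathy–Holder forms, with 1-based gray-level index
  $i$ (pixel value + 1) and run-length index $j$. Run-length matrices are
  computed in the four directions 0°, 45°, 90°, 135° and each feature is
  the mean of its four per-direction values (the common radiomics
  convention; per-direction matrices are available from `glrlm()`).
  The run counter is verified exactly against a brute-force per-pixel
  scanner on random images, and the tiling identity
  $\sum_{ij} j P(i,j) = n_\text{pixels}$ holds per direction.

Entropies are computed on the same quantized image as the run-length
features (not on raw magnitudes), so both families see the identical
input.

## Preprocessing

`bandpass()` applies the 0.3–40 Hz band. Because the downstream statistic
is phase-sensitive, filtering must be zero-phase; the package realizes the
forward–backward Butterworth response spectrally, multiplying each
channel's FFT by the closed-form squared Butterworth magnitude
$G(f) = 1/(1 + W(f)^{2n})$, $W(f) = (f^2 - f_{lo} f_{hi})/(f (f_{hi} -
f_{lo}))$, order $n = 4$ per pass. A recursive (transfer-function IIR)
realization of the same filter is numerically fragile at these parameters
— a 0.3 Hz edge at 500 Hz sampling places poles essentially on the unit
circle, and measured departures from linearity reach $10^{-5}$ relative —
while the spectral form is exactly linear and exactly zero-phase, at the
cost of circular edge handling, which is immaterial for the long,
zero-mean oscillatory records processed here.

`segment_channel()` cuts half-open windows of `L = 5519` samples (the
fixed segment length of the motivating study) with configurable overlap
(default 0: the segmentation is a partition, and concatenating segments
reproduces a prefix of the channel exactly).

## LSDA reduction

Locality sensitive discriminant analysis finds linear directions that
maximize the local between-class margin relative to local within-class
compactness. A kNN graph (k = 5) is split into same-label (Ww) and
different-label (Wb) adjacencies; with $L_b = D_b - W_b$ the directions
solve

$$X^\top(\alpha L_b + (1-\alpha) W_w)X\, a = \lambda\, X^\top D_w X\, a,$$

$\alpha = 0.5$ by default, keeping the top-$d$ eigenvectors ($d = 30$
requested by default, always clamped to $\min(\text{rank},
n_\text{features}, n-1)$ with a message).

Two numerical safeguards are applied, both standard for this family of
graph-embedding methods and both visible in the model object:

* features are standardized to unit variance (they have wildly mixed
  units: log-energy is a large negative number, RP a fraction), and
* the centered data are first projected onto the leading principal
  subspace retaining `pca_var = 0.95` of the variance. Without this, the
  right-hand metric is singular whenever the feature count approaches the
  sample count and the eigenproblem returns null-space directions that
  separate any labeling perfectly in-sample and at chance out-of-sample —
  an effect we observed directly when running the pipeline with
  per-channel feature blocks. A residual ridge (1e-8 of the mean metric
  diagonal) is applied, with a message, if the metric is still singular.

`welch_t_from_summary()` implements the unequal-variance two-sample test
with Welch–Satterthwaite degrees of freedom, reported as a magnitude.
The choice of Welch over the pooled test is not arbitrary: recomputing
the published summary table's t-values from its printed means and SDs
with group sizes 37/40 reproduces them to four decimals under Welch
(e.g. 3.7863) and not under pooling (3.7926). `ttest_rank()` applies the
same computation per reduced feature and `select_features()` keeps
features with $p < 0.05$, ascending in $p$ — deliberately without
multiple-testing correction, mirroring the published selection rule; that
this inflates selection under the null when reduction and testing use the
same data is a known caveat, and the leakage-free mode below is the
package's mitigation.

## Classification and validation

The probabilistic neural network (`pnn_fit()`) is a Parzen-window
classifier: the class-conditional density at $x$ is the average isotropic
Gaussian kernel to that class's training points, and prediction weights
the densities by the training priors $n_c/n$. As $\sigma \to 0$ it
degenerates to 1-nearest-neighbor (the implementation shifts distances
per test point so this limit is reached instead of underflowing); as
$\sigma \to \infty$ to the majority class, ties resolving to the first
class level. $\sigma$ defaults to an inner 5-fold grid search over 13
log-spaced multipliers $0.01$–$10$ of the median pairwise training
distance — an absolute grid would be meaningless across the orders of
magnitude spanned by reduced features. LDA/QDA (MASS), kNN (class) and
polynomial/RBF SVMs (e1071, coef0 = 1, C = 1, $\gamma = 1/d$) are wired
behind the same fit/predict contract.

`cross_validate()` performs stratified 10-fold CV (group-aware when
multiple rows share a subject), pools held-out confusion counts over
folds (micro-averaging — the only aggregation under which the published
percentages are exact ratios of a 77-subject cohort), and reports
accuracy, sensitivity, specificity, and PPV with the ASD class positive.
Undefined ratios are NA, never 0. `accuracy_vs_n_features()` traces CV
accuracy over top-$m$ feature subsets, ties resolved toward smaller $m$.

The pipeline offers two reduction-fitting modes. The default, `lsda_mode
= "cv"`, refits LSDA and the t-test selection inside every training fold,
so held-out subjects never influence the projection; `"global"` fits once
on the whole cohort before CV, which is how a single printed t-table
arises but lets the reduction see test labels. The global fit is always
computed for reporting (it is what `report$ttest` shows); only the CV
metrics differ between modes.

## The synthetic cohort

No EEG recordings accompany the motivating study, so validation uses a
generator (`generate_cohort()`) whose two classes differ **only** in the
prevalence of quadratic phase coupling — amplitudes and spectra are
identical by construction, so the power spectrum carries no class signal
and the bispectrum stage is load-bearing: if it were broken, no
downstream stage could recover the labels.

Per subject, each channel is a sum of cosine triplets (defaults: (8, 14)
and (11, 17) Hz, sums at 22 and 28 Hz, all inside the 0.3–40 Hz band)
over $1/f^\gamma$ Gaussian background noise ($\gamma = 1$, a generic
EEG-like slope) at 6 dB SNR. Phases are re-drawn every 0.5 s; a coupled
triplet sets $\phi_3 = \phi_1 + \phi_2$ in every epoch, an uncoupled one
draws $\phi_3$ independently — the phase-jump interval must be comparable
to the estimator's block length, or uncoupled triplets would be
indistinguishable from coupled ones within a segment. Each (channel,
triplet) pair is coupled with the class's probability: 0.1 for normals,
0.9 for the ASD class (the "strong contrast" study condition; a
zero-contrast cohort sets both to the same value). Triplet frequencies
are jittered by up to 1 Hz per subject.

Problem sizes were fixed once at desk scale: 37 + 40 subjects (the
cohort split of the motivating study), 8 channels, 60 s per subject at
500 Hz (five 5519-sample segments per channel). The full-size end-to-end
run takes on the order of four minutes; module tests use smaller cohorts
(10 + 10 subjects, 2 channels, 12 s) whose single segment per channel
makes them intentionally noisy, which the corresponding tolerances
reflect.

What the generator does *not* emulate: electrode topography, artifacts
(ocular, muscular, movement), non-stationarity beyond phase jumps, sleep
or vigilance structure, or any physiologically realistic ASD signature.
Passing the synthetic acceptance experiments demonstrates that the
implemented chain detects phase-coupling contrast end-to-end at realistic
SNR; it says nothing about clinical discriminability of real ASD EEG.

## Aggregation: one vector per child

Features are computed per (channel, segment), averaged over segments,
and, by default, averaged over channels too — one 18-feature vector per
subject (`aggregate = "subject"`), matching the group sizes (37/40) that
the published t-table implies. The alternative `aggregate = "channel"`
keeps per-channel blocks (18 × channels features). Channel blocks put
the reduction in the $n_\text{features} \approx n_\text{samples}$ regime
where the per-fold LSDA eigenproblem is unstable fold to fold, while
subject-level averaging cancels channel-level estimation noise and keeps
the reduction well-conditioned. Subject-level averaging is therefore the
default, with the
consequence that the requested $d = 30$ LSDA dimension clamps to at most
18.

## Degenerate inputs and tie-breaking

Constant magnitude images quantize to all-zero pixels; constant reduced
features get $t = 0$, $p = 1$ and a `degenerate` flag; empty selections
fall back to the single best-ranked component inside the CV composite (so
a fold never classifies on zero features); CV fold draws that leave a
one-class training set are redrawn from a derived seed, with a message;
kNN-graph and argmax ties break deterministically by index order;
eigenvector signs are fixed by making the largest-magnitude loading
positive. All randomness flows from explicit seeds; identical
configuration and seed reproduce cohorts, folds and reports bit-for-bit.

## Known limitations

* The entropy-measure names cover several inequivalent definitions in the
  literature; results depend on the declared choices (configurable, but
  defaults are what the tests pin down).
* The selection stage inherits the published rule ($p < 0.05$, no
  multiplicity control); its null behavior is calibrated only when the
  reduction is fit independently of the tested data, which is exactly
  what the default CV mode ensures.
* EDF support is a minimal 16-bit reader/writer for interchange of the
  package's own cohorts, not a general EDF+ implementation.
* Bicoherence, trispectra, GLCM features, artifact handling and
  deep-learning classifiers are out of scope.
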