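---
title: "Diverse-density dictionaries and constrained matching pursuit for hyperspectral classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diverse-density dictionaries and constrained matching pursuit for hyperspectral classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddsr)
```

## The problem

Supervised per-pixel classification of hyperspectral imagery suffers when
training pixels are scarce relative to the number of spectral bands (the
Hughes phenomenon): covariance-based classifiers become ill-conditioned,
margin classifiers become hyperparameter-sensitive, and every training pixel
that is mislabeled or spectrally mixed carries disproportionate weight.
`ddsr` implements a classifier built for exactly this regime. It represents
each ground-cover class by a *single* representative spectrum chosen to be
robust against impure training pixels, and classifies each image pixel by a
constrained sparse decomposition over those representatives.

## Dictionary learning by diverse density

Training pixels for a target class are treated as *positive bags* of
spectra, and all other classes' pixels as *negative bags* — the
multiple-instance learning view: a positive bag is only guaranteed to
contain *some* true example of the class. The diverse density (DD) of a
candidate spectrum $t$ is

$$\mathrm{DD}(t) \;=\; \prod_i \Big(1 - \prod_j\big(1 - \Pr(t \mid
B^{+}_{ij})\big)\Big)\;\prod_i \prod_j \big(1 - \Pr(t \mid B^{-}_{ij})\big),$$

with the instance kernel $\Pr(t \mid B_{ij}) = \exp(-\lVert B_{ij} -
t\rVert^2)$. The first factor is a noisy-OR: a positive bag supports $t$
if *any* of its instances is close. The second factor vetoes candidates
that sit near any negative instance. The dictionary atom for a class is the
$t$ maximizing this objective, computed by evaluating the log-DD at every
positive-bag instance and taking the argmax (`maximize_dd()`); ties break
to the first candidate in bag order. This candidate-set maximization is the
default and is exactly reproducible. An optional quasi-Newton refinement
(`refine = TRUE`, BFGS with an analytic gradient) continues the ascent into
the continuous spectral space from the best candidate.

Why singleton bags by default? Nothing in the bag formalism forces a
grouping of training pixels, and `bag_size = 1` is the least-assumption
choice: every training pixel is its own bag, the noisy-OR collapses to the
instance kernel, and the positive part of the objective becomes
$-\sum_i \lVert t - B_i\rVert^2$ — a vote by *all* training pixels that an
outlying (contaminated) candidate loses. Larger bags are supported.

### Numerical treatment

All DD arithmetic runs in the log domain: products of hundreds of bag
factors underflow double precision long before they stop being
informative. `log_dd` is accumulated by summing per-bag logs; an exact zero
factor (a negative bag containing the candidate itself) is carried as a
`-Inf` sentinel rather than an underflowed zero. When every instance
probability in a positive bag underflows, the noisy-OR is evaluated through
a log-sum-exp fallback ($1 - \prod(1-p_j) \approx \sum p_j$), so log-DD
stays finite and comparable even for distant candidates.

### The scale of the kernel

The kernel $\exp(-d^2)$ has no bandwidth parameter, so the *scale of the
spectra is the bandwidth*. On raw reflectance, within-class distances fall
in the kernel's sensitive range while cross-class distances push
probabilities toward zero — the regime where the objective discriminates.
L2-pre-normalizing every spectrum first compresses all pairwise distances
far below 1; every kernel value saturates near 1 and the objective
flattens, leaving candidates nearly indistinguishable.
`normalize = FALSE` is therefore the default for DD learning; the switch
exists for data whose raw scale is arbitrary, e.g. uncalibrated counts.
Note the asymmetry: dictionary *atoms* and test *pixels* are always
unit-normalized at the sparse-coding stage — scale-invariance is wanted at
decision time, scale-sensitivity at learning time.

### When refinement helps and when it hurts

With clean clustered bags, the continuous DD optimum averages noise across
bags, and refinement measurably sharpens concept recovery (the planted
concept test requires it). With singleton bags and contaminated training,
however, the continuous optimum degenerates toward the positive-instance
*mean* — negative-bag repulsion is negligible at raw scale — and that mean
is dragged off-class by the contaminated instances, while the candidate
argmax stays on a clean instance. Refinement is therefore off by default
and is a deliberate user choice.

## Sparse coding by constrained matching pursuit

Each test pixel is unit-normalized and greedily decomposed over the
dictionary $D = [d_1, \dots, d_m]$ (unit-norm atoms, grouped by class).
At step $m$ the atom with the largest *positive* inner product with the
current residual is selected; the projection is subtracted:

$$R^{m+1}x = R^m x - \langle R^m x, d\rangle\, d, \qquad R^0 x = x .$$

Atoms with negative correlation are never selected: mixed reflectance
pixels are physically non-negative combinations of materials, so negative
abundances are meaningless. Repeated selection of an atom accumulates onto
its coefficient, which preserves the expansion identity

$$\lVert x\rVert^2 = \sum_{m} \lvert\langle R^m x, d_m\rangle\rvert^2 +
\lVert R^M x\rVert^2,$$

checked to $10^{-10}$ for every pursuit by `expansion_energy_check()`.
The pursuit stops when the residual norm falls below the relaxation factor
$\xi$ (default $10^{-3}$ on unit-norm pixels — reconstruction to 0.1% of
the pixel's energy, which is below the noise floor of any realistic scene),
when the accumulated coefficient mass reaches 1, when no atom has positive
correlation, or at the iteration cap (default $4\times$ the atom count).
Accumulated coefficients are then rescaled to sum to one. Rescaling is the
simplest mechanism that delivers non-negative, sum-to-one coefficients
while preserving their ranking — and the downstream decision rule consumes
only the ranking and the 0.5 threshold.

A note on selection: maximizing $\lvert\langle x, d_i\rangle\rvert$ and
requiring positivity conflict for anti-correlated atoms; positivity wins
here, on the physical grounds above, so selection maximizes the *signed*
inner product restricted to positive values.

## The decision rule

If any finalized coefficient exceeds 0.5, the pixel is assigned that atom's
class outright — more than half the recovered abundance in one atom is
unambiguous (with threshold $\ge 0.5$ and simplex coefficients, at most one
atom can fire). Otherwise the per-class squared reconstruction residual

$$r_k(x) = \lVert x - D_k \alpha_k \rVert^2$$

is computed from the pursuit's own coefficients restricted to class $k$,
and the minimizing class wins. Squared and unsquared residuals rank
identically; the squared form is used. Two edge policies are ours, stated
explicitly rather than inherited: residual ties break to the lowest class
code, and a pixel whose code is all-zero (no positively correlated atom)
degenerates to a flagged lowest-code tie. An optional per-class
least-squares refit of $\alpha_k$ before the residual comparison is
available (`refit_residual = TRUE`); the default reuses the stored sparse
coefficients.

## The synthetic scene generator

`render_scene()` is first-class, tested code, not a fixture: every
downstream stage is validated against scenes with known ground truth.
A scene is a block layout of rectangular per-class patches. Each class's
endmember is a sum of Gaussian bumps on the band grid, rescaled to unit
peak. The default bump layout uses two broad *backbone* bumps shared by all
classes plus two small class-specific bumps whose centers are stratified
into class-specific slots of the band range. The backbone mimics the high
inter-class spectral correlation of real vegetation classes, which is what
makes hyperspectral classification hard; fully independent random
endmembers would make every classifier saturate. Stratified slots
guarantee pairwise distinctness (cosine below 0.999, asserted) for
any seed. Presets `"phi"` (65 bands, 7 classes) and `"aviris"` (166 bands,
6 classes) match the band/class counts of the airborne scenes this
simulator emulates.

Pure pixels are endmember plus i.i.d. Gaussian noise calibrated so that
mean signal power over noise power equals $10^{\mathrm{SNR_{dB}}/10}$.
A `mix_fraction` subset of labeled pixels is rendered as a convex
combination of the patch's endmember and the next class's endmember with
Beta(2, 2) weights; the larger weight goes to the patch's own class so the
recorded label remains the dominant material. Training draws
(`sample_training()`) follow the small-sample protocol: total count =
ratio × bands, split as evenly as possible with the remainder to the
lowest class codes, without replacement; an explicit per-class count
override reproduces fixed designs such as 4 per class on 65 bands.
`contaminate_training()` replaces a fraction of each class's training
spectra with pixels drawn from other classes' labeled pixels, emulating
mislabeled field picks.

What the generator does *not* model — and hence what green tests do not
certify about real data: spatially correlated or signal-dependent noise,
within-class spectral variability beyond isotropic noise (illumination,
moisture, canopy geometry), multi-modal class distributions, atmospheric
effects, and spectral libraries. The most consequential omission is
within-class structure: on unimodal Gaussian classes a nearest-class-mean
baseline in PCA space is close to the Bayes rule and is provably
insensitive to symmetric training contamination below 50% (the
contaminated mean moves at most the contamination fraction of the
inter-class distance), so the single-atom sparse classifier does not
out-rank it there, whereas on real heterogeneous scenes the representative-
instance dictionary is the method's advantage. Benchmarks on this generator
therefore read as *calibration and robustness* checks, not as evidence of
superiority on real imagery.

## Study problem sizes

The packaged benchmarks use a 42×42-pixel 7-class scene at 65 bands
(14×14-pixel patches, 1372 labeled pixels) and a 40×42 6-class scene at
166 bands; training sizes follow the 0.5/1.0/1.5 × bands ratios with three
repeated draws. The robustness benchmark fixes SNR at 20 dB, training
contamination at 0.25, and mixed-pixel fraction at 0.25 — the boundary
pixels of a 14×14 block are 27% of its area, so a quarter of labeled
pixels being mixtures matches a block-structured field scene. These sizes
were chosen as the smallest scenes on which patch structure, mixing and
contamination all operate at realistic proportions.

## Baselines

`fit_pca_mind()` implements the PCA + minimum-distance comparator: PCA on
the pooled centered training spectra, retaining the smallest number of
components reaching `variance_kept` (default 0.99) of total variance;
class means live in the projected space and prediction is
nearest-mean in raw (unwhitened) principal-component coordinates.
`svm_baseline()` is a thin adapter over an off-the-shelf RBF SVM; its
hyperparameters are exposed, not tuned, and it is excluded from the
package's correctness checks.

## Reproducibility

All randomness flows through explicit integer seeds (`with_seed()`
internally, so the caller's RNG state is never touched). `run_pipeline()`
derives every training draw's seed from the base seed, writes a manifest
(package version, config hash, base seed) beside its metrics, and two runs
of the same configuration produce byte-identical metrics JSON — asserted
in the test suite.

## Known limitations

* One atom per class is the default; multi-atom dictionaries are supported
  structurally (class-grouped atoms, per-class coefficient sums in the
  decision) but no multi-concept learning strategy is provided.
* The DD kernel has no per-band weighting; bands with large dynamic range
  dominate distances.
* The atom is a single learned instance: its pixel-level noise propagates
  into every decision, which is the binding constraint at low SNR.
* No spatial regularization of the output map.
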