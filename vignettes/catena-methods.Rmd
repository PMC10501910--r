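---
title: "Methods: multimodal integrity of catecholaminergic nuclei and memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal integrity of catecholaminergic nuclei and memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The dopaminergic substantia nigra-ventral tegmental area (SN-VTA) and the
noradrenergic locus coeruleus (LC) appear as focal hyperintensities on
dedicated MRI sequences (fast spin echo, FSE; magnetization transfer with
and without the saturation pulse, MT+ and MT-). Standardized against a
nearby white-matter reference region, their peak intensity is used as a
proxy for the structural integrity of these nuclei, and individual
differences in that proxy have been related to late-life memory.

`catena` re-implements this analysis chain as reusable, tested components:

1. semiautomatic **peak-intensity-ratio extraction** from masked volumes,
2. a self-contained **structural equation modeling (SEM) engine** with
   full-information maximum likelihood (FIML) under missingness,
3. declarative **builders** for the study's model families, and
4. a **synthetic cohort generator** with a fully known latent ground truth,
   so every downstream stage can be validated without access-restricted
   study data.

## Intensity extraction

For each axial slice $z$ (the third grid axis), hemisphere and scan, the
contrast ratio is

$$\mathrm{ratio}(z) \;=\; \frac{\max(\mathrm{ROI}_z) - \max(\mathrm{Ref}_z)}
{\max(\mathrm{Ref}_z)},$$

where $\max(\mathrm{ROI}_z)$ is the peak intensity inside the LC or SN-VTA
mask on that slice and $\max(\mathrm{Ref}_z)$ the peak inside the reference
mask (pontine for the LC, crus cerebri for the SN-VTA). The participant's
indicator is the maximum ratio over usable slices. Choices worth noting:

* **Slice-wise reference peak.** The formula is applied slice by slice, and
  we treat the reference symmetrically with the ROI (the region-global
  alternative is a one-line change; the slice-wise reading is the default
  because the ROI peak is explicitly defined per slice).
* **Exclusion masks mark voxels unusable (`NA`), never zero.** The fourth
  ventricle is hyperintense on MT scans and adjacent to the LC; zeroing it
  could create spurious minima in later extensions, so excluded voxels
  simply cannot win a peak search. FSE scans pass through untouched.
* **Ties at the peak are irrelevant**: only the maximum value enters the
  ratio, so no tie-breaking rule is needed.
* **FSE acquisitions** (two per participant at TP2) are averaged after
  extraction; a missing acquisition leaves the other flagged
  `single_acquisition`.
* **Outlier screening is single-pass**: within each stratum (region x
  modality x hemisphere x timepoint, pooled across age groups), the mean
  and s.d. are computed once, values beyond 3 s.d. are flagged and
  dropped, and survivors are scaled x100. Strata with fewer than three
  values are scaled but not screened (with a warning). Regional
  gray-matter volumes get the same screen, then x10,000 and division by
  total intracranial volume.

## The SEM engine

Models are declarative entry lists (loadings, regressions, covariances,
variances, means; free, fixed, or label-constrained) compiled to the
reticular path-matrix form $v = Av + u$, $u \sim N(M, S)$, observed
$= F v$, giving implied moments
$\Sigma = F(I-A)^{-1}S(I-A)^{-\top}F^\top$ and $\mu = F(I-A)^{-1}M$.
One algebra covers factor, regression, stability and change models.

**Likelihood.** FIML sums each case's multivariate-normal log-density over
its observed subset. Cases are grouped by missingness pattern and each
pattern reduced to sufficient statistics $(n_b, \bar y_b, S_b)$, so an
evaluation costs $O(\text{patterns} \cdot p^3)$ independent of sample
size; the compiled kernel (RcppArmadillo) returns an optimizer surrogate
($-\infty$) instead of raising when a restricted covariance is not
positive definite. A naive casewise implementation is kept solely as an
independent cross-check and the two are asserted to agree to $10^{-10}$.

**Optimization.** BFGS on a log-variance parameterization (variances stay
positive; covariances and paths unconstrained), with data-informed starts
plus dispersed jittered restarts (3 by default, seeded), forward-difference
gradients inside the optimizer and central differences for the final
polish and convergence check. A fit is flagged non-converged unless the
optimizer reports success and the gradient norm is small; all downstream
inference refuses non-converged fits. Standard errors come from the
inverse observed information (numerical Hessian in the untransformed
parameterization).

**Fit indices.** The saturated model is itself FIML-estimated — by EM on
the pattern sufficient statistics — so $\chi^2 = 2(\ell_{sat} - \ell_M)$
is well defined under missingness (with complete data the EM reduces to
the closed-form MLE in one step). The independence baseline (free means
and variances, zero covariances) has a closed-form FIML solution per
variable. RMSEA uses the multi-group convention
$\sqrt{G}\sqrt{\max(\chi^2-df,0)/(df\,N)}$ and is reported as 0 with a
note when $df = 0$; CFI is clamped to $[0, 1]$ by construction. By the
reporting convention adopted throughout, $\alpha = 0.05$ and
$0.05 < p \le 0.1$ is labelled a "trend".

**Invariance ladder.** Configural, weak (equal loadings), strong (equal
intercepts, latent means freed in non-reference groups), strict (equal
residual variances), each compared to the previous step by a
likelihood-ratio test. The same machinery applies across timepoints for
variables following the `name_tp<k>` convention.

## Model families and identification choices

* **Modality factors**: left/right peak ratios load on one latent per
  modality (first loading fixed to 1); the SN-VTA has no FSE factor
  because that sequence covers only the brainstem.
* **Multimodal factors**: a second-order factor over the modality factors
  removes modality-specific measurement error. With only two first-order
  factors (SN-VTA; also the MTL volume factor and the multimodal slope
  factor) *both* second-order loadings are fixed to 1 — a free loading
  plus a free variance would not be identified from a single covariance.
* **Neurocognitive models**: the correlation variant frees neural x
  cognitive latent covariances; the regression variant reparameterizes the
  same joint covariance as directed paths plus disturbance covariances.
  The two are statistically equivalent (identical likelihood and df), and
  the suite asserts this on every fixture dataset.
* **Latent change scores**: baseline and change latents with loadings
  fixed to 1 (change loads on the later occasion only). Single-indicator
  (cognitive task) models fix occasion residuals to 0 — observed-score
  change, the standard single-indicator identification. The joint neural
  model (hemisphere-averaged MT+ and MT-) keeps free occasion residuals
  constrained equal within modality, which is identified once both
  modalities are modelled jointly with a higher-order slope factor.
* **Prediction model**: age predicts the multimodal change factor
  (testing more negative change at higher ages) and, together with the
  change factor, the TP3 cognitive factor (testing prediction of future
  memory over and above age). These are single-group older-adult models;
  `older_only()` drops younger rows with a notice.
* **Reported comparisons**: all-zero associations (df 3), equal across
  domains (df 2), equal across regions (df 1), each an equality/zero
  constraint on *raw* latent covariances tested by LRT, mirroring the
  nested-model workflow of the emulated analysis. The printed z-test for
  dependent correlations is not reproduced; the LRT is the supported
  alternative.

## The synthetic world

The generator states a known world chosen to emulate the study's design,
not to reproduce its estimates:

* 69 younger (age ~ N(32.7, 3.9)) and 251 older (N(72.4, 4.0)) adults by
  default; imaging at TP1/TP2; FSE only at TP2 with two acquisitions;
  cognition at TP1-TP3 with TP3 restricted to older adults.
* Per participant, six latent constructs (LC, SN-VTA, working memory,
  episodic memory, fluid intelligence, MTL volume) with moderate positive
  correlations (e.g. LC-EM 0.49, SN-VTA-WM 0.28, LC-SN-VTA 0.25 — the
  directional pattern of interest), older-group mean deficits, and
  within-person change with an age slope (standardized ~ -0.2 for neural
  change) plus correlated change residuals (neural change -> memory
  change), so the prediction models have signal to find.
* Rendering is multiplicative on the reference intensity: ROI voxels carry
  `ref_mean * (1 + roi_offset + gain * latent)` plus Gaussian voxel noise,
  reference voxels `ref_mean`, so the noiseless target ratio is exactly
  `roi_offset + gain * latent` — which makes extraction oracle-checkable.
  Offsets (0.26 / 0.20 / 0.06) echo the printed contrast ordering
  MT+ > FSE > MT-; a modality-specific true-score component (s.d. 0.8 in
  latent units, i.i.d. over time) yields realistic cross-modality
  correlations (~0.6) and makes multimodal factors genuinely more stable
  than modality-specific ones.
* The fourth-ventricle box is rendered hyperintense (1.5 x reference) in
  MT scans only, and the LC *masks* are dilated into it, so the exclusion
  mask has real work to do.
* Missingness is completely at random at per-(modality, timepoint) rates
  (placeholders exposed in the config; the study reports only counts), on
  top of the structural rules, which are never violated. FIML is valid
  under MCAR/MAR, so green tests do not certify behavior under informative
  missingness.
* Randomness is drawn from named per-participant substreams derived from
  the master seed, so adding participants never perturbs earlier ones and
  cohorts are byte-reproducible.

What a green suite establishes: the formulas and algorithms do what they
claim on data whose truth is known, at the stated tolerances. What it does
not establish: anything about scanner physics, registration error,
non-normal score distributions, or informative dropout — none of which are
simulated.

## Numerical choices

* Optimizer tolerances: relative log-likelihood change `1e-12` (loosened
  to `1e-9` inside large simulation loops), gradient check on central
  differences, up to 3 extra jittered restarts if every planned start
  fails.
* Variances live on the log scale; a non-positive-definite implied
  covariance or singular $(I-A)$ yields a large finite penalty, never an
  exception, so BFGS can back off.
* The likelihood-ratio test requires nesting by df and errors if the
  "free" model fits worse than the constrained one by more than `1e-4`;
  tiny negative $\Delta\chi^2$ is clipped to 0. Identical models return
  the degenerate result $\Delta\chi^2 = 0$, $p = 1$.
* Builder "truth" values (gains 4/3/2 on the x100 ratio scale, intercepts
  26/20/6, residual variance 4) anchor simulation-based recovery tests;
  they are engine choices consistent with the synthetic world, set once at
  design time.
* NIfTI output is float32 with a zeroed gzip timestamp: byte-identical
  reruns, at the cost of ~1e-7 relative storage precision (tests that
  round-trip through files use tolerances accordingly).

## Known limitations

* The engine fits multivariate-normal FIML only: no robust or weighted
  least squares, no ordinal indicators, no bootstrap standard errors.
* Standard errors are numerical-Hessian based and can be fragile near
  variance boundaries; inference in the package rests on likelihood-ratio
  tests, as in the emulated analysis.
* Spatial preprocessing (template construction, registration, bias
  correction, segmentation) is out of scope; volumes and masks are assumed
  to share a common space, as the synthetic volumes do by construction.
* The exact availability rates per sequence and the source study's
  optimizer settings are not public; both are exposed as configuration
  with documented defaults rather than claimed as reproductions.
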