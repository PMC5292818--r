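---
title: "Network-based survival analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based survival analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icasurv)
```

## The problem

In longitudinal dementia cohorts, a fraction of people with mild cognitive
impairment (MCI) convert to Alzheimer's disease within a few years of
follow-up while the rest remain stable or are censored. The question this
package addresses is how to quantify conversion risk from baseline brain
images — gray-matter maps from structural MRI and glucose-metabolism (SUVr)
maps from FDG-PET — without modelling every voxel separately. The approach:

1. **Network extraction.** On an independent *reference* cohort with a clear
   group contrast (patients vs. controls), spatial independent component
   analysis factorizes the subjects-by-voxels matrix \(X \approx A S\),
   where rows of \(S\) are spatial networks of covarying voxels and columns
   of \(A\) ("loadings") say how strongly each subject expresses each
   network.
2. **Network selection.** A two-sample *t*-test on each loading column finds
   the networks that separate the reference groups; Bonferroni correction
   controls the familywise error over the estimated components. Selected
   sources are Z-scored and thresholded at \(Z \ge 3\) into binary
   templates.
3. **Feature extraction.** For each survival-cohort subject, the mean image
   intensity inside each template is one covariate.
4. **Survival modelling.** Cox proportional-hazards models relate these
   network features and clinical variables to months-to-conversion, with
   administrative censoring at 36 months. Five chained models are fitted
   (per-modality, two-modality, clinical, comprehensive), each later stage
   keeping only the covariates that were significant before.
5. **Evaluation.** The significant factors of each stage are combined by
   logistic regression into one index and assessed by ROC analysis
   (AUC, accuracy, sensitivity, specificity) against converter status.

## Models

### MDL model order

The number of retained components is chosen by minimum description length
on the eigenvalues \(\lambda_1 \ge \dots \ge \lambda_p\) of the
subjects-covariance matrix (voxels as samples):
\[
\mathrm{MDL}(k) = -N\,(p-k)\,
  \log\frac{\mathrm{GM}(\lambda_{k+1..p})}{\mathrm{AM}(\lambda_{k+1..p})}
  + \tfrac12\,k\,(2p-k+1)\,\log N .
\]
The log-ratio term is zero when the trailing eigenvalues are equal
(pure isotropic noise) and grows when structure is left unexplained; the
penalty grows with \(k\). We take the effective sample size \(N\) to be the
number of in-mask voxels. Smoothed images have spatially correlated voxels,
so this \(N\) is optimistic and the criterion errs toward larger orders on
real smoothed data; `estimate_order_mdl(..., n_eff =)` allows an explicit
correction. On the synthetic worlds below (iid voxel noise) the criterion
is exact and recovers the planted rank.

### Infomax ICA

After PCA whitening to the chosen order, the unmixing matrix `W` is fitted
by natural-gradient Infomax with the logistic nonlinearity:
\(W \leftarrow W + \eta\,(I + (1-2g(U))U^{\mathsf T}/N)\,W\),
\(U = WY\), \(g(u) = 1/(1+e^{-u})\). Choices that matter:

* **Initialization** — a random orthogonal matrix drawn from an explicit
  seed; runs are bit-reproducible, and two different seeds on
  well-separated data agree up to permutation and sign (tested).
* **Learning rate** — 0.01, halved whenever the angle between successive
  updates exceeds 60°; a divergence guard restarts colder.
* **Convergence** — relative weight-change norm below `tol = 1e-6`.
  Full-batch gradient ascent reaches this in roughly 1000–2000 sweeps, so
  the default `max_iter` is 2048. (512 iterations, a common default
  elsewhere, reproducibly stops short of `tol` on our fixtures; the result
  is then still usable but flagged.)
* **Normalization** — each source row is scaled to unit population variance
  with its largest-magnitude voxel positive, and the mixing columns absorb
  the change. This makes Z-maps and templates deterministic: without a sign
  convention, ICA is only defined up to sign and every downstream template
  could silently flip.

The reconstruction identity \(A S = \) (rank-\(k\) projection of the
centred data) holds exactly by construction, independent of `W`'s
convergence; component *identification* is what iteration buys.

### Cox partial likelihood

`fit_cox()` maximizes the log partial likelihood by Newton–Raphson with
step-halving; standard errors come from the inverse observed information.
Tied event times use Breslow's approximation by default (Efron selectable):
survival time is reported "by the month" (to 0.1 month in the generator),
so ties are guaranteed and a tie rule is not optional. Breslow was chosen
as the default because it is the convention most survival software used
historically and it makes the duplication-invariance property exact; on
our cohorts the two rules agree to well within one standard error (both
are tested against the `survival` package).

Degenerate inputs are first-class: constant covariates and collinear
columns are named errors; a covariate that perfectly orders the risk sets
(monotone likelihood) is detected as unbounded coefficient growth and
returned flagged rather than silently "converged".

Covariates enter **unstandardized**. Template means are small numbers
(unit-norm sources), so hazard ratios per unit can be extreme
(e.g. \(10^{-4}\)); this mirrors how such models are usually reported and
is why the CI identities `hr = exp(beta)`,
`ci = exp(beta ∓ 1.959964 · se)` are part of the acceptance suite.

### Chaining and evaluation

Stages carry forward covariates with per-covariate Wald \(p < 0.05\)
within their own model. The comprehensive stage enters the significant
clinical variables only (flag `cox.all_clinical` enters all seven).
Evaluation is **in-sample**: the logistic index is fitted and assessed on
the same survival cohort. That mirrors the analysis this package
operationalizes, and it means reported accuracies are optimistic; the
pipeline exposes the pieces needed for cross-validation but does not do it
by default. The ROC operating point maximizes Youden's \(J\) (ties broken
toward higher sensitivity) because no selection rule is standard for
printed accuracy/sensitivity/specificity triples; a fixed-0.5 rule is
available (`evaluation.rule = "fixed"`).

## The synthetic world

The generator states one world and the tests live in it:

* **Sources** are unit-norm Gaussian blobs (sd = radius/2, support
  truncated at 2.5 sd) at centres ≥ 2 radii apart — pairwise |cosine|
  < 0.3. Only the mixing algebra matters for the statistics downstream;
  anatomical realism does not, and none is attempted.
* **Loadings** are N(5, 1); the case group's mean is shifted by
  `group_shift` on the affected components, so `group_shift` is in units
  of the loading SD.
* **Noise** is iid Gaussian per voxel, in intensity units. Unit-norm maps
  put the per-voxel signal RMS near \(\sqrt{26k/V}\) (≈ 0.2 on a 16³
  grid), so the default `noise_sd = 0.01` is about 5% of signal — the
  regime the recovery criteria stipulate. No scanner artifacts,
  partial-volume effects, or registration error are simulated; a green
  recovery test says the algorithms work on well-specified linear
  mixtures, not that they survive real-scanner physics.
* **Conversion times** are inverse-transform draws from an exponential
  proportional-hazards model, hazard
  \(\lambda_0 \exp(\beta^{\mathsf T}(x - \bar x))\); covariates are centred
  in the linear predictor so `baseline_rate` is the hazard at covariate
  means (Cox estimates are unaffected by the centring). Times beyond 36
  months are censored *at exactly 36* — administrative censoring, as in
  the cohorts this emulates.
* **`baseline_rate = 0.02`/month** reproduces a ≈ 51% conversion fraction
  by 36 months (the emulated cohorts run ~54%). An exponential baseline
  cannot simultaneously match that fraction and an 18-month mean
  conversion time (the mean-among-events is < 18 for every rate and
  approaches 18 only as the rate vanishes), so the fraction was matched
  and the resulting ≈ 16-month mean accepted. This is a default, not a
  claim under test.
* **Clinical covariates** use MCI-typical baseline distributions
  (ADAS-cog 10.8 ± 4.9, CDR-SB 1.6 ± 0.9, MMSE 27.4 ± 1.8, age
  73.4 ± 7.5 y, education 16 ± 2.6 y, 62% male, APOE ε4 allele counts
  0/1/2 with probabilities 0.444/0.427/0.128). The three cognitive scales
  are drawn jointly with correlations ±0.5 so that "correlated clinical
  covariates" is true of the world, not just allowed by it. APOE enters
  as an allele count by default (`cox.apoe_binary` switches to carrier
  status); the count coding matches reporting a single hazard ratio "per
  unit".
* **Determinism** — every stochastic operation takes an explicit seed and
  restores the ambient RNG state; identical seeds give bit-identical
  cohorts, decompositions, templates and reports.

## Numerical choices and degenerate inputs

* Voxel flattening is R column-major order (x fastest); one order is fixed,
  asserted in tests, and used by both the matrix and 3-D code paths.
* The default analysis mask keeps voxels nonzero in **all** subjects.
* Z-maps use the population SD; templates are positive-tail only
  (`Z >= 3.0`, inclusive). Whether negative tails should also form
  templates is genuinely open; with the positive-peak sign convention the
  dominant tail of each source is positive, which is what the one-sided
  rule assumes.
* The Bonferroni divisor is the number of *estimated* components per
  modality, not the number selected.
* `estimate_order_mdl` clamps eigenvalues at machine epsilon before logs;
  a rank-deficient whitening request fails naming the numerical rank.
* Gaussian smoothing renormalizes truncated kernels at array edges so
  constant volumes are exactly preserved; `fwhm = 0` is the identity.
* Logistic separation is capped at |30| and flagged; the index still ranks.

## Known limitations

* The NIfTI-1 reader/writer is minimal (uncompressed single-file `.nii`,
  scalar datatypes, sform affine). It round-trips its own output exactly
  and reads typical preprocessed volumes, but it is not a general
  neuroimaging I/O layer.
* In-sample evaluation overstates out-of-sample accuracy (by design,
  documented above).
* MDL's iid-voxel assumption inflates model order on smoothed real data.
* The five-model chain propagates selection uncertainty silently: a
  covariate that misses \(p < 0.05\) at one stage is gone, and no
  stability analysis (e.g. resampling the reference cohort) is performed.
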