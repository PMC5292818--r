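# icasurv

Network-based survival analysis of multimodal brain-imaging cohorts in R.

## What it is for

Cohort studies of mild cognitive impairment (MCI) follow patients from a
baseline scan until they convert to Alzheimer's disease or are censored.
`icasurv` implements, as a tested and reusable pipeline, the network-based
version of that analysis:

1. **Spatial ICA on a reference cohort.** A subjects-by-voxels matrix
   (patients + controls, per modality: structural gray-matter maps,
   FDG-PET SUVr maps) is decomposed as `X ≈ A S` by natural-gradient
   Infomax, with the model order chosen by the eigenvalue-based MDL
   criterion. Rows of `S` are spatial brain networks; columns of `A` are
   per-subject network loadings.
2. **Network templates.** Loading columns are compared between groups by a
   pooled-variance two-sample *t*-test; Bonferroni-surviving components are
   Z-scored and binarized at `Z ≥ 3.0` into template masks.
3. **Features for an independent survival cohort.** Each subject's mean
   intensity inside each template is one covariate.
4. **Chained Cox models.** Five multivariate Cox proportional-hazards
   models (Newton–Raphson partial likelihood, Breslow/Efron ties):
   MRI-only, PET-only, two-modality (significant factors of the first
   two), clinical-only, and comprehensive (significant factors of the
   two-modality and clinical stages). Hazard ratios are reported with
   Wald 95% CIs, `HR = exp(β)`, `CI = exp(β ∓ 1.959964·SE)`.
5. **ROC evaluation.** Per stage, significant factors are combined by
   logistic regression into one index; AUC, accuracy, sensitivity and
   specificity are computed at the Youden-optimal threshold.

Restricted clinical data are not required anywhere: a first-class
synthetic-data module generates reference and survival cohorts with the
assumed statistical structure (linear spatial mixing, group-shifted
loadings, proportional-hazards conversion times censored at 36 months)
and retains the full ground truth for recovery testing. Minimal NIfTI-1
I/O is built in (the target environment ships no R NIfTI package).

See `vignettes/network-survival-methods.Rmd` for the models, assumptions,
parameter choices and limitations.

## Worked example

```r
library(icasurv)

cfg <- default_config()        # a fully seeded synthetic world
cfg$output.dir <- tempfile("demo")
report <- run_pipeline(cfg, quiet = TRUE)
print(report)
```

```
<pipeline_report> f73870764b69576005356c9d49afdd4f 
  ICA orders: structural=6, metabolic=5 
  templates: structural_IC_02, structural_IC_05, metabolic_IC_02 
  metrics:
         model accuracy sensitivity specificity       auc
           mri     70.5    65.21739    77.64706 0.7848593
           pet     60.0    52.17391    70.58824 0.6130946
  two_modality     76.5    86.08696    63.52941 0.8089003
      clinical     72.0    76.52174    65.88235 0.7394885
 comprehensive     81.0    80.00000    82.35294 0.8826598
```

Reading this output: the synthetic world plants risk in two structural
networks, one metabolic network, and three clinical variables (ADAS-cog,
CDR-SB, APOE ε4). MDL recovered the planted orders (6 and 5 components).
Selection found three group-separating networks and built their
templates. The metric table is the qualitative signature the pipeline is
designed to exhibit: combining modalities beats either alone, and adding
clinical variables beats imaging alone (AUC 0.88 vs 0.81 vs 0.78/0.61).
The comprehensive Cox table (`report$cox$comprehensive`) shows negative
β (protective hazard per unit of network intensity — atrophy/
hypometabolism raise risk) for the imaging features and positive β for
the cognitive/genetic covariates:

```
              term        beta         se         z            p         hr      ci_low    ci_high
1 structural_IC_02 -4.25192131 0.72508242 -5.864052 4.517047e-09 0.01423685 0.003437342 0.05896649
2 structural_IC_05 -4.15904844 0.73529164 -5.656325 1.546486e-08 0.01562242 0.003697148 0.06601302
3  metabolic_IC_02 -4.36099062 0.85410198 -5.105937 3.291599e-07 0.01276574 0.002393497 0.06808615
4          apoe_e4  0.57476295 0.13773872  4.172849 3.008138e-05 1.77670930 1.356353722 2.32733976
5         adas_cog  0.07621393 0.02136289  3.567585 3.602871e-04 1.07919342 1.034939971 1.12533911
6           cdr_sb  0.42534600 0.12750655  3.335876 8.503116e-04 1.53011974 1.191767806 1.96453237
```

All artifacts (selection tables, per-stage Cox CSVs, metrics CSV, a JSON
report embedding the config and its hash) are written under
`cfg$output.dir`; rerunning the same config reproduces them bit-for-bit.

The same pipeline runs from the command line:

```sh
inst/bin/icasurv run --config pipeline.cfg --out results/
```

with verbs `generate | decompose | select | fit | evaluate | run` resuming
from cached stages.

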