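# specdcm

Dynamic causal modelling of EEG cross-spectral densities for a cortical
grasping network, in R.

## The problem

Visually guided precision grip is controlled by a parieto-frontal network —
inferior parietal lobule (IPL), primary motor cortex (M1), ventral premotor
cortex (PMv), supplementary motor area (SMA) and dorsolateral prefrontal
cortex (DLPFC) — whose directed interactions change over development and
relate to how precisely a person can trace a force target. `specdcm` is for
researchers who want to estimate those directed (effective) couplings from
EEG spectra and relate them to behaviour across a cohort:

* **Generative model.** Each source is a convolution-based neural mass
  (spiny stellate, inhibitory and pyramidal populations, second-order
  synaptic kernels). Sources are coupled by 14 extrinsic connections —
  forward, backward and lateral, targeting the physiologically appropriate
  populations — each parameterized as a unit-less log-scaling θ of a fixed
  baseline. The linearized system predicts mode-level cross-spectra
  G(f) = L·T(f)·G_u(f)·T(f)ᴴ·Lᴴ + G_n(f) with transfer function
  T(f) = C (2πif·I − J)⁻¹ B over 4–48 Hz.
* **Inversion.** Variational Laplace: Gauss–Newton/Levenberg–Marquardt
  ascent on the free energy F = accuracy − complexity, returning Gaussian
  posteriors over couplings, the model evidence, and variance explained.
* **Model comparison.** Random-effects Bayesian model selection across
  subjects (variational Dirichlet scheme) with exceedance and protected
  exceedance probabilities; a hidden-source control model verifies that
  each source contributes to the observed spectra.
* **Group level.** Parametric empirical Bayes: a hierarchical Gaussian GLM
  θᵢ = Xᵢβ + εᵢ over subjects' couplings (design: intercept, performance,
  age group, interaction), fitted through Bayesian model reduction, with
  greedy/exhaustive search over nested models, Bayesian model averaging,
  and thresholding at posterior probability > 0.95.
* **Prediction.** Leave-one-out cross-validated multiple regression
  (performance, age in months) and quadratic discriminant classification of
  age group from the coupling estimates, with an exact binomial test
  against the no-information rate.
* **Synthetic cohorts.** A first-class generator plants known group effects
  and produces spectra and force traces with the statistical structure the
  analysis assumes, so every stage is validated by parameter recovery.

## Worked example

Generate a small synthetic cohort (5 subjects per age group, planted
effects of 0.3 log-units) and run the full pipeline:

```r
library(specdcm)

rep <- run_pipeline(list(cohort = list(n_per_group = c(5, 5, 5, 5)),
                         fit_opts = list(max_iter = 12), seed = 70))
print(rep)
#> Pipeline report
#>   cohort: 20 subjects; 40 first-level fits; mean r2 100.0%
#>   behavior: F(3, 16) = 12.66
#>   BMS: pxp(full) = 1.000, bor = 0.000
#>   PEB: 5 effects retained at pp > 0.95
#>   prediction: perf R2 0.70, age R2 0.88, QDA accuracy 70%
```

Reading the report: the 20 force traces differ by age group (one-way ANOVA
F(3, 16) = 12.66 on the −ln RMSE precision scores); the first-level fits
reproduce each subject's cross-spectra almost exactly (mean variance
explained 99.98%, printed rounded); model comparison prefers the full
network over the hidden-IPL control with protected exceedance probability
≈ 1; and the group-level search retains exactly the five planted effects:

```r
subset(rep$peb$effects, retained & !grepl("commonalities", effect))
#>                            effect  mean    sd pp retained
#> 19   performance:forward:IPL->PMv -0.27 0.047  1     TRUE
#> 25  performance:backward:PMv->IPL  0.28 0.047  1     TRUE
#> 40    age_group:backward:SMA->IPL  0.28 0.025  1     TRUE
#> 43 interaction:forward:PMv->DLPFC  0.29 0.047  1     TRUE
#> 52   interaction:backward:SMA->M1  0.32 0.047  1     TRUE
```

Each row is a regressor × connection effect in log-scaling units: e.g.
better performers have stronger backward PMv→IPL coupling (+0.28) and
weaker forward IPL→PMv coupling (−0.27), recovering the planted ±0.3.
The held-out predictions (R² = 0.70 for performance, 0.88 for age, 70%
age-group classification) close the loop from spectra back to behaviour.

Individual stages are plain functions with S3 methods:

```r
cohort <- generate_cohort(cohort_config(n_per_group = c(5, 5, 5, 5), seed = 70))
fit <- fit_dcm(cohort$spectra[[1]], cohort$model)
print(fit)
#> DCM fit (variational Laplace)
#>   F = -1139.31 nats, r2 = 100.0%, 11 iterations (converged)
coef(fit)          # 14 posterior coupling log-scalings
fitted(fit)        # predicted cross-spectra
summary(fit)       # estimates with posterior sds
```

See the vignette (`vignettes/grasping-network-dcm.Rmd`) for the model,
its assumptions, and every numerical convention.

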