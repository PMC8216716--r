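---
title: "Effective connectivity of a cortical grasping network from EEG cross-spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective connectivity of a cortical grasping network from EEG cross-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specdcm)
```

# The analysis this package implements

`specdcm` estimates directed (effective) connectivity between five cortical
sources involved in visually guided precision grip — IPL, M1, PMv, SMA and
DLPFC — from EEG cross-spectral densities, and relates the couplings to age
and motor performance across a cohort. The chain is:

1. score precision-grip force traces (`compute_precision_score`,
   `group_statistics`);
2. project multichannel EEG onto principal spatial modes and estimate
   auto-/cross-spectra over 4–48 Hz (`project_to_modes`, `estimate_csd`);
3. fit a generative neural-mass network model to each subject's spectra by
   variational Laplace (`dcm_model`, `fit_dcm`);
4. check that every source earns its place by comparing the full network
   against a control in which the IPL is a hidden source, using
   random-effects Bayesian model selection (`make_hidden_source_model`,
   `rfx_bms`);
5. aggregate the 14 extrinsic couplings across subjects with a hierarchical
   Bayesian GLM — parametric empirical Bayes with Bayesian model reduction,
   greedy search and model averaging (`fit_peb`, `greedy_search_bma`,
   `extract_subject_estimates`);
6. predict performance and age out of sample from the coupling estimates
   (`loocv_regression`, `qda_loocv`, `nir_test`).

A synthetic-cohort generator (`cohort_config`, `generate_cohort`) produces
data with exactly the statistical structure the analysis assumes, so the
whole chain can be exercised and validated end to end without any
recordings. `run_pipeline` orchestrates all stages from one configuration.

# The generative model

## Network

The a priori network (`grasping_network`) places backward (top-down)
connections DLPFC→PMv, DLPFC→SMA, PMv→M1, SMA→M1, PMv→IPL and SMA→IPL,
forward connections along the reverse edges, and reciprocal lateral
connections PMv↔SMA: 14 extrinsic couplings. Each coupling is parameterized
as a unit-less log-scaling $\theta$ of a fixed baseline (32 forward, 16
backward, 4 lateral), so effective strength is $b\,e^{\theta}$ and priors
are zero-mean Gaussians in log-space (variance 1/8).

## Neural masses

Each source is a convolution-based mass model with three populations —
spiny stellate cells, inhibitory interneurons and pyramidal cells. Every
population's postsynaptic potential obeys a second-order synaptic kernel

$$\ddot v = \frac{H}{\tau}u - \frac{2}{\tau}\dot v - \frac{1}{\tau^2}v,$$

with $\tau_e = 4$ ms, $\tau_i = 16$ ms, $H_e = 8$ mV, $H_i = 32$ mV and
intrinsic gains $\gamma = 128\,(1, 0.8, 0.25, 0.25)$ — standard constants
for this model family. The firing-rate sigmoid is replaced by its slope at
the operating point (fixed at the origin; no root-finding), making the
whole system linear. Forward afferents drive the stellate population,
backward afferents the pyramidal and inhibitory populations, lateral
afferents all three, and inter-source signals are carried by the pyramidal
depolarization.

Two implementation choices matter here:

* **State space.** We use 8 states per source and read the pyramidal
  depolarization out as the difference of the pyramidal excitatory and
  inhibitory compartment voltages. Carrying that difference as an extra
  integrated state (a common bookkeeping device) creates an exact linear
  redundancy — a structural zero eigenvalue that is neither controllable
  nor observable — which would falsely fail a strict `Re(eig) < 0`
  stability test on every model.
* **Operating-point slope.** The default slope is 0.125. A stability scan
  showed the coupled default network must remain strictly stable with
  margin for coupling excursions of at least ±1 log-unit (at slope 0.25 the
  default network is already unstable). The slope only rescales effective
  gains, so this is a parameterization convention, not a scientific claim.

## Spectra

With Jacobian $J$, innovation input map $B$ and read-out $C$, the transfer
function is $T(f) = C\,(2\pi i f I - J)^{-1} B$ (a direct resolvent solve
per 1-Hz bin, implemented in compiled code), and the predicted mode-level
cross-spectrum is

$$G(f) = L\,T(f)\,G_u(f)\,T(f)^{H}L^{H} + G_n(f),$$

where $L$ is the lead field, $G_u$ the diagonal innovation spectrum with
power-law form $\exp(a_1)\,f^{-\exp(a_2)}$ per source, and $G_n$
mode-specific plus common observation-noise terms of the same form. The
innovation exponent prior is set to $a_2 = -32$, i.e. a flat innovation
spectrum ($f^{-e^{-32}} \approx f^0$), appropriate for task data whose
spectra need not follow the 1/f form assumed for resting state. The
observation-noise floor defaults to $\exp(-16)$, several orders of
magnitude below the model's natural output scale, so it regularizes
without influencing fits.

The lead field is a seeded random mixing with unit column norms — a
synthetic, configurable stand-in for a boundary-element head model, which
is out of scope. `simulate` draws stationary time series whose spectrum
equals the predicted CSD exactly (spectral synthesis on the discrete
Fourier grid), used to cross-validate the analytic spectra against Welch
estimates.

# Subject-level inversion

`fit_dcm` maximizes the Laplace free energy

$$F = \underbrace{\mathbb{E}_q[\log p(y\mid\theta,\lambda)]}_{\text{accuracy}}
 - \underbrace{KL[q(\theta)\,\|\,p(\theta)] + KL[q(\lambda)\,\|\,p(\lambda)]}_{\text{complexity}}$$

over a Gaussian belief $q(\theta)$ on the free parameters (14 coupling
log-scalings plus the innovation log-amplitude) and a single log-precision
$\lambda$ for the residuals. Residuals stack the real parts of the upper
triangle (with diagonal) and imaginary parts of the strict upper triangle
of every frequency bin; diagonal imaginary parts are identically zero and
dropped. Observed spectra are scale-normalized to unit mean diagonal power
and the innovation amplitude anchored so the prior-mean prediction matches
that scale — free energies remain comparable across models fitted to the
same data.

The ascent is Gauss–Newton with Levenberg–Marquardt damping, alternating
parameter and log-precision updates (the $\lambda$ step is a damped Newton
on a strictly concave 1-D objective). A candidate step is accepted only if
the free energy — evaluated with a fresh Jacobian at the candidate —
increases; otherwise the damping doubles. The recorded free-energy trace is
therefore monotone by construction. Convergence is declared after four
consecutive improvements below 0.01 nats (or when no admissible step
remains), with a 64-iteration default cap. Proposals whose linearization is
unstable (any eigenvalue with non-negative real part) are rejected and
damped, never evaluated.

**Jacobians.** The derivative of the predicted spectra with respect to each
coupling is computed analytically: each coupling perturbs the state
Jacobian sparsely ($dJ$ has a handful of entries), and
$d(L C R B) = (L C R)\,dJ\,(R B)$ with $R$ the resolvent. This is exact and
roughly twenty times faster than numerical differentiation, which matters
at cohort scale; a central finite-difference path is retained
(`opts = list(jacobian = "fd")`) and the test suite asserts the two agree
to $10^{-6}$.

**Hyperpriors.** The log-precision prior is $\lambda \sim N(h_E, h_C)$ with
$h_E = 18$ — deliberately high, to avoid premature convergence early in
the ascent, a known failure mode for nonlinear electrophysiological
models — and $h_C = 1/128$. A consequence worth stating plainly: the
Laplace posterior over parameters is **overconfident**. With a single
precision component the posterior covariance cannot represent
heteroscedastic, structured residual noise, and empirically the 90%
credible intervals cover the true couplings far less than nominally
(~30% elementwise in our recovery simulations) even though point recovery
is excellent (errors of 0.03–0.07 log-units at low noise, perfect sign
recovery). Inference about effects should therefore be read from the
group level (PEB posterior probabilities, which behave well in recovery
simulations), not from subject-level credible intervals.

Model fit is summarized as variance explained,
$100\,(1 - SS_{res}/SS_{tot})$ over the concatenated real and imaginary
parts of all bins and mode pairs, with the uncentered total sum of squares
(so a zero prediction scores 0%).

# Model comparison across subjects

`rfx_bms` treats the model identity as a random effect with a Dirichlet
prior over model frequencies (uniform counts 1). The variational scheme
iterates subject responsibilities (log-sum-exp normalized) and Dirichlet
counts to convergence. Exceedance probabilities use the exact Beta tail
integral for two models and seeded Monte-Carlo Dirichlet sampling (default
$10^6$ draws) otherwise. The Bayes omnibus risk compares the free energy
of the random-effects model against a null in which all models are equally
frequent, $bor = 1/(1 + e^{F_1 - F_0})$, and the protected exceedance
probability is $pxp = (1 - bor)\,xp + bor/K$. Reported probabilities are
never rounded.

# Group level: PEB, BMR, model averaging

The second level is a Bayesian GLM over the subjects' coupling posteriors:
$\theta_i = X_i\beta + \varepsilon_i$ with isotropic random effects of log
precision $\gamma$. The design matrix (`build_design_matrix`) has columns
intercept, mean-centred performance, mean-centred ordinal age-group code
(1–4), and the mean-centred product of the two centred columns. Age enters
as one ordinal column by default — the analysis reports a single group
effect per connection, which is consistent with that coding — and a dummy
coding is available by flag.

Candidate $(\beta, \gamma)$ are scored *without revisiting any spectra*:
Bayesian model reduction (`bmr`) turns each subject's first-level posterior
into the evidence change under the implied empirical prior
$N(X_i\beta,\, e^{-\gamma} I)$. Two structural facts make the fit fast and
exact:

* given $\gamma$, the summed evidence is an exact quadratic in $\beta$, so
  the $\beta$ update is closed-form (and its Gaussian integral gives the
  $\beta$-marginalized free energy in closed form);
* $\gamma$ is a scalar, updated by damped Newton with explicit
  accept/reject, so the second-level free energy is monotone over accepted
  iterations.

The $\beta$ prior is zero-mean with variance 1/8 per effect (matching the
first-level coupling priors); the random-effects log-precision hyperprior
is $N(4, 1/64)$.

`greedy_search_bma` searches nested models that switch effects off by
shrinking their prior variance to $10^{-8}$. With at most 8 candidate
effects the search enumerates all on/off combinations exactly; otherwise it
scores every remaining effect by its single-removal evidence change,
exhaustively searches the 8 least-contributing, permanently prunes the
effects switched off in the best model, and repeats until nothing more is
pruned. The final model set is averaged with softmax weights on their
evidences (models more than 20 nats below the best are dropped as
numerically weightless); an effect's posterior probability is the summed
weight of models containing it, and effects with $pp > 0.95$ (strictly)
are retained.

`extract_subject_estimates` re-evaluates each subject's couplings under the
group-level empirical prior. The contract is fixed by its limits — as the
between-subject variance grows the estimates must tend to the first-level
means, and as it vanishes to the group prediction $X_i\beta$ — which
identifies the update as the precision-weighted combination of the
first-level posterior with the empirical prior:
$(\Sigma_i^{-1} + e^{\gamma} I)^{-1}(\Sigma_i^{-1}\mu_i + e^{\gamma} X_i\beta)$.

# Prediction

`loocv_regression` refits an ordinary least-squares regression $n$ times,
predicting each held-out subject; it reports the held-out RMSE and both
$R^2$ conventions (squared correlation of predicted versus observed, the
primary one, and $1 - SSE/SST$, which can be negative out of sample).
`qda_loocv` uses class-conditional Gaussians with class-specific
covariances, shrinkage-regularized by $10^{-6}\,\mathrm{tr}(\Sigma_k)/p$ on
the diagonal (class sizes of ~20 against 14 features are near-singular),
priors equal to training class frequencies, an exact Clopper–Pearson 95%
interval on accuracy, and a one-sided exact binomial test against the
no-information rate (the largest class share).

# The synthetic cohort

`cohort_config` defaults encode the study conditions: four age groups of
22, 19, 19 and 28 subjects (labels 8–10, 12–14, 16–18, 20–30 years);
couplings drawn from the second-level GLM with planted effects of
magnitude 0.3 — performance raising backward PMv→IPL and lowering forward
IPL→PMv coupling, age raising backward SMA→IPL, and age-by-performance
interactions on forward PMv→DLPFC and backward SMA→M1, mirroring the kind
of effects the analysis is meant to detect; between-subject coupling
standard deviation 0.05; spectra over 4–48 Hz from the generative model.

Values the study does not fix are chosen once as plausible conventions:
performance scores (the negative log tracking error in newtons) have group
means 0.4, 0.7, 0.8, 1.1 — adults best — with within-group SD 0.3 around a
10% target of a 60 N maximal voluntary contraction; ages are uniform in
each group's range; force traces are 120 s at 100 samples/s of
half-pink/half-white noise around the target line, rescaled so the
trace's RMSE reproduces the subject's planted score exactly (a round-trip
the tests assert).

Spectral observation noise is a *centered* complex Wishart-type
perturbation in mode space, scaled to a fraction (default 0.02) of the
mean diagonal power, with eigenvalues clipped at zero so every bin remains
a valid PSD matrix. Centering matters: the estimation error of sample
cross-spectra is zero-mean around the true spectrum, whereas an
uncentered Wishart term adds a systematic power offset that the fits
correctly absorb into coupling means — contaminating the group-level
commonalities with artefactual "effects". All randomness derives from the
single cohort seed via fixed per-subject sub-seeds, so any subject is
reproducible in isolation and cohorts are byte-identical across runs.

What the generator deliberately does **not** emulate: volume conduction
and realistic scalp topographies (the lead field is synthetic), artifacts
(blinks, EMG), non-stationarity within the recording, and model mismatch —
the data are generated by the same model family that is fitted. Passing
recovery tests therefore demonstrates the correctness and calibration of
the inference machinery, not robustness of the model class to real EEG.

# Problem sizes and numerical choices

The test-suite simulations run at desk scale, chosen so the full suite
completes in a few minutes: recovery simulations use 10 cohorts of 40
subjects (10 per group) with first-level fits capped at 12 iterations
(convergence is typically reached near that point on synthetic data, and
group-level recovery is unchanged at higher caps); the model-comparison
analog uses 16 subjects and both models; the variance-explained analog a
12-subject low-noise cohort. Other conventions: finite-difference step
$10^{-3}$ in log-scaling units where numerical Jacobians are requested;
damping halves on accepted and doubles on rejected steps; ties in the
greedy search's single-removal ranking resolve by the fixed
regressor-major effect order; Monte-Carlo exceedance probabilities use
$10^6$ seeded draws; BMS responsibilities are normalized with log-sum-exp.
Degenerate inputs (empty traces, zero tracking error, empty frequency
bands, non-PSD beliefs, unstable autoregressions, groups with fewer than
two members, improper prior reductions) raise errors rather than
propagating silently.

# Known limitations

* Subject-level credible intervals are overconfident (see above); use the
  group level for inference.
* The spectral estimator for analysis is an ordinary least-squares vector
  autoregression (default order 8); the Bayesian autoregressive estimator
  sometimes used for this purpose is not specified precisely enough to
  reproduce, and at these data lengths the two agree within sampling error
  (a property the tests check against Welch estimates).
* The paper-reported pairwise t-test degrees of freedom are internally
  inconsistent with pooled two-sample tests at the stated group sizes; the
  package reports classic pooled-variance tests with their exact degrees
  of freedom.
* Replication targets that require the article's deposited source data
  (group ANOVA F, LOOCV $R^2$/RMSE, QDA accuracy on the real cohort) are
  supported by the same functions but need those CSVs as input.
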