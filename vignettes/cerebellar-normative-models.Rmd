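---
title: "Methods: normative cerebellar growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative cerebellar growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cerebnorm)
```

This vignette records the model, the numerical choices, and the design
decisions behind `cerebnorm`, in the spirit of the methods sections of
mature modelling packages. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model

For one region of interest (ROI) with measure $y_i$ on scan $i$:

$$y_i \sim \mathrm{SHASHb}(\mu_i,\ \sigma_{b(i)},\ \epsilon,\ \delta),
\qquad
\mu_i = \alpha_{b(i)} + \sum_k \beta_{b(i),k}\, \mathrm{basis}_k(\mathrm{age}_i),$$

where $b(i)$ is the scan's *batch cell* — one level of the crossed
sex × scanner factor. Intercepts $\alpha_b$, slopes $\beta_b$ and the
(softplus-transformed) scale parameters $s_b$ are drawn per cell from
shared Normal hyperpriors, so all cells are partially pooled; the skew
$\epsilon$ and tail weight $\delta$ are global per ROI, because batch
effects on distributional *shape* have no support in the data sizes
this model targets.

The SHASHb family is the standardized sinh-arcsinh distribution: with
$S = \sinh\!\big((\mathrm{asinh}(Z)+\epsilon)/\delta\big)$, $Z$
standard normal, the response is
$Y = \mu + \sigma\,(S - m_{\epsilon,\delta})/\sqrt{v_{\epsilon,\delta}}$
with the base moments

$$m = \sinh(\epsilon/\delta)\,P(1/\delta), \qquad
  v = \tfrac12\big(\cosh(2\epsilon/\delta)P(2/\delta) - 1\big) - m^2,$$

$$P(q) = \frac{e^{1/4}}{\sqrt{8\pi}}
  \Big[K_{(q+1)/2}\!\big(\tfrac14\big) +
       K_{(q-1)/2}\!\big(\tfrac14\big)\Big],$$

$K$ the modified Bessel function of the second kind. Standardizing the
base variate keeps $\mu$ and $\sigma$ interpretable as location and
scale for any shape; $\epsilon = 0, \delta = 1$ gives exactly
$\mathcal N(\mu, \sigma^2)$. Sign convention, stated explicitly because
the literature varies: positive $\epsilon$ produces positive skew.

**Deviation scores.** A held-out scan is scored as
$z = \Phi^{-1}\!\big(F_{\mathrm{SHASHb}}(y;\hat\mu_i, \hat\sigma_b,
\hat\epsilon, \hat\delta)\big)$ at plug-in posterior means of its own
batch cell. Under the model this is exactly standard normal in every
cell — the z-scores are batch-free by construction — and it reduces to
$(y-\mu)/\sigma$ in the Gaussian case. The CDF route (not the raw
standardized residual) is what keeps "2.5% beyond ±1.96" true under
skewed likelihoods. Draw-averaged scoring is available
(`method = "draws"`); at the training sizes of interest the two agree
closely because parameter uncertainty is small relative to residual
spread, and plug-in is the default.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_chains`, `n_samples`, `n_tune` | 4, 2000, 500 | draws | the study protocol; 6000 retained draws |
| basis | linear | — | linear and 5-knot cubic B-spline fit this age range equally well by LOO; linear is the parsimonious default |
| `n_knots` | 5 | — | "evenly spaced" knots over the training range; the count includes the boundary knots by default (`boundary_in_count`), both readings supported |
| hyper-means | $\mathcal N(0,1)$ | std. units | weakly informative on z-scored response/age |
| hyper-scales | Half-Normal(1) | std. units | same |
| $\epsilon$ prior | $\mathcal N(0,1)$ | — | generous for morphometric skew |
| $\delta$ | softplus-linked, mode 1 | — | $\delta_{raw}=0 \Rightarrow \delta = 1$: centered on Gaussian tails |
| `target_accept` | 0.9 | — | see "Sampler" below |
| `traj_len` | 3.0 | mass-std. units | trajectory length; shorter values leave the correlated hyper-scale/shape block under-mixed at 2-chain test settings |
| z threshold | 1.96 | — | two-sided 95% normal bound; configurable |
| binomial $p_0$, $\alpha$ | 0.025, 0.05 | — | each tail of ±1.96 under calibration |

Responses are z-scored on the *training* half only; the basis records
the training age mean/sd and range, so test-time design matrices are
bit-compatible with training. Slope coefficients on these scales are
the "standardized age betas" used by the gradient analysis.

## The sampler

No MCMC engine of the Stan/PyMC class is available in the target
environment, so `src/hbr_sampler.cpp` implements adaptive Hamiltonian
Monte Carlo with analytic gradients of the full log-posterior
(finite differences are used only for the $\partial(m,v)/\partial
(\epsilon,\delta)$ of the data-independent Bessel moments). Warmup uses
dual averaging toward the acceptance target, one variance-estimation
window (25%–75% of warmup) for a diagonal mass matrix with Stan-style
shrinkage toward unit mass, and a fresh step-size search under the new
metric; trajectory lengths are jittered uniformly up to
`traj_len`/stepsize. Divergent trajectories (non-finite or exploding
Hamiltonian) are rejected and counted; a fit with more than 5%
post-warmup divergences is flagged and warned about.

Choices found necessary in practice, kept as defaults:

- **Non-centered parameterization** (default): with only 4 batch cells
  the hyper-scales are weakly identified; non-centered sampling shows
  zero divergences on well-specified data while the centered variant
  funnels (2–3% divergences). The centered form remains available.
- **`target_accept = 0.9`**: at 0.8 the post-mass-update re-adaptation
  occasionally lands a chain at a too-large step size (acceptance
  0.2–0.6, ~10% divergences). 0.9 eliminated this across seeds at ~15%
  extra cost.
- **$\delta$ floor at $10^{-3}$** inside the sampler: the Bessel order
  in the moment functions is $\approx 2/\delta$, and R's `bessel_k`
  allocates workspace proportional to the order — a warmup excursion to
  tiny $\delta$ would otherwise request gigabytes. Such proposals are
  treated as divergent. The same floor guards `shash_moments()`.
- Degenerate AP trend fits (perfect lines or constant values) return
  $t = \pm\infty$ or $t = 0$ with $p \in \{0, 1\}$ instead of `NaN`.

R-hat is the split rank-normalized statistic with the folded variant
(maximum of the two), computed on the *transformed* interpretable
parameters (per-cell $\alpha$, $\beta$, $\sigma$; hyper-means/-scales;
$\epsilon$, $\delta$). LOO is Pareto-smoothed importance sampling with
the Zhang–Stephens generalized-Pareto tail fit, computed on the
training scans (the source protocol does not say which split was used;
training scans are the ones both models always share).

## The synthetic cohort

The generator reproduces the statistical structure the analysis
assumes, with defaults fixed at the published cohort design: three
waves with mean ages 7.9/10.1/14.0 years and hard age ranges
[6.1, 10.7], [8.6, 12.0], [12.6, 17.1] (truncated-normal within-wave
ages; SDs 1.0/0.6/0.8 y chosen once so the truncated draws match the
printed means and ranges); 56.2%/38.0%/5.8% of subjects measured
once/twice/three times; ~50.6% female; wave 1 on one scanner and waves
2–3 on its successor, so scanner is deterministically confounded with
wave.

Visit patterns are not published beyond those marginals. Decisions,
made once: three-visit subjects attend all waves; two-visit subjects
attend waves {2,3} with probability 0.8, else {1,2}; single-visit
subjects are allocated to waves with probabilities (0.12, 0.60, 0.28),
obtained by solving the printed per-wave scan counts (974/3785/2511)
against the other patterns. Measures follow
`intercept_b + slope_b · age_std + scale_b · S` with a standardized
SHASHb residual `S`; `example_roi_models()` defaults (males +0.5
measure units, later scanner +0.3, slope 0.25 per SD of age, scale 1.2,
$\epsilon = 0.1$, $\delta = 1.05$) give standardized age betas near
0.2 and mild skew, the regime the real analysis reports. Age is
standardized by the generated cohort's own mean/sd, mirroring how
standardized coefficients are reported.

What the generator does **not** emulate: attrition/non-response
structure, image-level artifacts and QC exclusions, spatially
correlated residuals across ROIs (ROIs are generated independently),
and non-linear growth. A green calibration test therefore establishes
that the pipeline is correct *under its own assumptions*, not that real
cerebellar data meet them.

## Analysis-stage decisions

- **Train/test split**: 50/50 at the *subject* level, stratified on sex
  × the subject's scanner set. Stricter than splitting scans, which
  would leak longitudinal information between halves.
- **AP gradient families**: vermal volumes; hemispheric volumes
  averaged left/right per lobule (posterior-mean slopes are averaged;
  whether averaging preceded posterior summarization in the source is
  unstated); functional volumes; GMD; WMD — each per sex. AP position
  enters as unit-spaced integer rank; inter-lobular spacing is
  acknowledged ambiguous upstream and alternative spacings can be
  passed by editing the rank column.
- **FDR family**: all family × sex tests jointly (10 in the canonical
  layout). This is the only reading that reproduces every published
  adjusted p-value, verified arithmetically in the suite
  (e.g. 0.019·10/6 → 0.032, 0.036·10/7 → 0.051, 0.060·10/8 → 0.075).
  A "below 0.001" raw value occupies rank 1 and leaves the other
  adjusted values unchanged anywhere ≤ 0.001.
- **Group comparisons count individuals, not scans**: subjects with
  several scans contribute their *latest* scan per ROI by default
  (configurable to earliest or mean-z); the upstream analysis counts
  "participants" without stating the rule.
- **Strict inequality** in the critical percentage
  ($P(X \ge k^*) < \alpha$): the only convention that reproduces both
  published thresholds, 63/2012 = 3.13% and 10/198 = 5.05%.
- **Tails tested separately** (negative and positive), each against
  $p_0 = 0.025$, one-sided.

## Numerical details

- CDF values are clamped to $[10^{-15}, 1-10^{-15}]$ before the normal
  quantile, so z-scores are always finite.
- Ages outside the training range are clamped to the boundary for
  basis evaluation and flagged (`clamped` attribute); the model is
  never extrapolated.
- The cubic-spline design keeps the full B-spline basis plus an
  explicit intercept column. The resulting rank deficiency (partition
  of unity) is deliberate — the hierarchical Normal priors make the
  posterior proper and predictions identified; only the
  intercept/spline-coefficient decomposition is soft.
- `compare_loo()` declares models "equal" when
  $|\Delta\mathrm{elpd}| \le 2\,\mathrm{SE}$; identical fits give an
  exact zero.
- Seeds: every stochastic stage takes an explicit seed;
  `run_pipeline()` derives per-ROI sampler seeds from the single
  pipeline seed, and the cohort TSV header records the generator seed.

## Scaled-down testing and known limitations

Unit tests run the sampler at 2 chains × 700 samples on cohorts of
200–1000 subjects to stay within CI budgets; the acceptance criteria
for calibration and convergence run the full 4 × 2000 protocol. The
held-out tail-calibration check pools three independent
cohort-fit replicates: a single ~1100-scan test half carries roughly
±0.6 percentage points of binomial-plus-estimation noise per tail,
which would make a one-seed check of a ±0.7-point band close to a coin
flip; pooling estimates the same quantity with three times less
variance.

Limitations: the sampler is single-threaded and fixed-trajectory
(jittered HMC, not U-turn-adaptive); no federated prior transfer to
new sites; no within-subject longitudinal change statistics; ROI
residuals are modelled independently; the generator's linear growth
means spline-vs-linear LOO comparisons on synthetic data are
equivalence checks, not evidence about real growth curvature.
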