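---
title: "Nucleation-and-growth modelling of single-cell cancer transformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation-and-growth modelling of single-cell cancer transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avramicarc)
```

## The model

Carcinogenesis is classically described by multi-hit models: a cell
transforms after it has accumulated some number (typically two to eight) of
mutations in driver genes. `avramicarc` treats this process *volumetrically*,
as a phase transition of the DNA molecule described by nucleation-and-growth
(Johnson–Mehl–Avrami–Kolmogorov, JMAK) kinetics.

The ingredients:

* The DNA molecule occupies a volume $V$ (arbitrary units). Proto-oncogenes
  (driver genes) are scattered through it; of roughly 20,000 human genes, 299
  are drivers, so a uniformly placed mutation is oncogenic with probability
  $\mu = 299/20000 \approx 0.015$.
* A mutated oncogene is a *cancer cluster*: a transformed nucleus of volume
  $V_n = \beta\,m^{\xi}$ that grows as the cell's oncogenic mutation count
  $m$ rises ($\beta$, $\xi$ constants). Each oncogenic mutation nucleates new
  clusters at rate $N'V$ per mutation.
* The cell counts as neoplastically transformed when the aggregate cluster
  volume $V_{N,\mathrm{tot}} = \sum_n V_n$ reaches an effective threshold
  $V_T \ll V$.

### Closed forms

For $M$ total mutations landing uniformly in $V$, the probability that at
least one falls inside the threshold volume is the binomial complement

$$p = 1 - \left(1 - \tfrac{V_T}{V}\right)^{M},$$

which for $V_T \ll V$ becomes the exponential form
$p(m) = 1 - e^{-(V_T/V)\,m/\mu}$ with $m = \mu M$ the oncogenic count
(`oncogenic_hit_probability_sum()`, `_exact()`, `_approx()`). The package
keeps the literal binomial sum for $M \le 30$ and switches to the
log-space complement beyond that — the two are identical by the binomial
normalisation identity, but factorials overflow while `M * log1p(-r)` does
not.

### The Avrami law and the critical index

Integrating the cluster-volume increment
$\mathrm{d}V_{N,\mathrm{tot}} = \beta m^{\xi} N' V\,\mathrm{d}m$ gives the
aggregate growth law

$$V_{N,\mathrm{tot}}(m) = \frac{\beta N'}{\xi + 1}\, V\, m^{\xi+1},$$

(the prefactor is exposed as `growth_law_constant()`). Substituting this
growing volume for $V_T$ in the exponential hit formula composes the two
mechanisms — every one of the $M = m/\mu$ mutations is a potential hit on a
target that itself grows with $m$ — and yields the Avrami sigmoid

$$P(m) = 1 - e^{-\alpha m^{k}}, \qquad k = \xi + 2,$$

with $\alpha = \beta N' / ((\xi+1)\,\mu)$ under this composition. The
critical index $k$ therefore reports the dimensionality of cluster growth:
three-dimensional growth ($\xi = 2$) gives $k = 4$, and fitted $k > 4$ is
read as fractal DNA geometry. For cohort data the probability is rescaled to
a risk $P(m) = C\,(1 - e^{-\alpha m^k})$, where $C$ is in the cohort's
case-count units.

Ages are mapped to mean oncogenic mutation counts linearly,
$m = 0.053 \times \mathrm{age}$ for gastric tissue by default. The rate is a
parameter (`rate`) because it is tissue-specific, measured data rather than
a constant of the model.

## The Monte Carlo simulator

`estimate_curve()` simulates cells mutation by mutation: each mutation is
oncogenic with probability $\mu$; each oncogenic mutation nucleates
$\mathrm{Poisson}(N'V)$ clusters "marked" with the oncogenic count at their
birth; a cluster born at count $i$ has volume $\beta (m - i)^{\xi}$ once the
count reaches $m$. Two transformation mechanisms are available:

* **composition** (default): each of the $M$ accumulated mutations is an
  independent Bernoulli hit on the transformed volume fraction
  $V_{N,\mathrm{tot}}/V$; the cell transforms when at least one hits. This
  is the composition that provably reproduces $k = \xi + 2$, and it is the
  reading consistent with substituting the growth law into the exponential
  hit formula. (A stricter incremental reading — integrating each
  mutation's hit chance against the volume at its own arrival time — gives
  the same $m^{\xi+2}$ exponent but a different prefactor,
  $\alpha = \beta N' / ((\xi+1)(\xi+2)\mu)$; the package implements the
  substitution form, whose prefactor matches the closed-form model above.)
* **threshold**: the cell transforms exactly when
  $V_{N,\mathrm{tot}} \ge V_T$. This literal crossing rule produces a
  sharper sigmoid that is *not* exactly Avrami-shaped; both mechanisms are
  kept because the model's derivation uses the composition while its
  verbal statement uses the threshold, and no attempt is made here to
  reconcile the two.

Design choices worth knowing:

* **Growth reading.** $V_n = \beta m^{\xi}$ does not say whether $m$ counts
  from nucleation or globally. The default is growth since nucleation,
  $\beta(m - m_{\mathrm{nuc}})^{\xi}$, which is the Avrami-faithful
  reading; the `"snapshot"` alternative ($\beta m^{\xi}$ for every cluster)
  is available for comparison. Both aggregate to the same $m^{\xi+1}$
  ensemble scaling.
* **Overlaps.** The aggregate volume is a plain sum over clusters, not a
  geometric union: with $V_T \ll V$ overlaps are negligible, and the
  integral growth law is itself a sum. No spatial placement is simulated —
  the model's mathematics never uses cluster positions.
* **Stochastic nucleation.** The nucleation relation $N = N'V\,\Delta m$ is
  deterministic on its face; the simulator draws
  $\mathrm{Poisson}(N'V)$ so cells vary, and recovers the deterministic
  limit as $N'V$ grows.
* **Vectorisation.** The per-cell stepper (`step_mutation()`,
  `transformation_outcome()`) is the readable reference; `estimate_curve()`
  draws the identical distributions vectorised over cells (Poisson cluster
  counts per step; a negative-binomial total mutation count at the grid
  point; Bernoulli hits). One seeded base-R stream drives each run, saved
  and restored around it; there is no parallel execution.
* **Discreteness.** The simulator lives on integer $m$, so the empirical
  Avrami slope carries a finite-size correction of order $+1/m$ relative to
  the continuum exponent $\xi + 2$ over the practical fitting window
  ($m \approx 5$–$12$); partially offsetting it, averaging over the
  random total mutation count bends the upper tail down. Both effects are
  visible at the default scales and stay well inside the $\pm 0.25$
  tolerance used for the critical-index checks.

Default scales (`genome_geometry()`, `cluster_dynamics()`): $V = 1$,
$V_T = 10^{-3}$, $\mu = 0.015$, $\xi = 2$, $N' = 50$,
$\beta = 1.9\times 10^{-7}$. Volumes are arbitrary units; $\beta$ and $N'$
were chosen once so that the median transformation falls near $m = 8$ —
inside the observable 5–10 window, with $V_{N,\mathrm{tot}} \approx V_T$ at
the median, which is the regime the model describes.

```{r simulator}
geom <- genome_geometry()
dyn <- cluster_dynamics()
curve <- estimate_curve(geom, dyn, m_grid = 3:14, n_cells = 2000, seed = 42)
avrami_plot_slope(curve)
```

## The Avrami-plot slope estimator

`avrami_plot_slope()` regresses $\ln(-\ln(1 - \hat p))$ on $\ln m$ by
unweighted OLS. Points with $\hat p$ outside $(0.05, 0.95)$ are discarded
first — the double-log transform amplifies binomial noise without bound at
both tails — and at least four points must survive (standard Avrami-plot
practice; the bounds are exposed as `p_range`). On a noiseless curve the
slope and intercept reproduce $k$ and $\ln\alpha$ to numerical precision.

## Fitting cohort data

`fit_avrami()` minimises
$\sum_i w_i\,\big(y_i - C(1 - e^{-\alpha m_i^k})\big)^2$ with any subset of
$(\alpha, k, C)$ held fixed. Numerical choices:

* **Parameterisation.** The optimiser works on
  $(\log\alpha,\; k,\; \log C)$ with box constraints
  $k \in [0.5, 10]$. $\alpha$ and $k$ trade off strongly (raising $k$ is
  almost compensated by lowering $\alpha$ over a narrow $m$ window — the
  same compensation visible in fixed-$k$ profiles), and the log scale makes
  that valley tractable.
* **Multi-start.** Levenberg–Marquardt (`minpack.lm::nls.lm`, tight
  `ftol`/`ptol` so exact data are recovered to machine precision) from a
  deterministic $3\times3\times3$ grid centred on data-driven guesses:
  $C_0$ just above the largest response, $k_0 = 4$, $\log\alpha_0$ from the
  Avrami-plot intercept at $k_0$. The best converged start wins.
* **Loss.** Unweighted least squares on the cumulative responses by
  default, matching how such registry curves are usually fitted; a
  Poisson-deviance loss (`loss = "poisson"`) is available when responses
  are raw counts. Cumulative tables are fitted as given — no decumulation.
* **Degenerate input.** All-zero responses are rejected ($C \to 0$ is a
  boundary, not a fit); fewer than four distinct mutation counts, or fewer
  points than free parameters plus one, are errors.

`profile_k()` refits once per value of a $k$ grid and reports
$(k, \hat\alpha, \hat C, \mathrm{RSS})$; model selection among the profiled
fits is left to the user, since visual fit quality and RSS can disagree.
`bootstrap_ci()` provides case-resampling percentile intervals — case
rather than residual resampling because cohort tables are small sets of
cumulative counts of heterogeneous precision; each resample refit starts
from the point estimate, and more than 20% failed refits aborts with an
error rather than returning intervals from a biased subset.

```{r fit}
params <- avrami_params(alpha = 0.0087, k = 4.4, scale = 155)
co <- generate_cohort(params, noise_sd = 2, seed = 1)
fit <- fit_avrami(co)
summary(fit)
profile_k(co, k_grid = seq(4.0, 4.4, by = 0.1), fix_scale = 155)
```

The *effective threshold* of transformation is reported three ways
(`effective_threshold()`): the density mode (most probable transformation
count — the closed form $((k-1)/(\alpha k))^{1/k}$, degenerate at 0 with a
warning for $k \le 1$) and the central 5–95% interval. The sigmoid's
location and width both depend on $\alpha$ and $k$ jointly, so no single
number is privileged. Under the fixed $k = 4$, $\alpha = 0.0133$ gastric
fit the mode sits at $\approx 2.74$ oncogenic mutations — between two and
four, consistent with experimental multi-hit counts.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure of a registry-derived
cumulative-incidence table: 12 age points spanning 30–85 years (the span
over which gastric cumulative incidence is informative), converted to
mutation counts at 0.053/year, with the Avrami risk as the mean response.
Noise is additive Gaussian on the cumulative counts by default (the error
structure of digitised registry tables is unknown, and Gaussian is the
neutral choice); `noise = "poisson_increment"` draws Poisson counts on the
per-age-band increments and re-accumulates, which is closer to how a
registry accrues cases and guarantees integer, nondecreasing responses.
The default noise level in the package's own checks is `noise_sd = 2`
cases against $C = 155$ — a 1–3% relative error, the magnitude of
digitisation scatter.

What the generator does *not* emulate: inter-individual variation in
mutation rate (one shared age-to-mutation slope), age-band widths and
censoring, and any misreporting structure. Parameter-recovery and coverage
results on these cohorts therefore show the estimator works when the model
and conversion are correct, not that the model is correct for any given
registry.

## Problem sizes and determinism

Every stochastic function takes a `seed` and is bit-reproducible; seeded
calls restore the caller's RNG state. The package's own checks run at:
10,000 cells per grid point on 12-point grids for the critical-index
checks (where the recovered slope must land within $\pm 0.25$ of
$\xi + 2$); 5,000–10,000 replicates for ensemble means; 100 synthetic
cohorts for parameter recovery (median relative error under 15% at
`noise_sd = 2`); and 50 replicates of 1,000-resample bootstraps for
interval coverage (accepted within $[0.85, 1]$ at nominal 0.95). These
sizes keep each Monte Carlo standard error a few times smaller than the
tolerance it is checked against.

## Known limitations

* The model stops at the transformation of a single cell: tumour growth,
  selection and clonal dynamics after transformation are out of scope.
* Hits are uniform over the DNA volume; per-gene heterogeneity and repair
  kinetics are not modelled.
* The threshold mechanism and the composition mechanism are both offered
  but disagree in shape; the model's own derivation effectively uses the
  composition, and the package does not arbitrate further.
* The age conversion is linear with a tissue-specific slope; tissues where
  mutation burden accumulates non-linearly need their own conversion
  before fitting on the age axis.
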