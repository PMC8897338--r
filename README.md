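# avramicarc

Volumetric multi-hit modelling of single-cell cancer (neoplastic)
transformation with nucleation-and-growth — Avrami/JMAK — kinetics.

Multi-hit models say a cell transforms after accumulating several driver
(oncogenic) mutations. `avramicarc` treats that process volumetrically: the
DNA molecule is a volume *V* in which mutations land uniformly; mutated
oncogenes are *cancer clusters* of volume *V<sub>n</sub> = β m<sup>ξ</sup>*
that nucleate (at rate *N′V* per oncogenic mutation) and grow with the
oncogenic mutation count *m*; the cell transforms when the aggregate cluster
volume reaches an effective threshold *V<sub>T</sub> ≪ V*. Composing cluster
growth with the multi-hit probability yields the Avrami transformation law

> P(m) = 1 − exp(−α m<sup>k</sup>),  k = ξ + 2,

and, scaled by a factor *C* into cohort units, the risk function
*P(m) = C (1 − exp(−α m<sup>k</sup>))* that can be fitted to cumulative
cancer-incidence tables, with ages converted to mean oncogenic mutation
counts at a linear rate (0.053 mutations/cell/year for gastric tissue). The
critical index *k* reflects the dimensionality of cluster growth: *k = 4*
corresponds to three-dimensional growth, and fitted *k* > 4 suggests
fractal DNA geometry.

The package is aimed at modellers in cancer biophysics and radiation
biology who want to (a) evaluate the closed-form multi-hit and Avrami
probabilities, (b) check by simulation that the critical index *k = ξ + 2*
emerges from cluster nucleation and growth, and (c) fit the
three-parameter risk curve to registry-style cohort data with fixed-*k*
profiling and bootstrap uncertainty.

## Worked example

Generate a synthetic 12-point gastric-style cohort from the risk curve with
α = 0.0087, k = 4.4, C = 155 (ages 30–85, mutation rate 0.053/year,
Gaussian noise of 2 cases), fit it, and profile over fixed *k*:

```r
library(avramicarc)

params <- avrami_params(alpha = 0.0087, k = 4.4, scale = 155)
co <- generate_cohort(params, noise_sd = 2, seed = 1)
fit <- fit_avrami(co)
summary(fit)
#> Avrami risk-curve fit: y = C (1 - exp(-alpha m^k))
#>   alpha = 0.0087316
#>   k     = 4.3903
#>   scale = 156.31
#>   RSS = 25.537 on 12 points
#>   residual SD = 1.6845
#>   effective threshold: mode 2.78 mutations, central 90% in [1.5, 3.78]
```

The fit recovers the generating parameters (α within 0.4%, *k* within
0.3%), and the effective-threshold report says transformations are most
likely at ≈ 2.8 oncogenic mutations. Bootstrap intervals and the fixed-*k*
profile:

```r
round(bootstrap_ci(NULL, fit, n_boot = 1000, seed = 2), 4)
#>          lower    upper
#> alpha   0.0073   0.0106
#> k       4.1919   4.5671
#> scale 154.1416 158.6030

profile_k(co, seq(4.0, 4.4, 0.1), fix_scale = 155)
#>     k       alpha scale       rss converged
#> 1 4.0 0.013404859   155 122.45251      TRUE
#> 2 4.1 0.012064853   155  83.71127      TRUE
#> 3 4.2 0.010860295   155  56.07446      TRUE
#> 4 4.3 0.009777294   155  38.58226      TRUE
#> 5 4.4 0.008803409   155  30.35379      TRUE
```

Note the compensation pattern — as the profiled *k* rises, the fitted α
falls (0.0134 → 0.0088) — and the RSS minimum at the generating k = 4.4.

The mechanistic simulator demonstrates the critical-index identity: with
growth exponent ξ = 2, the Avrami-plot slope of the simulated
transformation curve comes out near ξ + 2 = 4:

```r
curve <- estimate_curve(genome_geometry(), cluster_dynamics(),
                        m_grid = 3:14, n_cells = 10000, seed = 42)
avrami_plot_slope(curve)
#> Avrami plot (OLS on ln(-ln(1 - p)) ~ ln m):
#>   critical index k = 4.0990 (SE 0.0325), alpha = 0.00013269, 7 points
```

A thin command-line wrapper over the same functions lives at
`inst/cli/avramicarc.R` (subcommands `generate`, `simulate`, `fit`,
`predict`, `avrami-plot`; every stochastic subcommand takes `--seed` and
is bit-reproducible; `fit` writes its report as JSON with fields `params`,
`fixed`, `rss`, `n_points`, `converged`, `effective_threshold`, plus
optional `bootstrap` and `profile_k` blocks).

See the methods vignette (`vignettes/avrami-transformation.Rmd`) for the
model's assumptions, the simulator's design choices, and what the
synthetic cohorts do and do not emulate.

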