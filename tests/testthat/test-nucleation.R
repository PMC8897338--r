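geom_default <- function(mu = 0.015) genome_geometry(1, 1e-3, mu)

test_that("stepper conserves counts and respects degenerate parameter limits", {
  # mu = 1, no nucleation: oncogenic count grows, volume stays zero
  geom1 <- genome_geometry(1, 1e-3, oncogene_fraction = 1)
  dyn0 <- cluster_dynamics(beta = 1e-3, xi = 2, nucleation_density = 1e-12)
  set.seed(1)
  st <- new_sim_state()
  for (i in 1:20) st <- step_mutation(st, geom1, dyn0)
  expect_equal(st$oncogenic_count, 20L)
  expect_equal(st$total_count, 20L)
  expect_equal(total_transformed_volume(st, dyn0), 0)

  # mu ~ 0: oncogenic count never moves
  geom0 <- genome_geometry(1, 1e-3, oncogene_fraction = 1e-12)
  st <- new_sim_state()
  for (i in 1:50) st <- step_mutation(st, geom0, dyn0)
  expect_equal(st$oncogenic_count, 0L)
  expect_equal(st$total_count, 50L)
  out <- transformation_outcome(st, geom0, dyn0)
  expect_false(out$transformed)

  # m <= M and monotone nondecreasing trajectory quantities
  geom <- geom_default()
  dyn <- cluster_dynamics(beta = 1e-4, xi = 1, nucleation_density = 5)
  set.seed(42)
  st <- new_sim_state()
  prev_vol <- 0
  for (i in 1:400) {
    st2 <- step_mutation(st, geom, dyn)
    expect_gte(st2$oncogenic_count, st$oncogenic_count)
    expect_equal(st2$total_count, st$total_count + 1L)
    vol <- total_transformed_volume(st2, dyn)
    expect_gte(vol, prev_vol)
    prev_vol <- vol
    st <- st2
  }
  expect_lte(st$oncogenic_count, st$total_count)
})

test_that("cluster volumes follow the growth law, including degenerate xi = 0", {
  dyn <- cluster_dynamics(beta = 0.2, xi = 0, nucleation_density = 1)
  st <- new_sim_state()
  st$oncogenic_count <- 5L
  st$cluster_marks <- c(0L, 3L)
  # xi = 0: every cluster holds constant volume beta from birth
  expect_equal(total_transformed_volume(st, dyn), 0.4)
  dyn2 <- cluster_dynamics(beta = 0.2, xi = 2, nucleation_density = 1)
  expect_equal(total_transformed_volume(st, dyn2), 0.2 * (25 + 4))
  # empty cell
  expect_equal(total_transformed_volume(new_sim_state(), dyn), 0)
})

test_that("mean cluster count after m oncogenic steps is N'Vm", {
  # mu = 1 so each mutation is an oncogenic step
  geom <- genome_geometry(2, 1e-3, oncogene_fraction = 1)
  npr <- 1.5 # N' V = 3
  dyn <- cluster_dynamics(beta = 1e-6, xi = 1, nucleation_density = npr)
  m_steps <- 4L
  reps <- 10000L
  set.seed(11)
  counts <- vapply(seq_len(reps), function(i) {
    st <- new_sim_state()
    for (j in seq_len(m_steps)) st <- step_mutation(st, geom, dyn)
    length(st$cluster_marks)
  }, numeric(1))
  expected <- npr * geom$total_volume * m_steps # Poisson mean per step, summed
  se <- sqrt(expected / reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("ensemble mean aggregate volume scales as m^(xi+1)", {
  npV <- 5
  beta <- 1e-6
  n_cells <- 5000
  m_grid <- seq(10, 100, by = 10)
  for (xi in c(0, 1, 2)) {
    set.seed(100 + xi)
    mean_vol <- vapply(m_grid, function(m) {
      nmat <- matrix(rpois(n_cells * m, npV), nrow = n_cells)
      w <- (m - seq_len(m))^xi
      mean(beta * as.vector(nmat %*% w))
    }, numeric(1))
    slope <- coef(lm(log(mean_vol) ~ log(m_grid)))[2]
    expect_lt(abs(slope - (xi + 1)), 0.1)
  }
})

test_that("threshold mechanism crossing matches the inverted growth law", {
  # deterministic limit: N'V large => median crossing at
  # ((xi+1) V_T / (beta N' V))^(1/(xi+1))
  geom <- geom_default()
  dyn <- cluster_dynamics(beta = 8e-9, xi = 1, nucleation_density = 500,
                          mechanism = "threshold")
  m_star <- ((dyn$xi + 1) * geom$threshold_volume /
               (dyn$beta * dyn$nucleation_density * geom$total_volume))^
    (1 / (dyn$xi + 1))
  curve <- estimate_curve(geom, dyn, m_grid = 18:28, n_cells = 2000, seed = 5)
  crossing <- min(curve$m[curve$p_hat >= 0.5])
  expect_lt(abs(crossing - m_star), 2)
  # zero volume never transforms
  st <- new_sim_state()
  st$oncogenic_count <- 3L
  expect_false(transformation_outcome(st, geom, dyn)$transformed)
})

test_that("empirical curves are seeded, reproducible, and monotone", {
  geom <- geom_default()
  dyn <- cluster_dynamics()
  c1 <- estimate_curve(geom, dyn, m_grid = 4:10, n_cells = 500, seed = 99)
  c2 <- estimate_curve(geom, dyn, m_grid = 4:10, n_cells = 500, seed = 99)
  expect_identical(c1, c2)
  c3 <- estimate_curve(geom, dyn, m_grid = 4:10, n_cells = 500, seed = 100)
  expect_false(identical(c1$p_hat, c3$p_hat))
  expect_equal(c1$std_err, sqrt(c1$p_hat * (1 - c1$p_hat) / 500))

  # no nucleation: no clusters, no transformed volume, nothing transforms
  dyn0 <- cluster_dynamics(beta = 1e-3, xi = 2, nucleation_density = 1e-12)
  c0 <- estimate_curve(geom, dyn0, m_grid = c(2L, 4L, 6L), n_cells = 100,
                       seed = 1)
  expect_true(all(c0$p_hat == 0))

  # monotone up to 3-SE noise
  big <- estimate_curve(geom, dyn, m_grid = 3:14, n_cells = 4000, seed = 3)
  slack <- 3 * sqrt(pmax(big$std_err[-1]^2 + big$std_err[-nrow(big)]^2, 1e-12))
  expect_true(all(diff(big$p_hat) > -slack))
})

test_that("composition-mechanism curve matches its analytic expectation", {
  geom <- geom_default()
  dyn <- cluster_dynamics(beta = 1.9e-7, xi = 2, nucleation_density = 50)
  curve <- estimate_curve(geom, dyn, m_grid = 3:14, n_cells = 10000, seed = 21)
  expected <- vapply(curve$m, expected_composition_p, numeric(1),
                     mu = geom$oncogene_fraction, beta = dyn$beta,
                     npV = dyn$nucleation_density * geom$total_volume,
                     xi = dyn$xi, V = geom$total_volume)
  se <- pmax(sqrt(expected * (1 - expected) / curve$n_cells), 1e-4)
  expect_true(all(abs(curve$p_hat - expected) < 4 * se))
  # and the continuous Avrami law is approached over the central window
  alpha_cont <- dyn$beta * dyn$nucleation_density /
    ((dyn$xi + 1) * geom$oncogene_fraction)
  central <- curve$p_hat > 0.2 & curve$p_hat < 0.8
  cont <- 1 - exp(-alpha_cont * curve$m[central]^(dyn$xi + 2))
  expect_true(all(abs(curve$p_hat[central] - cont) < 0.12))
})

test_that("Avrami-plot regression recovers exact parameters from a noiseless curve", {
  p <- gastric_params()
  # non-integer grid so that >= 4 points fall in the retained (0.05, 0.95) band
  m <- seq(1.6, 3.6, by = 0.25)
  curve <- data.frame(m = m, p_hat = transformation_probability(m, p))
  fit <- avrami_plot_slope(curve)
  expect_equal(fit$k, 4.4, tolerance = 1e-8)
  expect_equal(fit$log_alpha, log(0.0087), tolerance = 1e-8)
  expect_equal(fit$alpha, 0.0087, tolerance = 1e-8)
})

test_that("Avrami-plot regression refuses an under-determined curve", {
  curve <- data.frame(m = 1:6, p_hat = c(0.001, 0.01, 0.04, 0.2, 0.97, 0.999))
  expect_error(avrami_plot_slope(curve), "only 1 point")
  expect_error(avrami_plot_slope(data.frame(x = 1)), "columns")
})

test_that("critical index k = xi + 2 emerges from the composition mechanism", {
  geom <- geom_default()
  # xi = 2 at the package defaults (median transformation near m = 8)
  c2 <- estimate_curve(geom, cluster_dynamics(), m_grid = 3:14,
                       n_cells = 10000, seed = 2024)
  k2 <- avrami_plot_slope(c2)$k
  expect_lt(abs(k2 - 4), 0.25)
  # xi = 1: same law, second exponent (beta rescaled to keep the median
  # in the observable window)
  dyn1 <- cluster_dynamics(beta = 9.3e-7, xi = 1, nucleation_density = 50)
  c1 <- estimate_curve(geom, dyn1, m_grid = 3:16, n_cells = 10000,
                       seed = 2025)
  k1 <- avrami_plot_slope(c1)$k
  expect_lt(abs(k1 - 3), 0.25)
})

test_that("pathological parameterisations clamp the hit probability and warn", {
  geom <- suppressWarnings(genome_geometry(1, 0.5, oncogene_fraction = 1))
  dyn <- cluster_dynamics(beta = 10, xi = 1, nucleation_density = 5)
  st <- new_sim_state()
  st$oncogenic_count <- 4L
  st$total_count <- 4L
  st$cluster_marks <- c(1L, 1L, 2L)
  expect_warning(out <- transformation_outcome(st, geom, dyn), "clamp")
  expect_true(out$transformed)
})
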