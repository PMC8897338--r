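noiseless_cohort <- function(params = gastric_params()) {
  generate_cohort(params, noise_sd = 0)
}

test_that("noiseless data give back the generating parameters", {
  fit <- fit_avrami(noiseless_cohort())
  est <- coef(fit)
  truth <- c(alpha = 0.0087, k = 4.4, scale = 155)
  expect_true(all(abs(est - truth) / truth < 1e-6))
  expect_true(fit$converged)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fitted(fit) + residuals(fit), fit$data$response)
})

test_that("fixed-parameter refits honour the mask", {
  co <- noiseless_cohort()
  fit <- fit_avrami(co, fix_k = 4.4, fix_scale = 155)
  expect_equal(unname(coef(fit)["alpha"]), 0.0087, tolerance = 1e-8)
  expect_identical(fit$params$k, 4.4)
  expect_identical(fit$params$scale, 155)
  expect_equal(unname(fit$fixed), c(FALSE, TRUE, TRUE))
  # the one-dimensional fixed-k fit at the gastric table's k = 4 setting
  fit4 <- fit_avrami(co, fix_k = 4, fix_scale = 155)
  expect_true(fit4$converged)
  expect_gt(fit4$rss, fit$rss)
})

test_that("degenerate and malformed inputs are rejected with clear errors", {
  co <- noiseless_cohort()
  zero <- data.frame(mutations = co$mutations, response = rep(0, nrow(co)))
  expect_error(fit_avrami(zero), "zero")
  expect_error(fit_avrami(data.frame(mutations = c(1, 1, 1, 1),
                                     response = c(1, 2, 3, 4))), "distinct")
  expect_error(fit_avrami(data.frame(response = 1:5)), "mutations")
  few <- data.frame(mutations = c(1, 2, 3, 4), response = c(0, 1, 5, 20))
  expect_error(fit_avrami(few, fix_k = NULL), NA) # 4 points, 3 free: ok
  expect_error(fit_avrami(few[1:3, ]), "distinct")
})

test_that("profiling over k is consistent with constrained fits and minimised at the truth", {
  co <- noiseless_cohort()
  prof <- profile_k(co, k_grid = seq(4.0, 4.5, by = 0.1), fix_scale = 155)
  expect_equal(nrow(prof), 6)
  expect_equal(prof$k[which.min(prof$rss)], 4.4)
  # free-k fit beats every fixed-k fit on the same data
  free_rss <- fit_avrami(co, fix_scale = 155)$rss
  expect_true(all(free_rss <= prof$rss + 1e-10))
  # alpha compensates downward as k is profiled upward
  expect_true(all(diff(prof$alpha) < 0))
  # single-element grid equals the constrained fit
  one <- profile_k(co, k_grid = 4.2, fix_scale = 155)
  direct <- fit_avrami(co, fix_k = 4.2, fix_scale = 155)
  expect_equal(one$alpha, direct$params$alpha, tolerance = 1e-10)
  expect_equal(one$rss, direct$rss, tolerance = 1e-10)
})

test_that("fitting on the age axis equals fitting on the mutation axis", {
  co <- generate_cohort(gastric_params(), noise_sd = 2, seed = 8)
  fit_m <- fit_avrami(data.frame(mutations = co$mutations,
                                 response = co$response))
  fit_a <- fit_avrami(data.frame(age = co$age, response = co$response),
                      rate = 0.053)
  expect_equal(coef(fit_m), coef(fit_a), tolerance = 1e-8)
})

test_that("parameters are recovered from noisy synthetic cohorts", {
  truth <- c(alpha = 0.0087, k = 4.4, scale = 155)
  rel_err <- vapply(1:100, function(i) {
    co <- generate_cohort(gastric_params(), noise_sd = 2, seed = 1000 + i)
    est <- coef(fit_avrami(co))
    max(abs(est - truth) / truth)
  }, numeric(1))
  expect_lt(median(rel_err), 0.15)
})

test_that("Poisson-deviance loss fits count data", {
  co <- generate_cohort(gastric_params(), noise_sd = 0,
                        noise = "poisson_increment", seed = 3)
  fit <- fit_avrami(co, loss = "poisson")
  expect_true(fit$converged)
  est <- coef(fit)
  expect_lt(abs(est["k"] - 4.4) / 4.4, 0.35)
  expect_lt(abs(est["scale"] - 155) / 155, 0.35)
})

test_that("prediction works on mutation counts, ages, and probability scale", {
  fit <- fit_avrami(noiseless_cohort())
  m <- c(1, 2.5, 4)
  expect_equal(predict(fit, m), avrami_risk(m, fit$params))
  expect_equal(predict(fit, data.frame(mutations = m)),
               avrami_risk(m, fit$params))
  expect_equal(predict(fit, data.frame(age = m / 0.053)),
               avrami_risk(m, fit$params), tolerance = 1e-10)
  expect_equal(predict(fit, m, type = "probability"),
               transformation_probability(m, fit$params))
  expect_equal(predict(fit), fitted(fit))
})

test_that("model-object methods behave like standard fits", {
  fit <- fit_avrami(generate_cohort(gastric_params(), noise_sd = 2, seed = 5))
  expect_named(coef(fit), c("alpha", "k", "scale"))
  s <- summary(fit)
  expect_s3_class(s, "summary.avrami_fit")
  expect_gt(s$sigma, 0)
  expect_output(print(fit), "Avrami risk-curve fit")
  expect_output(print(s), "effective threshold")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n_points, 3))
  expect_true(all(sims >= 0))
  expect_identical(simulate(fit, nsim = 2, seed = 7),
                   simulate(fit, nsim = 2, seed = 7))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("bootstrap intervals are deterministic and collapse on exact fits", {
  co <- noiseless_cohort()
  fit <- fit_avrami(co)
  ci <- bootstrap_ci(co, fit, n_boot = 120, seed = 4)
  expect_identical(ci, bootstrap_ci(co, fit, n_boot = 120, seed = 4))
  # exact-fit resamples refit identically: zero-width intervals
  expect_lt(max(ci[, "upper"] - ci[, "lower"]), 1e-6)
  expect_equal(unname(ci["alpha", "lower"]), 0.0087, tolerance = 1e-6)
  ci2 <- bootstrap_ci(NULL, fit, n_boot = 120, seed = 4)
  expect_identical(ci, ci2)
  expect_error(bootstrap_ci(co, fit, n_boot = 50), "n_boot")
})

test_that("bootstrap coverage of the generating alpha is near nominal", {
  truth_alpha <- 0.0087
  n_outer <- 50
  covered <- vapply(seq_len(n_outer), function(i) {
    co <- generate_cohort(gastric_params(), noise_sd = 2, seed = 5000 + i)
    fit <- fit_avrami(co)
    ci <- bootstrap_ci(NULL, fit, n_boot = 1000, level = 0.95,
                       seed = 6000 + i)
    ci["alpha", "lower"] <= truth_alpha && truth_alpha <= ci["alpha", "upper"]
  }, logical(1))
  expect_gte(mean(covered), 0.85)
  expect_lte(mean(covered), 1.0)
})
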