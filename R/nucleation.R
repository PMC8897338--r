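#' Cluster nucleation-and-growth dynamics
#'
#' Constants governing the Monte Carlo mechanism: each oncogenic mutation
#' nucleates new cancer clusters (mutated oncogenes) at Poisson rate
#' `nucleation_density * V` clusters per oncogenic mutation, and a cluster
#' nucleated when the cell carried `m_nuc` oncogenic mutations has volume
#' `beta * (m - m_nuc)^xi` once the count has grown to `m` (the
#' `"since_nucleation"` growth reading). The alternative `"snapshot"`
#' reading gives every cluster the volume `beta * m^xi` of the current
#' global count; both aggregate to the same `m^(xi+1)` ensemble scaling.
#'
#' Two transformation mechanisms are supported:
#' \describe{
#'   \item{`"composition"`}{each of the `M` total mutations independently
#'     hits the currently transformed volume with probability
#'     `V_N,tot / V`; the cell transforms when at least one hits. This is
#'     the multi-hit composition that yields the Avrami law with critical
#'     index `k = xi + 2`, and is the default.}
#'   \item{`"threshold"`}{the cell transforms exactly when the total
#'     cluster volume reaches the threshold, `V_N,tot >= V_T`. This literal
#'     crossing rule gives a sharper sigmoid that is not exactly
#'     Avrami-shaped.}
#' }
#'
#' @param beta Cluster growth prefactor `beta` (volume units per
#'   mutation^xi, positive).
#' @param xi Cluster growth exponent `xi` (nonnegative).
#' @param nucleation_density Expected new clusters per oncogenic mutation
#'   per unit DNA volume, `N'` (positive).
#' @param mechanism Transformation mechanism, `"composition"` (default) or
#'   `"threshold"`.
#' @param growth Cluster growth reading, `"since_nucleation"` (default) or
#'   `"snapshot"`.
#' @return An object of class `"cluster_dynamics"`.
#' @examples
#' cluster_dynamics(beta = 1.9e-7, xi = 2, nucleation_density = 50)
#' @export
cluster_dynamics <- function(beta = 1.9e-7, xi = 2, nucleation_density = 50,
                             mechanism = c("composition", "threshold"),
                             growth = c("since_nucleation", "snapshot")) {
  structure(
    list(beta = check_scalar(beta, "beta", lower = 0, strict_lower = TRUE),
         xi = check_scalar(xi, "xi", lower = 0),
         nucleation_density = check_scalar(nucleation_density,
                                           "nucleation_density",
                                           lower = 0, strict_lower = TRUE),
         mechanism = match.arg(mechanism),
         growth = match.arg(growth)),
    class = "cluster_dynamics"
  )
}

#' @export
print.cluster_dynamics <- function(x, ...) {
  cat("Cluster dynamics: beta =", format(x$beta), " xi =", format(x$xi),
      " N' =", format(x$nucleation_density), "\n")
  cat("  mechanism:", x$mechanism, "  growth:", x$growth, "\n")
  cat("  aggregate volume law: V_N,tot ~ (beta N' V/(xi+1)) V m^(xi+1),",
      "critical index k =", format(x$xi + 2), "\n")
  invisible(x)
}

#' Aggregate volume prefactor of the growth law
#'
#' Integrating the per-mutation volume increment
#' `dV_N,tot = beta m^xi N' V dm` from 0 to `m` gives
#' `V_N,tot = const * V * m^(xi+1)` with
#' `const = beta * N' / (xi + 1)`; this derived constant is exposed
#' because the Avrami shape parameter inherits it.
#'
#' @param dynamics A [cluster_dynamics()] object.
#' @return The constant `beta * nucleation_density / (xi + 1)`.
#' @export
growth_law_constant <- function(dynamics) {
  stopifnot(inherits(dynamics, "cluster_dynamics"))
  dynamics$beta * dynamics$nucleation_density / (dynamics$xi + 1)
}

#' Initialise a single-cell simulation state
#'
#' @return An object of class `"sim_state"` with zero mutations, no
#'   clusters, and `transformed = FALSE`. `cluster_marks` records, for each
#'   nucleated cluster, the oncogenic count at which it appeared.
#' @seealso [step_mutation()], [total_transformed_volume()]
#' @export
new_sim_state <- function() {
  structure(
    list(oncogenic_count = 0L, total_count = 0L,
         cluster_marks = integer(0), transformed = FALSE),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "Cell state: m = %d oncogenic of M = %d mutations, %d clusters%s\n",
    x$oncogenic_count, x$total_count, length(x$cluster_marks),
    if (x$transformed) " [transformed]" else ""))
  invisible(x)
}

#' Advance a cell by one DNA mutation
#'
#' One mutation lands uniformly in the DNA volume: with probability `mu`
#' (the oncogene fraction) it is oncogenic, incrementing the oncogenic
#' count and nucleating `Poisson(N' * V)` new clusters marked at the new
#' count. Non-oncogenic mutations only increment the total count. Uses the
#' current R random stream; seed with `set.seed()` for reproducibility.
#'
#' @param state A `"sim_state"` object (see [new_sim_state()]).
#' @param geometry A [genome_geometry()] object (supplies `mu` and `V`).
#' @param dynamics A [cluster_dynamics()] object (supplies `N'`).
#' @return The updated state.
#' @export
step_mutation <- function(state, geometry, dynamics) {
  stopifnot(inherits(state, "sim_state"),
            inherits(geometry, "genome_geometry"),
            inherits(dynamics, "cluster_dynamics"))
  if (state$transformed) {
    stop("cell is already transformed; no further mutations are simulated",
         call. = FALSE)
  }
  state$total_count <- state$total_count + 1L
  if (stats::runif(1) < geometry$oncogene_fraction) {
    state$oncogenic_count <- state$oncogenic_count + 1L
    n_new <- stats::rpois(1, dynamics$nucleation_density * geometry$total_volume)
    if (n_new > 0) {
      state$cluster_marks <- c(state$cluster_marks,
                               rep.int(state$oncogenic_count, n_new))
    }
  }
  state
}

#' Total transformed (cluster) volume of a cell
#'
#' Sum of the volumes of all nucleated clusters at the cell's current
#' oncogenic count. Cluster overlaps are neglected (`V_T << V` makes them
#' negligible), so the union volume is evaluated as a plain sum, matching
#' the integral form of the aggregate growth law.
#'
#' @inheritParams step_mutation
#' @return The total transformed volume `V_N,tot` (nonnegative).
#' @export
total_transformed_volume <- function(state, dynamics) {
  stopifnot(inherits(state, "sim_state"),
            inherits(dynamics, "cluster_dynamics"))
  if (length(state$cluster_marks) == 0L) return(0)
  m <- state$oncogenic_count
  if (dynamics$growth == "since_nucleation") {
    age <- m - state$cluster_marks
    sum(dynamics$beta * age^dynamics$xi) # 0^0 = 1: xi = 0 clusters are born at volume beta
  } else {
    length(state$cluster_marks) * dynamics$beta * m^dynamics$xi
  }
}

#' Evaluate the transformation outcome of a cell
#'
#' Applies the configured transformation mechanism to the cell's current
#' state. Under `"threshold"` the cell is transformed iff its total
#' cluster volume has reached `V_T`. Under `"composition"` each of the `M`
#' mutations accumulated so far is independently tested against the
#' transformed volume fraction `V_N,tot / V` (a Bernoulli draw per
#' mutation); the cell is transformed iff at least one lands inside.
#'
#' @inheritParams step_mutation
#' @return The state with its `transformed` flag set from this evaluation.
#' @export
transformation_outcome <- function(state, geometry, dynamics) {
  stopifnot(inherits(state, "sim_state"),
            inherits(geometry, "genome_geometry"),
            inherits(dynamics, "cluster_dynamics"))
  vol <- total_transformed_volume(state, dynamics)
  if (dynamics$mechanism == "threshold") {
    state$transformed <- vol >= geometry$threshold_volume
  } else {
    frac <- vol / geometry$total_volume
    if (frac > 1) {
      warning("transformed volume exceeds the DNA volume; ",
              "clamping hit probability to 1 (pathological parameters)",
              call. = FALSE)
      frac <- 1
    }
    state$transformed <- vol > 0 &&
      stats::rbinom(1, size = state$total_count, prob = frac) > 0
  }
  state
}

#' Simulate a cell until a target oncogenic mutation count
#'
#' Repeatedly applies [step_mutation()] until the cell has accumulated
#' `m_target` oncogenic mutations, then evaluates the transformation
#' outcome. Mainly a readable reference path; [estimate_curve()] runs the
#' identical process vectorised over many cells.
#'
#' @inheritParams step_mutation
#' @param m_target Oncogenic mutation count at which to stop (positive
#'   integer).
#' @return The final `"sim_state"`, with `transformed` evaluated.
#' @export
simulate_cell <- function(geometry, dynamics, m_target) {
  m_target <- check_scalar(m_target, "m_target", lower = 1)
  state <- new_sim_state()
  while (state$oncogenic_count < m_target) {
    state <- step_mutation(state, geometry, dynamics)
  }
  transformation_outcome(state, geometry, dynamics)
}

#' Empirical transformation curve from the cluster simulator
#'
#' Simulates `n_cells` independent cells to each point of an oncogenic
#' mutation grid and records the fraction transformed, yielding an
#' empirical estimate of the transformation probability `P(m)` with its
#' binomial standard error. Cells are independent across grid points
#' (each point gets a fresh cohort, not a continuation).
#'
#' The sampling is performed with vectorised draws that are
#' distributionally identical to running [step_mutation()] /
#' [transformation_outcome()] cell by cell: per cell, cluster counts at
#' each oncogenic step are Poisson(`N' V`), the total mutation count at
#' the grid point is `m` plus a negative-binomial number of non-oncogenic
#' mutations, and the mechanism is applied to the resulting volume.
#'
#' @inheritParams step_mutation
#' @param m_grid Increasing grid of positive integer oncogenic mutation
#'   counts.
#' @param n_cells Number of cells per grid point (at least 100).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   curves. The caller's random stream is left untouched.
#' @return An object of class `"transformation_curve"`: a data frame with
#'   columns `m`, `p_hat`, `n_cells`, `std_err`.
#' @examples
#' curve <- estimate_curve(genome_geometry(), cluster_dynamics(),
#'                         m_grid = 4:12, n_cells = 500, seed = 1)
#' curve
#' @export
estimate_curve <- function(geometry, dynamics, m_grid = 3:14,
                           n_cells = 10000, seed = NULL) {
  stopifnot(inherits(geometry, "genome_geometry"),
            inherits(dynamics, "cluster_dynamics"))
  m_grid <- check_nonneg_vector(m_grid, "m_grid")
  if (any(m_grid != round(m_grid)) || any(m_grid < 1)) {
    stop("`m_grid` must contain positive integers", call. = FALSE)
  }
  if (is.unsorted(m_grid, strictly = TRUE)) {
    stop("`m_grid` must be strictly increasing", call. = FALSE)
  }
  n_cells <- check_scalar(n_cells, "n_cells", lower = 100)
  mu <- geometry$oncogene_fraction
  npV <- dynamics$nucleation_density * geometry$total_volume
  warned <- FALSE

  p_hat <- with_seed(seed, vapply(m_grid, function(m) {
    # Poisson cluster counts per oncogenic step, per cell
    nmat <- matrix(stats::rpois(n_cells * m, npV), nrow = n_cells, ncol = m)
    w <- if (dynamics$growth == "since_nucleation") {
      (m - seq_len(m))^dynamics$xi
    } else {
      rep(m^dynamics$xi, m)
    }
    vol <- dynamics$beta * as.vector(nmat %*% w)
    if (dynamics$mechanism == "threshold") {
      return(mean(vol >= geometry$threshold_volume))
    }
    frac <- vol / geometry$total_volume
    if (!warned && any(frac > 1)) {
      warning("transformed volume exceeds the DNA volume; ",
              "clamping hit probability to 1 (pathological parameters)",
              call. = FALSE)
      warned <<- TRUE
    }
    frac <- pmin(frac, 1)
    # total mutations when the oncogenic count first reaches m
    M <- m + stats::rnbinom(n_cells, size = m, prob = mu)
    mean(stats::rbinom(n_cells, size = M, prob = frac) > 0)
  }, numeric(1)))

  structure(
    data.frame(m = m_grid, p_hat = p_hat, n_cells = n_cells,
               std_err = sqrt(p_hat * (1 - p_hat) / n_cells)),
    class = c("transformation_curve", "data.frame")
  )
}

#' Estimate the Avrami critical index from a transformation curve
#'
#' Ordinary least-squares fit of the Avrami plot: `ln(-ln(1 - p_hat))`
#' against `ln(m)`. Its slope estimates the critical index `k` and its
#' intercept `ln(alpha)`. Points with `p_hat` outside `(p_range[1],
#' p_range[2])` (default 0.05--0.95) are discarded first, since the
#' double-log transform blows up at both tails; at least four points must
#' survive.
#'
#' @param curve A `"transformation_curve"`, or any data frame with columns
#'   `m` and `p_hat`.
#' @param p_range Open retention interval for `p_hat` (default
#'   `c(0.05, 0.95)`).
#' @return An object of class `"avrami_plot_fit"`: a list with `k`
#'   (slope), `log_alpha` (intercept), `alpha`, `n_used`, `k_se` and the
#'   underlying `lm` fit.
#' @examples
#' p <- transformation_probability(2:12, avrami_params(0.0087, 4.4))
#' avrami_plot_slope(data.frame(m = 2:12, p_hat = p))
#' @export
avrami_plot_slope <- function(curve, p_range = c(0.05, 0.95)) {
  if (!is.data.frame(curve) || !all(c("m", "p_hat") %in% names(curve))) {
    stop("`curve` must be a data frame with columns `m` and `p_hat`",
         call. = FALSE)
  }
  keep <- curve$p_hat > p_range[1] & curve$p_hat < p_range[2] & curve$m > 0
  n_used <- sum(keep)
  if (n_used < 4L) {
    stop("insufficient data for the Avrami plot: only ", n_used,
         " point(s) with p_hat strictly inside (", p_range[1], ", ",
         p_range[2], "); at least 4 are required", call. = FALSE)
  }
  x <- log(curve$m[keep])
  y <- avrami_transform(curve$p_hat[keep])
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  structure(
    list(k = unname(cf[2]), log_alpha = unname(cf[1]),
         alpha = exp(unname(cf[1])), n_used = n_used,
         # vcov warns on numerically perfect fits (zero residual); the SE
         # is still the right degenerate answer there
         k_se = suppressWarnings(unname(sqrt(diag(stats::vcov(fit)))[2])),
         lm_fit = fit),
    class = "avrami_plot_fit"
  )
}

#' @export
print.avrami_plot_fit <- function(x, ...) {
  cat("Avrami plot (OLS on ln(-ln(1 - p)) ~ ln m):\n")
  cat(sprintf("  critical index k = %.4f (SE %.4f), alpha = %.5g, %d points\n",
              x$k, x$k_se, x$alpha, x$n_used))
  invisible(x)
}

#' @export
print.transformation_curve <- function(x, ...) {
  cat(sprintf("Empirical transformation curve (%d grid points, %d cells/point)\n",
              nrow(x), x$n_cells[1]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot a transformation curve
#'
#' Draws the empirical transformation fraction against the oncogenic
#' mutation count, with +/- 2 SE error bars, or the linearised Avrami plot
#' (`avrami = TRUE`).
#'
#' @param x A `"transformation_curve"`.
#' @param avrami If `TRUE`, draw `ln(-ln(1 - p_hat))` against `ln(m)` for
#'   points inside `(0.05, 0.95)` instead of the raw sigmoid.
#' @param ... Passed on to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.transformation_curve <- function(x, avrami = FALSE, ...) {
  if (avrami) {
    keep <- x$p_hat > 0.05 & x$p_hat < 0.95
    graphics::plot(log(x$m[keep]), avrami_transform(x$p_hat[keep]),
                   xlab = "ln m", ylab = "ln(-ln(1 - p))",
                   main = "Avrami plot", ...)
  } else {
    graphics::plot(x$m, x$p_hat, ylim = c(0, 1),
                   xlab = "oncogenic mutations m",
                   ylab = "transformed fraction",
                   main = "Empirical transformation curve", ...)
    graphics::arrows(x$m, pmax(0, x$p_hat - 2 * x$std_err),
                     x$m, pmin(1, x$p_hat + 2 * x$std_err),
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
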