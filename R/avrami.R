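#' Parameters of the Avrami transformation and risk functions
#'
#' The sigmoidal transformation probability `P(m) = 1 - exp(-alpha * m^k)`
#' has two shape parameters: `alpha`, which sets where the central part of
#' the sigmoid sits on the mutation axis (jointly with `k`), and the
#' critical index `k`, which sets the steepness and reflects the
#' dimensionality of cluster growth (`k = xi + 2` in the
#' nucleation-and-growth mechanism). The risk form multiplies the
#' probability by a scaling factor `C` (`scale`), e.g. the number of cancer
#' cases a registry would record in the cohort; `scale = 1` recovers the
#' pure probability.
#'
#' @param alpha Shape constant `alpha` (positive).
#' @param k Critical index `k` (positive).
#' @param scale Scaling factor `C` from probability to risk (positive;
#'   default 1).
#' @return An object of class `"avrami_params"`.
#' @examples
#' avrami_params(alpha = 0.0087, k = 4.4, scale = 155) # headline gastric fit
#' @export
avrami_params <- function(alpha, k, scale = 1) {
  structure(
    list(alpha = check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE),
         k = check_scalar(k, "k", lower = 0, strict_lower = TRUE),
         scale = check_scalar(scale, "scale", lower = 0, strict_lower = TRUE)),
    class = "avrami_params"
  )
}

#' @export
print.avrami_params <- function(x, ...) {
  cat("Avrami parameters: alpha =", format(x$alpha),
      " k =", format(x$k), " C =", format(x$scale), "\n")
  invisible(x)
}

as_avrami_params <- function(params) {
  if (inherits(params, "avrami_params")) return(params)
  if (is.numeric(params) && !is.null(names(params)) &&
      all(c("alpha", "k") %in% names(params))) {
    scale <- if ("scale" %in% names(params)) params[["scale"]] else 1
    return(avrami_params(params[["alpha"]], params[["k"]], scale))
  }
  stop("`params` must be an `avrami_params` object ",
       "(or a named vector with alpha, k and optionally scale)",
       call. = FALSE)
}

#' Avrami transformation probability
#'
#' Probability that a cell carrying `m` oncogenic mutations has undergone
#' neoplastic transformation: `P(m) = 1 - exp(-alpha * m^k)`. This is the
#' Johnson-Mehl-Avrami-Kolmogorov kinetics of nucleation and growth with
#' the oncogenic mutation count playing the role of time.
#'
#' @param m Oncogenic mutation count(s), nonnegative real (the model treats
#'   `m` as a continuous mean count).
#' @param params An [avrami_params()] object (its `scale` is ignored here).
#' @return Probabilities in `[0, 1)`, strictly increasing in `m`.
#' @examples
#' p <- avrami_params(alpha = 0.0133, k = 4)
#' transformation_probability(0:6, p)
#' @export
transformation_probability <- function(m, params) {
  params <- as_avrami_params(params)
  m <- check_nonneg_vector(m, "m")
  -expm1(-params$alpha * m^params$k)
}

#' Avrami risk function
#'
#' The transformation probability rescaled to cohort units:
#' `C * (1 - exp(-alpha * m^k))`. With `C` equal to, say, the number of
#' cancer cases a registry accumulates in the cohort, this is the expected
#' cumulative incidence at mean oncogenic mutation count `m`; its supremum
#' as `m` grows is `C`.
#'
#' @inheritParams transformation_probability
#' @return Nonnegative values in `[0, scale)`.
#' @examples
#' avrami_risk(2.5, avrami_params(0.0087, 4.4, scale = 155))
#' @export
avrami_risk <- function(m, params) {
  params <- as_avrami_params(params)
  params$scale * transformation_probability(m, params)
}

#' Most probable transformation mutation count
#'
#' The mode of the transformation density `dP/dm = alpha k m^(k-1)
#' exp(-alpha m^k)`: the number of oncogenic mutations at which
#' transformations are most likely to occur, i.e. the location of the
#' effective threshold. For `k > 1` the argmax is
#' `((k - 1) / (alpha k))^(1/k)`; for `k <= 1` the density is
#' monotonically decreasing and the mode sits at the origin (returned as 0,
#' with a warning).
#'
#' @param params An [avrami_params()] object.
#' @return The mutation count maximising `dP/dm`.
#' @examples
#' mode_of_density(avrami_params(0.0133, 4)) # ~2.74, i.e. between 2 and 4
#' @export
mode_of_density <- function(params) {
  params <- as_avrami_params(params)
  if (params$k <= 1) {
    warning("density has no interior mode for k <= 1; returning 0",
            call. = FALSE)
    return(0)
  }
  ((params$k - 1) / (params$alpha * params$k))^(1 / params$k)
}

#' Mutation count at a given transformation probability
#'
#' Inverse of [transformation_probability()]:
#' `m(p) = (-log(1 - p) / alpha)^(1/k)`.
#'
#' @param p Probability value(s) in `[0, 1)`.
#' @inheritParams mode_of_density
#' @return Mutation count(s) `m` with `P(m) = p`.
#' @examples
#' quantile_m(0.5, avrami_params(0.0087, 4.4))
#' @export
quantile_m <- function(p, params) {
  params <- as_avrami_params(params)
  p <- check_nonneg_vector(p, "p")
  if (any(p >= 1)) {
    stop("`p` must be strictly less than 1 (P(m) never reaches 1)",
         call. = FALSE)
  }
  (-log1p(-p) / params$alpha)^(1 / params$k)
}

#' Effective threshold summary of the transformation sigmoid
#'
#' The sigmoid acts as an effective (soft) threshold on the mutation count.
#' Because "threshold" admits several readings, three summaries are
#' reported: the density mode (most probable transformation count) and the
#' central 5--95% interval of the transformation distribution.
#'
#' @inheritParams mode_of_density
#' @return A list with `mode`, `lower` (m at P = 0.05) and `upper`
#'   (m at P = 0.95).
#' @examples
#' effective_threshold(avrami_params(0.0133, 4))
#' @export
effective_threshold <- function(params) {
  params <- as_avrami_params(params)
  list(mode = mode_of_density(params),
       lower = quantile_m(0.05, params),
       upper = quantile_m(0.95, params))
}

#' Avrami-plot linearising transform
#'
#' The double-log transform `ln(-ln(1 - p))`, under which the Avrami
#' sigmoid becomes the straight line `ln(alpha) + k * ln(m)`. Used by the
#' slope estimator and available for plotting.
#'
#' @param p Probabilities strictly inside `(0, 1)`.
#' @return `log(-log(1 - p))`.
#' @export
avrami_transform <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  log(-log1p(-p))
}

#' Convert age to mean oncogenic mutation count
#'
#' Mutation burden accumulates roughly linearly with age; for gastric
#' tissue the mean number of oncogenic mutations per cell is
#' `0.053 * age` (years). The rate is tissue-specific, so it is exposed as
#' a parameter with the gastric value as default.
#'
#' @param age Age(s) in years, nonnegative.
#' @param rate Mean oncogenic mutations per cell per year (positive;
#'   default 0.053).
#' @return Mean oncogenic mutation count(s) `rate * age`.
#' @examples
#' mutations_from_age(60) # 3.18
#' @export
mutations_from_age <- function(age, rate = 0.053) {
  age <- check_nonneg_vector(age, "age")
  rate <- check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  rate * age
}

#' Convert mean oncogenic mutation count to age
#'
#' Inverse of [mutations_from_age()]: `age = m / rate`.
#'
#' @param m Mean oncogenic mutation count(s), nonnegative.
#' @inheritParams mutations_from_age
#' @return Age(s) in years.
#' @export
age_from_mutations <- function(m, rate = 0.053) {
  m <- check_nonneg_vector(m, "m")
  rate <- check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  m / rate
}
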