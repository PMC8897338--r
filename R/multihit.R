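#' Probability that a single mutation is oncogenic
#'
#' In the volumetric multi-hit model a mutation lands uniformly at random in
#' the DNA volume `V`; it contributes to transformation when it falls inside
#' the threshold volume `V_T` of proto-oncogenes. For a single mutation the
#' probability is simply the volume ratio `V_T / V`.
#'
#' @param geometry A [genome_geometry()] object.
#' @return The probability `V_T / V`, in `(0, 1)`.
#' @examples
#' single_hit_probability(genome_geometry(10000, 1)) # 1e-4
#' @export
single_hit_probability <- function(geometry) {
  stopifnot(inherits(geometry, "genome_geometry"))
  geometry$ratio
}

#' Probability that at least one of two mutations is oncogenic
#'
#' With two mutations (`M = 2`) three scenarios lead to at least one
#' oncogenic hit: only the first lands in `V_T`, only the second does, or
#' both do. Writing `r = V_T / V`, the probability is
#' `2 r (1 - r) + r^2 = 1 - (1 - r)^2`.
#'
#' @inheritParams single_hit_probability
#' @return The two-mutation hit probability.
#' @examples
#' two_hit_probability(genome_geometry(1, 0.1)) # 0.19
#' @export
two_hit_probability <- function(geometry) {
  stopifnot(inherits(geometry, "genome_geometry"))
  r <- geometry$ratio
  2 * r * (1 - r) + r^2
}

#' Oncogenic hit probability as an explicit binomial sum
#'
#' The probability that at least one of `M` independent uniform mutations
#' lands in the threshold volume, evaluated as the literal binomial sum
#' `sum_{m=1}^{M} C(M, m) r^m (1 - r)^(M - m)` with `r = V_T / V`. For
#' `M > 30` the numerically identical complement form `1 - (1 - r)^M` is
#' used instead (the binomial coefficients overflow long before double
#' precision runs out of exponent); the literal sum is kept for small `M`
#' where it serves as a cross-check against exhaustive enumeration.
#'
#' @inheritParams single_hit_probability
#' @param total_mutations Total number of mutations `M` (nonnegative
#'   integer, vectorised).
#' @return Probability of at least one oncogenic hit; 0 when `M = 0`.
#' @seealso [oncogenic_hit_probability_exact()] for the closed complement
#'   form, [oncogenic_hit_probability_approx()] for the exponential limit.
#' @export
oncogenic_hit_probability_sum <- function(geometry, total_mutations) {
  stopifnot(inherits(geometry, "genome_geometry"))
  M <- check_nonneg_vector(total_mutations, "total_mutations")
  if (any(M != round(M))) {
    stop("`total_mutations` must be integer-valued", call. = FALSE)
  }
  r <- geometry$ratio
  vapply(M, function(Mi) {
    if (Mi == 0) return(0)
    if (Mi > 30) return(-expm1(Mi * log1p(-r)))
    sum(stats::dbinom(seq_len(Mi), size = Mi, prob = r))
  }, numeric(1))
}

#' Oncogenic hit probability, closed complement form
#'
#' Because the binomial distribution sums to one, the probability of at
#' least one oncogenic hit among `M` mutations is
#' `1 - (1 - r)^M` with `r = V_T / V`. Evaluated in log space
#' (`-expm1(M * log1p(-r))`) so that tiny ratios and large `M` do not lose
#' precision.
#'
#' @inheritParams oncogenic_hit_probability_sum
#' @return `1 - (1 - r)^M`, vectorised over `total_mutations`.
#' @examples
#' geom <- genome_geometry(1, 1e-4)
#' oncogenic_hit_probability_exact(geom, 1000) # ~0.09517
#' @export
oncogenic_hit_probability_exact <- function(geometry, total_mutations) {
  stopifnot(inherits(geometry, "genome_geometry"))
  M <- check_nonneg_vector(total_mutations, "total_mutations")
  if (any(M != round(M))) {
    stop("`total_mutations` must be integer-valued", call. = FALSE)
  }
  -expm1(M * log1p(-geometry$ratio))
}

#' Oncogenic hit probability, exponential (rare-hit) limit
#'
#' In the limit `V_T << V` the complement form converts to the first-order
#' exponential expansion `p = 1 - exp(-(V_T/V) * M)`. Expressed through the
#' mean number of oncogenic mutations `m = mu * M` this is
#' `p(m) = 1 - exp(-(V_T/V) * m / mu)`, which accepts a continuous `m`
#' (downstream, the age conversion yields non-integer mean mutation
#' counts).
#'
#' @inheritParams single_hit_probability
#' @param oncogenic_mutations Mean number of oncogenic mutations `m`
#'   (nonnegative real, vectorised).
#' @return `1 - exp(-(V_T/V) * m / mu)`.
#' @examples
#' geom <- genome_geometry(1, 1e-4, oncogene_fraction = 0.015)
#' oncogenic_hit_probability_approx(geom, 15) # ~0.09516 (M = 1000)
#' @export
oncogenic_hit_probability_approx <- function(geometry, oncogenic_mutations) {
  stopifnot(inherits(geometry, "genome_geometry"))
  m <- check_nonneg_vector(oncogenic_mutations, "oncogenic_mutations")
  -expm1(-geometry$ratio * m / geometry$oncogene_fraction)
}
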