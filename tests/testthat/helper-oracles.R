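# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation available so they stay independent of
# the implementation paths they check.

# Exhaustive enumeration of all 2^M hit/miss configurations of M mutations,
# each mutation in the threshold volume with probability r: probability that
# at least one configuration bit is set, summed configuration by
# configuration.
enumerate_hit_probability <- function(r, M) {
  if (M == 0) return(0)
  stopifnot(M <= 16)
  total <- 0
  for (config in 0:(2^M - 1)) {
    hits <- sum(bitwAnd(config, bitwShiftL(1L, 0:(M - 1))) != 0)
    if (hits >= 1) total <- total + r^hits * (1 - r)^(M - hits)
  }
  total
}

# Argmax of the finite-difference derivative of the transformation
# probability on an evenly spaced grid: a brute-force stand-in for the
# closed-form density mode.
grid_search_mode <- function(params, m_max = 20, spacing = 1e-4) {
  m <- seq(0, m_max, by = spacing)
  p <- transformation_probability(m, params)
  dp <- diff(p) / spacing
  mid <- (m[-1] + m[-length(m)]) / 2
  mid[which.max(dp)]
}

# Expected composition-mechanism transformation probability at integer
# oncogenic count m, under the package's discrete dynamics: cluster volume
# beta * (m - i)^xi for nucleation at count i with mean N'V clusters per
# step, and the total mutation count distributed as m plus a
# negative-binomial number of non-oncogenic mutations. Uses the
# negative-binomial probability generating function at s = 1 - v; cluster
# count variance is neglected (its relative contribution is O(1/(N'V))).
expected_composition_p <- function(m, mu, beta, npV, xi, V = 1) {
  vbar <- beta * npV * sum((m - seq_len(m))^xi)
  s <- 1 - vbar / V
  1 - (mu * s / (1 - (1 - mu) * s))^m
}

# Deterministic default test fixture: the headline gastric-cancer fit.
gastric_params <- function() avrami_params(alpha = 0.0087, k = 4.4, scale = 155)
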