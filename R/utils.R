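# internal helpers shared across modules

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so seeded calls do not perturb the
# global stream. seed = NULL means "use the current stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # force initialisation so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "`%s` must be in %s%g, %g%s (got %g)", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ), call. = FALSE)
  }
  as.numeric(x)
}

check_nonneg_vector <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric vector", name), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("`%s` must be nonnegative", name), call. = FALSE)
  }
  as.numeric(x)
}
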