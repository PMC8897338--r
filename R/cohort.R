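#' Construct a cohort incidence table
#'
#' A cohort dataset records, per age point, the mean oncogenic mutation
#' count per cell (`mutations = rate * age`) and a response — either the
#' cumulative number of cancer cases registered up to that age or a
#' probability. When both `age` and `mutations` are supplied they must be
#' consistent with the rate; when only one is supplied the other is filled
#' in.
#'
#' Real registry tables can be noisy, so violations of cumulative
#' monotonicity only warn; negative responses and non-increasing ages are
#' errors.
#'
#' @param age Strictly increasing ages in years (optional if `mutations`
#'   given).
#' @param mutations Mean oncogenic mutation counts (optional if `age`
#'   given).
#' @param response Nonnegative responses (cumulative cases or
#'   probabilities).
#' @param rate Mutations-per-year conversion rate (default 0.053).
#' @param response_kind `"cumulative_cases"` (default) or `"probability"`.
#' @return A data frame of class `"cohort"` with columns `age`,
#'   `mutations`, `response` and attributes `rate`, `response_kind`.
#' @export
cohort <- function(age = NULL, mutations = NULL, response,
                   rate = 0.053, response_kind = c("cumulative_cases",
                                                   "probability")) {
  response_kind <- match.arg(response_kind)
  rate <- check_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  if (is.null(age) && is.null(mutations)) {
    stop("at least one of `age` and `mutations` must be supplied",
         call. = FALSE)
  }
  if (is.null(age)) age <- age_from_mutations(mutations, rate)
  if (is.null(mutations)) mutations <- mutations_from_age(age, rate)
  age <- check_nonneg_vector(age, "age")
  mutations <- check_nonneg_vector(mutations, "mutations")
  response <- check_nonneg_vector(response, "response")
  if (length(age) != length(response) || length(mutations) != length(response)) {
    stop("`age`, `mutations` and `response` must have equal lengths",
         call. = FALSE)
  }
  if (length(age) > 1 && is.unsorted(age, strictly = TRUE)) {
    stop("`age` must be strictly increasing", call. = FALSE)
  }
  if (length(age) > 0 &&
      max(abs(mutations - rate * age)) > 1e-9 * max(1, max(mutations))) {
    stop("`mutations` is inconsistent with `rate * age` ",
         "(check the rate or drop one of the two columns)", call. = FALSE)
  }
  if (response_kind == "cumulative_cases" && length(response) > 1 &&
      any(diff(response) < 0)) {
    warning("cumulative responses are not nondecreasing in age; ",
            "keeping the data as given", call. = FALSE)
  }
  structure(
    data.frame(age = age, mutations = mutations, response = response),
    rate = rate, response_kind = response_kind,
    class = c("cohort", "data.frame")
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort dataset: %d points, rate = %g mutations/year, %s\n",
              nrow(x), attr(x, "rate"), attr(x, "response_kind")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Generate a synthetic cohort from the Avrami risk curve
#'
#' Builds a registry-style cumulative incidence table: ages are converted
#' to mean oncogenic mutation counts at `rate` mutations per year, the
#' noiseless response is the Avrami risk `C (1 - exp(-alpha m^k))`, and
#' noise is added either as additive Gaussian error on the cumulative
#' counts (default) or as Poisson noise on the per-age-band increments,
#' re-accumulated (`noise = "poisson_increment"`, closer to how a registry
#' actually accrues cases). Responses are truncated at zero;
#' `monotonize = TRUE` additionally enforces a nondecreasing cumulative
#' curve via a running maximum.
#'
#' The default design — 12 age points spanning 30 to 85 years — mirrors
#' the span over which gastric-cancer cumulative incidence is informative.
#'
#' @param params An [avrami_params()] object (use `scale` for the cohort's
#'   case-count ceiling).
#' @param rate Mutations-per-year rate (default 0.053).
#' @param ages Strictly increasing ages in years (default 12 points,
#'   30--85).
#' @param noise_sd Standard deviation of the Gaussian noise, in response
#'   units (default 0 = noiseless; ignored for Poisson-increment noise).
#' @param noise `"gaussian"` (default) or `"poisson_increment"`.
#' @param monotonize Enforce a nondecreasing response (default `FALSE`).
#' @param seed Optional integer seed; identical seeds give identical
#'   datasets.
#' @return A `"cohort"` data frame.
#' @examples
#' generate_cohort(avrami_params(0.0087, 4.4, 155), noise_sd = 2, seed = 1)
#' @export
generate_cohort <- function(params, rate = 0.053,
                            ages = seq(30, 85, length.out = 12),
                            noise_sd = 0, noise = c("gaussian",
                                                    "poisson_increment"),
                            monotonize = FALSE, seed = NULL) {
  params <- as_avrami_params(params)
  noise <- match.arg(noise)
  ages <- check_nonneg_vector(ages, "ages")
  if (length(ages) > 1 && is.unsorted(ages, strictly = TRUE)) {
    stop("`ages` must be strictly increasing", call. = FALSE)
  }
  noise_sd <- check_scalar(noise_sd, "noise_sd", lower = 0)
  m <- mutations_from_age(ages, rate)
  mean_response <- avrami_risk(m, params)
  response <- with_seed(seed, {
    if (noise == "gaussian") {
      if (noise_sd > 0) {
        pmax(0, mean_response + stats::rnorm(length(ages), 0, noise_sd))
      } else {
        mean_response
      }
    } else {
      increments <- diff(c(0, mean_response))
      cumsum(stats::rpois(length(ages), pmax(increments, 0)))
    }
  })
  if (monotonize) response <- cummax(response)
  # noise on cumulative counts breaks monotonicity by design here, so the
  # cohort constructor's monotonicity warning is muffled for generated data
  withCallingHandlers(
    cohort(age = ages, response = response, rate = rate,
           response_kind = "cumulative_cases"),
    warning = function(w) {
      if (grepl("nondecreasing", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated table (dot decimal, header required) and maps
#' its columns onto the cohort structure. At least one of the age and
#' mutation-count columns must be present; a missing axis is filled in
#' from the rate. Validation errors name the offending column or row.
#'
#' @param path Path to the CSV file.
#' @param column_map Named character vector mapping cohort fields to file
#'   columns, e.g. `c(age = "age", mutations = "mutations",
#'   response = "response")` (the default). Entries for absent columns may
#'   be dropped.
#' @param rate Mutations-per-year rate used to fill a missing axis
#'   (default 0.053).
#' @param response_kind Passed to [cohort()].
#' @return A `"cohort"` data frame.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path,
                            column_map = c(age = "age",
                                           mutations = "mutations",
                                           response = "response"),
                            rate = 0.053,
                            response_kind = "cumulative_cases") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  get_col <- function(field, required = FALSE) {
    colname <- column_map[[field]]
    if (is.null(colname) || !colname %in% names(raw)) {
      if (required) {
        stop("required column `", if (is.null(colname)) field else colname,
             "` is missing from ", path, call. = FALSE)
      }
      return(NULL)
    }
    col <- raw[[colname]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0) {
      stop("non-numeric value in column `", colname, "` at data row ",
           bad[1], " of ", path, call. = FALSE)
    }
    num
  }
  response <- get_col("response", required = TRUE)
  age <- get_col("age")
  mutations <- get_col("mutations")
  if (is.null(age) && is.null(mutations)) {
    stop("need at least one of the age / mutations columns in ", path,
         call. = FALSE)
  }
  neg <- which(response < 0)
  if (length(neg) > 0) {
    stop("negative response at data row ", neg[1], " of ", path,
         call. = FALSE)
  }
  out <- cohort(age = age, mutations = mutations, response = response,
                rate = rate, response_kind = response_kind)
  message(sprintf("read %d cohort rows from %s", nrow(out), path))
  out
}

#' Write a cohort table to CSV
#'
#' Writes `age,mutations,response` with full double precision (17
#' significant digits), so that a read/write round trip reproduces the
#' values bit-exactly.
#'
#' @param data A `"cohort"` data frame (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  stopifnot(is.data.frame(data))
  cols <- c("age", "mutations", "response")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("`data` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  lines <- paste(cols, collapse = ",")
  if (nrow(data) > 0) {
    fmt <- vapply(cols, function(cl) {
      formatC(data[[cl]], format = "g", digits = 17)
    }, character(nrow(data)))
    fmt <- matrix(fmt, nrow = nrow(data))
    lines <- c(lines, apply(fmt, 1, paste, collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
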