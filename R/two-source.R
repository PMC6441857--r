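#' Two-source capture counts
#'
#' Sufficient statistics for two-list capture-recapture: the first-list size
#' `n1`, the second-list size `n2`, and the overlap `m` (individuals on both
#' lists).
#'
#' @param n1,n2 list sizes (non-negative integers).
#' @param m overlap count, `0 <= m <= min(n1, n2)`.
#' @return An object of class `two_source_counts`.
#' @export
two_source_counts <- function(n1, n2, m) {
  vals <- c(n1 = n1, n2 = n2, m = m)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("n1, n2 and m must be non-negative integers")
  }
  if (m > min(n1, n2)) {
    stop("overlap m = ", m, " exceeds min(n1, n2) = ", min(n1, n2),
         ": inconsistent capture data")
  }
  structure(as.list(stats::setNames(as.integer(round(vals)), names(vals))),
            class = "two_source_counts")
}

#' Lincoln-Petersen two-source estimator
#'
#' The classical two-list estimator `N-hat = n1 * n2 / m`, with the Wald 95%
#' interval from `var(N-hat) = n1 * n2 * (n1 - m) * (n2 - m) / m^3`. A
#' log-transformed interval (`ci = "log"`) is available since the sampling
#' distribution is right-skewed at small `m`. Undefined when the lists do
#' not overlap (`m = 0`).
#'
#' @param counts a [two_source_counts()].
#' @param ci `"wald"` (default) or `"log"`.
#' @param conf confidence level.
#' @return An [estimate_result()].
#' @examples
#' lincoln_petersen(two_source_counts(200, 100, 20))  # 1000
#' @export
lincoln_petersen <- function(counts, ci = c("wald", "log"), conf = 0.95) {
  ci <- match.arg(ci)
  stopifnot(inherits(counts, "two_source_counts"))
  n1 <- as.numeric(counts$n1); n2 <- as.numeric(counts$n2)
  m <- as.numeric(counts$m)
  if (m < 1) {
    stop("no overlap between lists (m = 0): ",
         "Lincoln-Petersen estimate is undefined/infinite")
  }
  Nhat <- n1 * n2 / m
  v <- n1 * n2 * (n1 - m) * (n2 - m) / m^3
  interval <- cr_interval(Nhat, v, ci, conf, floor_at = n1 + n2 - m)
  estimate_result(paste0("Lincoln-Petersen (", ci, " CI)"), Nhat,
                  interval[1], interval[2], conf,
                  inputs = list(n1 = n1, n2 = n2, m = m, ci_method = ci))
}

#' Chapman bias-corrected two-source estimator
#'
#' The small-sample bias-corrected variant of Lincoln-Petersen,
#' `N-hat = (n1 + 1)(n2 + 1)/(m + 1) - 1`, finite for all valid counts
#' including `m = 0`, with
#' `var = (n1+1)(n2+1)(n1-m)(n2-m) / ((m+1)^2 (m+2))`.
#' Chapman never exceeds Lincoln-Petersen when both are defined.
#'
#' @inheritParams lincoln_petersen
#' @return An [estimate_result()].
#' @examples
#' chapman(two_source_counts(200, 100, 20))  # 965.71
#' @export
chapman <- function(counts, ci = c("wald", "log"), conf = 0.95) {
  ci <- match.arg(ci)
  stopifnot(inherits(counts, "two_source_counts"))
  n1 <- as.numeric(counts$n1); n2 <- as.numeric(counts$n2)
  m <- as.numeric(counts$m)
  Nhat <- (n1 + 1) * (n2 + 1) / (m + 1) - 1
  v <- (n1 + 1) * (n2 + 1) * (n1 - m) * (n2 - m) / ((m + 1)^2 * (m + 2))
  interval <- cr_interval(Nhat, v, ci, conf, floor_at = n1 + n2 - m)
  estimate_result(paste0("Chapman (", ci, " CI)"), Nhat,
                  interval[1], interval[2], conf,
                  inputs = list(n1 = n1, n2 = n2, m = m, ci_method = ci))
}

# Wald or log-scale interval about Nhat; never below the number of distinct
# individuals actually observed (floor_at)
cr_interval <- function(Nhat, v, ci, conf, floor_at = 0) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(v)
  if (ci == "log" && Nhat > 0 && se > 0) {
    s <- sqrt(log(1 + v / Nhat^2))
    c(max(floor_at, Nhat / exp(z * s)), Nhat * exp(z * s))
  } else {
    c(max(floor_at, Nhat - z * se), Nhat + z * se)
  }
}

#' Two-source counts from a distribution round and an RDS survey
#'
#' Treats the object distribution as list 1 (`n1` = number of objects given
#' out) and the survey as list 2 (`n2` = survey size), with the overlap `m`
#' equal to the number of survey participants whose indicator shows they
#' received the object. Counts are unweighted: capture-recapture formulas use
#' raw list sizes, while degree weighting is reserved for multiplier
#' proportions.
#'
#' @param sample RDS sample (see [as_rds_sample()]).
#' @param distributed number of objects distributed (list-1 size).
#' @param indicator 0/1 column of `sample` marking receipt of the object.
#' @return A [two_source_counts()].
#' @export
pair_counts_from_rds <- function(sample, distributed, indicator) {
  sample <- as_rds_sample(sample)
  if (!indicator %in% names(sample)) {
    stop("no indicator column '", indicator, "' in RDS sample")
  }
  m <- sum(sample[[indicator]])
  two_source_counts(distributed, nrow(sample), m)
}
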