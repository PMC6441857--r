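#' Service / unique-object multiplier estimator
#'
#' Scales a known count `M` from a first capture source (service records, or
#' objects distributed) by the proportion `p` of a representative survey
#' reporting that capture: `N-hat = M / p`. The survey proportion is usually
#' an RDS-II weighted estimate (see [rds2_proportion()]).
#'
#' The default 95% interval is a delta-method interval on `log(N-hat)`
#' (log-normal), which keeps the lower bound positive at small `p`:
#' `var(log N-hat) = var(p) / p^2`. With `ci = "wald"` a symmetric interval
#' from `var(N-hat) = M^2 var(p) / p^4` is used instead; with
#' `ci = "bootstrap"` a percentile interval for `p` (see
#' [bootstrap_proportion_ci()]) is transformed through `M / p`.
#'
#' @param M known count from the first source (>= 0).
#' @param proportion a `weighted_proportion` from [rds2_proportion()], or a
#'   bare number in (0, 1] (then taken as exact, with zero variance).
#' @param ci interval method: `"lognormal"` (default), `"wald"`,
#'   or `"bootstrap"`.
#' @param conf confidence level.
#' @param sample,indicator,replicates,seed passed to
#'   [bootstrap_proportion_ci()] when `ci = "bootstrap"`.
#' @param contamination optional factor in (0, 1] multiplying `M` to discount
#'   service counts inflated by non-members of the population; default 1 (no
#'   adjustment).
#' @return An [estimate_result()] labelled with the multiplier method and CI
#'   choice.
#' @examples
#' p <- rds2_proportion(
#'   data.frame(id = 1:4, degree = rep(2, 4), used = c(1, 1, 0, 0)), "used")
#' multiplier_estimate(100, p)
#' @export
multiplier_estimate <- function(M, proportion,
                                ci = c("lognormal", "wald", "bootstrap"),
                                conf = 0.95, sample = NULL, indicator = NULL,
                                replicates = 2000, seed = 1L,
                                contamination = 1) {
  ci <- match.arg(ci)
  stopifnot(is.numeric(M), length(M) == 1L, M >= 0,
            contamination > 0, contamination <= 1)
  if (is.numeric(proportion)) {
    proportion <- structure(list(estimate = proportion, variance = 0,
                                 n = NA_integer_, scheme = "fixed",
                                 indicator = NA_character_),
                            class = "weighted_proportion")
  }
  stopifnot(inherits(proportion, "weighted_proportion"))
  p <- proportion$estimate
  if (p <= 0) {
    stop("survey proportion is 0: no overlap between the source and the ",
         "survey, multiplier estimate undefined")
  }
  M <- M * contamination
  if (M == 0) {
    warning("source count M is 0; returning degenerate zero estimate")
    return(estimate_result("multiplier", 0, 0, 0, conf,
                           inputs = list(M = 0, p = p)))
  }
  Nhat <- M / p
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (ci == "bootstrap") {
    if (is.null(sample) || is.null(indicator)) {
      stop("ci = 'bootstrap' needs 'sample' and 'indicator'")
    }
    b <- bootstrap_proportion_ci(sample, indicator, replicates, seed, conf,
                                 scheme = proportion$scheme)
    lo <- M / b$ci_high
    hi <- if (b$ci_low > 0) M / b$ci_low else Inf
  } else if (ci == "wald") {
    se <- sqrt(M^2 * proportion$variance / p^4)
    lo <- max(0, Nhat - z * se)
    hi <- Nhat + z * se
  } else {
    se_log <- sqrt(proportion$variance) / p
    lo <- Nhat * exp(-z * se_log)
    hi <- Nhat * exp(z * se_log)
  }
  estimate_result(paste0("multiplier (", proportion$scheme, ", ", ci, " CI)"),
                  Nhat, lo, hi, conf,
                  inputs = list(M = M, p = p, variance = proportion$variance,
                                n = proportion$n, scheme = proportion$scheme,
                                indicator = proportion$indicator,
                                ci_method = ci,
                                contamination = contamination))
}
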