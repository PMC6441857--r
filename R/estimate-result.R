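#' Labelled population-size estimate
#'
#' Common container for every estimator in the package: a method label, a
#' point estimate of the population size, a 95% (by default) uncertainty
#' interval, and the inputs that produced it, so each reported number carries
#' its full provenance.
#'
#' @param method short method label, e.g. `"service multiplier"`.
#' @param estimate point estimate (>= 0).
#' @param ci_low,ci_high interval bounds with `ci_low <= estimate <= ci_high`.
#' @param conf confidence / credibility level, default `0.95`.
#' @param inputs named list summarising the inputs and settings used.
#' @return An object of class `estimate_result`.
#' @export
estimate_result <- function(method, estimate, ci_low, ci_high,
                            conf = 0.95, inputs = list()) {
  stopifnot(is.character(method), length(method) == 1L)
  if (!is.finite(estimate) || estimate < 0) {
    stop("point estimate must be finite and non-negative")
  }
  if (is.finite(ci_low) && is.finite(ci_high)) {
    if (ci_low > ci_high) stop("ci_low must not exceed ci_high")
    # clamp tiny numerical overshoot rather than reject it
    ci_low <- min(ci_low, estimate)
    ci_high <- max(ci_high, estimate)
  }
  structure(list(method = method, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high,
                 conf = conf, inputs = inputs),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s: %.1f (%d%% CI %.1f-%.1f)\n", x$method, x$estimate,
              round(100 * x$conf), x$ci_low, x$ci_high))
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate,
             ci_low = x$ci_low, ci_high = x$ci_high, conf = x$conf,
             stringsAsFactors = FALSE)
}
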