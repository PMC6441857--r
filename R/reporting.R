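#' Reference-population context
#'
#' The denominator against which population-size estimates are expressed as
#' a percentage — typically an official count of females aged 15 to 64 in
#' the study area.
#'
#' @param reference_count positive reference population count.
#' @param reference_year year of the reference estimate.
#' @param area area label, e.g. a city name.
#' @return An object of class `population_context`.
#' @export
population_context <- function(reference_count, reference_year = NA,
                               area = "study area") {
  if (!is.numeric(reference_count) || length(reference_count) != 1L ||
      !is.finite(reference_count) || reference_count <= 0) {
    stop("reference_count must be a single positive number")
  }
  structure(list(reference_count = reference_count,
                 reference_year = reference_year, area = area),
            class = "population_context")
}

#' Estimate as a percentage of the reference population
#'
#' `100 * estimate / reference_count`, rounded to 2 decimals. Values over
#' 100% are returned as computed but flagged with a warning: a hidden
#' population larger than the whole reference population signals a violated
#' closure assumption or a biased estimate, not a plausible size.
#'
#' @param estimate an [estimate_result()] or a bare point estimate.
#' @param context a [population_context()].
#' @param decimals decimal places (default 2).
#' @return rounded percentage.
#' @examples
#' proportion_of_population(5800, population_context(85386))  # 6.79
#' @export
proportion_of_population <- function(estimate, context, decimals = 2) {
  stopifnot(inherits(context, "population_context"))
  point <- if (inherits(estimate, "estimate_result")) estimate$estimate
           else estimate
  stopifnot(is.numeric(point), point >= 0)
  pct <- round(100 * point / context$reference_count, decimals)
  if (pct > 100) {
    warning(sprintf(
      "estimate (%.0f) exceeds the reference population (%.0f): %s%% - ",
      point, context$reference_count, format(pct)),
      "the closed-population assumption is likely violated")
  }
  pct
}

#' Assemble estimates into a study report
#'
#' One row per estimation method with the point estimate, its 95% interval
#' and the percentage of the reference population. Rows are ordered
#' deterministically: multipliers first, then two-source pairs, then
#' latent-class (3-source) models, then anything else, stable within group.
#' Rows whose percentage exceeds 100 carry a closure-violation note. No
#' "final" estimate is selected automatically — choosing among divergent
#' methods is an analyst judgement; mark one with `final`.
#'
#' @param estimates list of [estimate_result()] objects.
#' @param context a [population_context()].
#' @param final optional method label of the row the analyst designates as
#'   the final estimate.
#' @return An object of class `study_report`: the report data frame plus
#'   area metadata and per-row input provenance.
#' @export
build_report <- function(estimates, context, final = NULL) {
  stopifnot(inherits(context, "population_context"))
  if (inherits(estimates, "estimate_result")) estimates <- list(estimates)
  if (!length(estimates)) stop("need at least one estimate to report")
  stopifnot(all(vapply(estimates, inherits, logical(1), "estimate_result")))
  rank <- vapply(estimates, function(e) {
    m <- tolower(e$method)
    if (grepl("multiplier", m)) 1L
    else if (grepl("petersen|chapman", m)) 2L
    else if (grepl("nplcm|latent", m)) 3L
    else 4L
  }, integer(1))
  ord <- order(rank, seq_along(estimates))
  estimates <- estimates[ord]
  pct <- vapply(estimates, function(e) {
    suppressWarnings(proportion_of_population(e, context))
  }, numeric(1))
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  df$pct_of_reference <- pct
  df$note <- ifelse(pct > 100, "exceeds reference population", "")
  if (!is.null(final)) {
    if (!final %in% df$method) {
      stop("designated final method '", final, "' is not among the rows")
    }
    df$final <- df$method == final
  }
  if (any(pct > 100)) {
    warning(sum(pct > 100), " estimate(s) exceed the reference population; ",
            "see the 'note' column")
  }
  structure(list(area = context$area,
                 reference_count = context$reference_count,
                 reference_year = context$reference_year,
                 table = df,
                 provenance = lapply(estimates, `[[`, "inputs")),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Population size estimates - %s (reference population %s)\n",
              x$area, format(x$reference_count, big.mark = ",")))
  df <- x$table
  df$estimate <- sprintf("%.0f", df$estimate)
  df$ci <- sprintf("%.0f-%.0f", x$table$ci_low, x$table$ci_high)
  cols <- c("method", "estimate", "ci", "pct_of_reference", "note")
  if ("final" %in% names(df)) cols <- c(cols, "final")
  print(df[cols], row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV and plain text
#'
#' @param report a [build_report()] result.
#' @param dir output directory.
#' @return named vector of written paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(csv = file.path(dir, "report.csv"),
             txt = file.path(dir, "report.txt"))
  utils::write.csv(report$table, paths[["csv"]], row.names = FALSE)
  sink(paths[["txt"]])
  print(report)
  sink()
  paths
}
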