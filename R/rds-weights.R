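#' Validate a respondent-driven-sampling survey sample
#'
#' An RDS sample is a data frame with one row per participant and columns
#' `id`, `degree` (self-reported network size, strictly positive),
#' `recruiter_id` (`NA` for seeds), `wave` (0 for seeds), plus any number of
#' 0/1 indicator columns (service use, object receipt, ...).
#'
#' @param sample data frame as described above.
#' @return the validated sample, invisibly classed as `rds_sample`.
#' @export
as_rds_sample <- function(sample) {
  if (!is.data.frame(sample) || nrow(sample) == 0L) {
    stop("RDS sample must be a non-empty data frame")
  }
  need <- c("id", "degree")
  miss <- setdiff(need, names(sample))
  if (length(miss)) stop("RDS sample lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(sample$degree) || any(sample$degree <= 0)) {
    stop("all degrees must be strictly positive; degree 0 or missing is an ",
         "error, not imputed (see 'impute_degrees')")
  }
  if (anyDuplicated(sample$id)) stop("duplicate participant id(s) in RDS sample")
  if ("recruiter_id" %in% names(sample)) {
    rec <- sample$recruiter_id
    known <- is.na(rec) | rec == "" | rec %in% sample$id
    if (!all(known)) {
      stop("recruiter id(s) not present in sample: ",
           paste(unique(rec[!known]), collapse = ", "))
    }
  }
  class(sample) <- unique(c("rds_sample", class(sample)))
  invisible(sample)
}

#' Replace non-positive or missing degrees by the sample median
#'
#' Off by default everywhere: degree imputation changes the weights, so it
#' must be an explicit analyst decision.
#'
#' @param sample RDS sample data frame.
#' @return sample with imputed degrees.
#' @export
impute_degrees <- function(sample) {
  bad <- is.na(sample$degree) | sample$degree <= 0
  if (any(bad)) {
    med <- stats::median(sample$degree[!bad])
    if (!is.finite(med)) stop("no valid degrees to impute from")
    sample$degree[bad] <- med
    message("imputed ", sum(bad), " degree(s) with sample median ", med)
  }
  sample
}

#' RDS-II (inverse-degree) weighted proportion
#'
#' The RDS-II estimator weights each participant inversely to their reported
#' network degree, `p-hat = sum(x_i / d_i) / sum(1 / d_i)`, which corrects
#' for the over-representation of well-connected individuals in a referral
#' sample. With `scheme = "unweighted"` the raw sample proportion is
#' returned. The variance is the Hajek ratio-estimator linearisation
#' `sum(w_i^2 (x_i - p)^2) / (sum w_i)^2` with `w_i = 1/d_i`, which reduces
#' to `p(1-p)/n` when all degrees are equal.
#'
#' @param sample RDS sample (see [as_rds_sample()]).
#' @param indicator name of a 0/1 column of `sample`.
#' @param scheme `"rds2"` (default) or `"unweighted"`.
#' @return An object of class `weighted_proportion`: list with `estimate`,
#'   `variance`, `n`, `scheme`, `indicator`.
#' @examples
#' s <- data.frame(id = 1:3, degree = c(1, 2, 4), tested = c(1, 0, 1))
#' rds2_proportion(s, "tested")$estimate  # (1 + 1/4) / (1 + 1/2 + 1/4)
#' @export
rds2_proportion <- function(sample, indicator,
                            scheme = c("rds2", "unweighted")) {
  scheme <- match.arg(scheme)
  sample <- as_rds_sample(sample)
  if (!indicator %in% names(sample)) {
    stop("no indicator column '", indicator, "' in RDS sample")
  }
  x <- sample[[indicator]]
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop("indicator '", indicator, "' must be 0/1 with no missing values")
  }
  w <- if (scheme == "rds2") 1 / sample$degree else rep(1, nrow(sample))
  p <- sum(w * x) / sum(w)
  v <- sum(w^2 * (x - p)^2) / sum(w)^2
  structure(list(estimate = p, variance = v, n = nrow(sample),
                 scheme = scheme, indicator = indicator),
            class = "weighted_proportion")
}

#' @export
print.weighted_proportion <- function(x, ...) {
  cat(sprintf("%s proportion of '%s': %.4f (var %.3g, n = %d)\n",
              x$scheme, x$indicator, x$estimate, x$variance, x$n))
  invisible(x)
}

#' Chain-respecting bootstrap interval for a survey proportion
#'
#' Resamples whole recruitment chains (a seed together with all of its
#' descendants) with replacement, recomputes the weighted proportion in each
#' replicate, and reports the percentile interval. Resampling chains rather
#' than individuals respects the dependence that referral recruitment induces
#' within a chain. When the sample carries no recruitment structure
#' (`recruiter_id` column absent), it falls back to an individual-level
#' bootstrap with a warning.
#'
#' @inheritParams rds2_proportion
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed; fixed seed gives identical intervals.
#' @param conf interval level, default 0.95.
#' @return list with `ci_low`, `ci_high`, `conf`, `replicates`, `estimate`
#'   (the full-sample point estimate) and `scheme`.
#' @export
bootstrap_proportion_ci <- function(sample, indicator, replicates = 2000,
                                    seed = 1L, conf = 0.95,
                                    scheme = c("rds2", "unweighted")) {
  scheme <- match.arg(scheme)
  stopifnot(replicates >= 1)
  sample <- as_rds_sample(sample)
  point <- rds2_proportion(sample, indicator, scheme)
  if (!"recruiter_id" %in% names(sample)) {
    warning("sample has no recruiter structure; ",
            "falling back to individual-level bootstrap")
    chain <- seq_len(nrow(sample))
  } else {
    chain <- chain_of(sample$id, sample$recruiter_id)
  }
  x <- sample[[indicator]]
  w <- if (scheme == "rds2") 1 / sample$degree else rep(1, nrow(sample))
  groups <- split(seq_len(nrow(sample)), chain)
  ng <- length(groups)
  reps <- with_local_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      idx <- unlist(groups[sample.int(ng, ng, replace = TRUE)],
                    use.names = FALSE)
      sum(w[idx] * x[idx]) / sum(w[idx])
    }, numeric(1))
  })
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(ci_low = qs[1], ci_high = qs[2], conf = conf,
       replicates = replicates, estimate = point$estimate, scheme = scheme)
}

# map each participant to the seed (chain root) of its recruitment tree
chain_of <- function(id, recruiter_id) {
  recruiter_id[recruiter_id %in% c("", NA)] <- NA
  parent <- match(recruiter_id, id)
  root <- seq_along(id)
  repeat {
    nxt <- ifelse(is.na(parent[root]), root, parent[root])
    if (all(nxt == root)) break
    root <- nxt
  }
  root
}

# evaluate expr under a temporary RNG state seeded with 'seed'
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
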