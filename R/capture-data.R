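#' Capture-profile tables
#'
#' A capture table stores, for `J` named capture sources, the counts of the
#' `2^J - 1` observable (non-zero) capture profiles. A profile is written as a
#' `J`-character bitstring in the declared source order, e.g. `"110"` for
#' individuals seen by the first two sources only. Source order is declared
#' once and never inferred from data, so columns cannot silently misalign
#' across captures.
#'
#' @param sources character vector of unique, non-empty source labels.
#' @param counts named non-negative integer vector; names are profile
#'   bitstrings over `sources`. Profiles not named are taken to be zero. The
#'   all-zero profile is unobservable and is rejected.
#' @return An object of class `capture_table`: a list with elements `sources`
#'   and `counts` (the full `2^J - 1` cell vector in canonical binary order).
#' @examples
#' capture_table(c("keychain", "bangle"), c("10" = 5, "01" = 3, "11" = 2))
#' @export
capture_table <- function(sources, counts) {
  if (!is.character(sources) || length(sources) < 1L ||
      anyNA(sources) || any(!nzchar(sources))) {
    stop("'sources' must be a character vector of non-empty labels")
  }
  if (anyDuplicated(sources)) {
    stop("duplicate source labels: ",
         paste(unique(sources[duplicated(sources)]), collapse = ", "))
  }
  J <- length(sources)
  cells <- capture_profiles(J)
  full <- stats::setNames(integer(length(cells)), cells)
  if (length(counts)) {
    if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
      stop("'counts' must be named by profile bitstrings")
    }
    bad <- setdiff(names(counts), cells)
    if (length(bad)) {
      stop("invalid capture profile(s) for ", J, " sources: ",
           paste(bad, collapse = ", "))
    }
    if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
      stop("profile counts must be non-negative integers")
    }
    full[names(counts)] <- as.integer(round(counts))
  }
  structure(list(sources = sources, counts = full), class = "capture_table")
}

#' All observable capture profiles for J sources
#'
#' Bitstrings of length `J` excluding the all-zero profile, in increasing
#' binary order with the last source as the least significant bit.
#'
#' @param J number of sources.
#' @return character vector of length `2^J - 1`.
#' @export
capture_profiles <- function(J) {
  stopifnot(J >= 1, J == round(J))
  vapply(seq_len(2^J - 1L), function(v) {
    paste(as.integer(intToBits(v))[J:1], collapse = "")
  }, character(1))
}

#' @export
print.capture_table <- function(x, ...) {
  cat("Capture table:", length(x$sources), "sources (",
      paste(x$sources, collapse = ", "), "),",
      sum(x$counts), "individuals\n")
  print(x$counts)
  invisible(x)
}

#' Aggregate individual capture histories into a capture table
#'
#' @param records data frame with an `id` column and one 0/1 indicator column
#'   per capture source. All-zero rows are unobservable by construction and
#'   are rejected, as are duplicated ids.
#' @param sources source labels; defaults to all columns except `id`, in
#'   their column order.
#' @return A [capture_table()].
#' @examples
#' rec <- data.frame(id = 1:4, keychain = c(1, 1, 0, 1), rds = c(0, 1, 1, 1))
#' aggregate_histories(rec)
#' @export
aggregate_histories <- function(records, sources = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("'records' must be a non-empty data frame of capture histories")
  }
  if (!"id" %in% names(records)) stop("'records' must have an 'id' column")
  if (is.null(sources)) sources <- setdiff(names(records), "id")
  missing_cols <- setdiff(sources, names(records))
  if (length(missing_cols)) {
    stop("indicator column(s) not found: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  ind <- as.matrix(records[sources])
  if (anyNA(ind) || !all(ind %in% c(0, 1))) {
    stop("capture indicators must be exactly 0 or 1")
  }
  profile <- apply(ind, 1L, paste, collapse = "")
  zero <- strrep("0", length(sources))
  if (any(profile == zero)) {
    stop(sum(profile == zero),
         " record(s) have an all-zero capture history; ",
         "never-captured individuals are unobservable")
  }
  tab <- table(profile)
  capture_table(sources, stats::setNames(as.integer(tab), names(tab)))
}

#' Marginal capture count of one source
#'
#' Sum of all cells whose profile includes the given source.
#'
#' @param table a [capture_table()].
#' @param source a source label belonging to the table.
#' @return integer count of individuals captured by `source`.
#' @export
marginal_count <- function(table, source) {
  stopifnot(inherits(table, "capture_table"))
  j <- match(source, table$sources)
  if (is.na(j)) {
    stop("unknown source '", source, "'; table sources are: ",
         paste(table$sources, collapse = ", "))
  }
  has <- substr(names(table$counts), j, j) == "1"
  sum(table$counts[has])
}

#' Distribution-registration tally
#'
#' Bookkeeping counts from one unique-object distribution round: individuals
#' contacted, those who agreed to participate, those newly receiving the
#' object, and those who already had it from an earlier pass. The already /
#' newly split is what the recapture questions key on.
#'
#' @param contacted,agreed,newly_received,already_received non-negative counts.
#' @return An object of class `distribution_tally`.
#' @export
distribution_tally <- function(contacted, agreed, newly_received,
                               already_received) {
  vals <- c(contacted = contacted, agreed = agreed,
            newly_received = newly_received,
            already_received = already_received)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("tally fields must be non-negative integers")
  }
  if (agreed > contacted) stop("'agreed' cannot exceed 'contacted'")
  if (newly_received + already_received > contacted) {
    stop("'newly_received' + 'already_received' cannot exceed 'contacted'")
  }
  structure(as.list(vals), class = "distribution_tally")
}

#' Percentage rate from a distribution tally
#'
#' Reports `100 * numerator / denominator` rounded to a fixed number of
#' decimals, matching the mixed reporting styles of field write-ups (2
#' decimals by default, 1 in some tables).
#'
#' @param tally a [distribution_tally()].
#' @param numerator,denominator field names of `tally`.
#' @param decimals decimal places to round to.
#' @return rounded percentage.
#' @examples
#' t <- distribution_tally(1306, 1306, 1127, 179)
#' tally_rate(t, "newly_received", "contacted")  # 86.29
#' @export
tally_rate <- function(tally, numerator, denominator, decimals = 2) {
  stopifnot(inherits(tally, "distribution_tally"))
  for (f in c(numerator, denominator)) {
    if (!f %in% names(tally)) stop("no tally field named '", f, "'")
  }
  den <- tally[[denominator]]
  if (den <= 0) stop("denominator field '", denominator, "' must be positive")
  round(100 * tally[[numerator]] / den, decimals)
}

#' Read / write capture-history and capture-table files
#'
#' Capture histories are CSV with columns `id,<source1>,<source2>,...` and
#' 0/1 entries; aggregate tables are CSV with columns `profile,count` where
#' `profile` is a J-character bitstring. Header rows are mandatory.
#'
#' @param path file path.
#' @name capture_io
NULL

#' @rdname capture_io
#' @param records capture-history data frame (see [aggregate_histories()]).
#' @export
write_capture_histories <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname capture_io
#' @export
read_capture_histories <- function(path) {
  if (!file.exists(path)) stop("capture-history file not found: ", path)
  utils::read.csv(path, check.names = FALSE)
}

#' @rdname capture_io
#' @param table a [capture_table()].
#' @export
write_capture_table <- function(table, path) {
  stopifnot(inherits(table, "capture_table"))
  df <- data.frame(profile = names(table$counts),
                   count = unname(table$counts))
  hdr <- paste0("# sources: ", paste(table$sources, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname capture_io
#' @param sources optional source labels when the file carries none.
#' @export
read_capture_table <- function(path, sources = NULL) {
  if (!file.exists(path)) stop("capture-table file not found: ", path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# sources:")) {
    file_sources <- strsplit(trimws(sub("^# sources:", "", first)), ",")[[1]]
    if (is.null(sources)) sources <- trimws(file_sources)
    df <- utils::read.csv(path, comment.char = "#",
                          colClasses = c("character", "integer"))
  } else {
    df <- utils::read.csv(path, colClasses = c("character", "integer"))
  }
  if (!all(c("profile", "count") %in% names(df))) {
    stop("capture-table file must have columns 'profile' and 'count': ", path)
  }
  J <- nchar(df$profile[1])
  if (is.null(sources)) sources <- paste0("source", seq_len(J))
  capture_table(sources, stats::setNames(df$count, df$profile))
}
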