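#' Configuration of the synthetic hidden-population world
#'
#' Describes a closed population of known size with latent-class
#' heterogeneous capture probabilities across named capture sources, a
#' service-use indicator, a degree distribution for the referral network,
#' and the respondent-driven-sampling (RDS) design, plus knobs that
#' deliberately violate the classical capture-recapture conditions (open
#' population, between-source behavioural dependence).
#'
#' Defaults emulate a border-town-scale study: a population of 2700 with two
#' latent classes of high- and low-visibility members, three capture sources
#' (two object distributions and an RDS survey) whose expected margins are
#' roughly 565, 540 and 405, service coverage of 8%, and an RDS design with
#' 7 seeds, 3 coupons and a target of 408 interviews.
#'
#' @param true_size population size `N` (>= 1).
#' @param sources character labels of the capture sources, in capture order.
#' @param class_weights probability vector over the latent classes (sums
#'   to 1 within 1e-9).
#' @param capture_probs `K x J` matrix of per-class per-source capture
#'   probabilities in `[0, 1]` (rows = classes).
#' @param service_coverage probability a member used the service.
#' @param degree_mean,degree_dispersion mean and negative-binomial
#'   dispersion of network degrees; degrees are `1 + NegBinom`, hence >= 1.
#' @param rds_seeds,rds_coupons,rds_target number of RDS seeds, coupons per
#'   participant, and target sample size.
#' @param rds_replace_seeds add fresh seeds when all chains die out before
#'   the target is reached (default `FALSE`: chains simply end).
#' @param turnover open-population fraction: each member leaves after the
#'   first capture round with this probability and is replaced by a new
#'   arrival only exposed to the later rounds. 0 (default) keeps the
#'   population closed.
#' @param dependence behavioural-dependence coefficient: log-odds tilt on
#'   second-source capture for individuals captured by the first source.
#'   Positive values emulate "once captured, easier to capture again".
#' @param seed RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(true_size = 2700,
                             sources = c("keychain", "bangle", "rds"),
                             class_weights = c(0.5, 0.5),
                             capture_probs = rbind(c(0.32, 0.31, 0.23),
                                                   c(0.10, 0.09, 0.07)),
                             service_coverage = 0.08,
                             degree_mean = 10, degree_dispersion = 2,
                             rds_seeds = 7, rds_coupons = 3,
                             rds_target = 408,
                             rds_replace_seeds = FALSE,
                             turnover = 0, dependence = 0,
                             seed = 1L) {
  stopifnot(true_size >= 1, true_size == round(true_size))
  capture_probs <- rbind(capture_probs)
  K <- length(class_weights); J <- length(sources)
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stop("class_weights must sum to 1 (within 1e-9)")
  }
  if (any(class_weights < 0)) stop("class_weights must be non-negative")
  if (!all(dim(capture_probs) == c(K, J))) {
    stop("capture_probs must be a ", K, " x ", J,
         " matrix (classes x sources)")
  }
  if (anyNA(capture_probs) || any(capture_probs < 0 | capture_probs > 1)) {
    stop("capture probabilities must lie in [0, 1]")
  }
  stopifnot(service_coverage >= 0, service_coverage <= 1,
            degree_mean >= 1, degree_dispersion > 0,
            rds_seeds >= 1, rds_coupons >= 0, rds_target >= 1,
            turnover >= 0, turnover < 1)
  structure(list(true_size = as.integer(true_size), sources = sources,
                 class_weights = class_weights,
                 capture_probs = capture_probs,
                 service_coverage = service_coverage,
                 degree_mean = degree_mean,
                 degree_dispersion = degree_dispersion,
                 rds_seeds = as.integer(rds_seeds),
                 rds_coupons = as.integer(rds_coupons),
                 rds_target = as.integer(rds_target),
                 rds_replace_seeds = rds_replace_seeds,
                 turnover = turnover, dependence = dependence,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate the hidden population and its capture events
#'
#' Each individual draws a latent class, then independent Bernoulli capture
#' indicators per source with the class's probabilities. A positive
#' `dependence` coefficient tilts the second source's capture log-odds
#' upward for individuals the first source captured. A non-zero `turnover`
#' opens the population: leavers are uncapturable after round 1 and are
#' replaced by arrivals uncapturable in round 1.
#'
#' @param config a [synthetic_config()].
#' @return An object of class `synthetic_truth`: data frame with columns
#'   `id`, `class`, one 0/1 column per source, `service_used` and `degree`;
#'   attributes carry the config and `true_size`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  N <- config$true_size
  J <- length(config$sources)
  K <- length(config$class_weights)
  with_local_seed(config$seed, {
    n_arrive <- if (config$turnover > 0) stats::rbinom(1L, N, config$turnover)
                else 0L
    total <- N + n_arrive
    cls <- sample.int(K, total, replace = TRUE, prob = config$class_weights)
    x <- matrix(0L, total, J)
    for (j in seq_len(J)) {
      pj <- config$capture_probs[cls, j]
      if (j == 2L && config$dependence != 0) {
        tilt <- stats::plogis(stats::qlogis(pmin(pmax(pj, 1e-12), 1 - 1e-12)) +
                                config$dependence * x[, 1L])
        pj <- ifelse(x[, 1L] == 1L, tilt, pj)
      }
      x[, j] <- stats::rbinom(total, 1L, pj)
    }
    if (config$turnover > 0) {
      resident <- seq_len(N)
      leaver <- resident[stats::runif(N) < config$turnover]
      if (J >= 2) x[leaver, 2:J] <- 0L        # gone after round 1
      if (n_arrive > 0) x[N + seq_len(n_arrive), 1L] <- 0L  # not yet present
    }
    service <- stats::rbinom(total, 1L, config$service_coverage)
    degree <- 1L + stats::rnbinom(total, size = config$degree_dispersion,
                                  mu = config$degree_mean - 1)
    truth <- data.frame(id = sprintf("P%05d", seq_len(total)),
                        class = cls, x, service_used = service,
                        degree = degree, stringsAsFactors = FALSE)
    names(truth)[2L + seq_len(J)] <- config$sources
    attr(truth, "config") <- config
    attr(truth, "true_size") <- N
    class(truth) <- c("synthetic_truth", class(truth))
    truth
  })
}

#' Simulate a respondent-driven-sampling survey over the population
#'
#' Builds a configuration-model network from the individuals' degrees
#' (self-loops and multi-edges dropped), seeds the survey with uniformly
#' chosen members, and recruits wave by wave: each participant passes up to
#' `rds_coupons` coupons to unrecruited network neighbours chosen uniformly
#' at random, until the target sample size is reached or every chain dies
#' out. No individual is recruited twice. Seeds are replenished after
#' exhaustion only when `rds_replace_seeds` is set.
#'
#' @param truth a [simulate_population()] result.
#' @param config the same [synthetic_config()] (its `seed` is offset
#'   internally so the survey randomness is independent of the capture
#'   randomness).
#' @return the RDS sample as per [as_rds_sample()]: columns `id`, `degree`,
#'   `recruiter_id`, `wave`, `service_used` and the source indicator
#'   columns of `truth`.
#' @export
simulate_rds <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "synthetic_config"))
  n_pop <- nrow(truth)
  if (config$rds_target > n_pop) {
    stop("RDS target (", config$rds_target,
         ") exceeds the population size (", n_pop, ")")
  }
  with_local_seed(config$seed + 1000003L, {
    deg <- truth$degree
    if (sum(deg) %% 2 == 1) deg[1L] <- deg[1L] + 1L  # even total for pairing
    g <- igraph::simplify(igraph::sample_degseq(deg, method = "configuration"))
    adj <- igraph::as_adj_list(g)
    sampled <- logical(n_pop)
    pick_seeds <- function(k) {
      avail <- which(!sampled)
      avail[sample.int(length(avail), min(k, length(avail)))]
    }
    rows <- list()
    frontier <- pick_seeds(config$rds_seeds)
    sampled[frontier] <- TRUE
    for (s in frontier) {
      rows[[length(rows) + 1L]] <- c(s, NA_integer_, 0L)
    }
    wave <- 0L
    repeat {
      if (sum(sampled) >= config$rds_target || length(frontier) == 0L) {
        if (length(frontier) == 0L && config$rds_replace_seeds &&
            sum(sampled) < config$rds_target && any(!sampled)) {
          frontier <- pick_seeds(config$rds_seeds)
          sampled[frontier] <- TRUE
          for (s in frontier) {
            rows[[length(rows) + 1L]] <- c(s, NA_integer_, 0L)
          }
          wave <- 0L
          next
        }
        break
      }
      wave <- wave + 1L
      nxt <- integer(0)
      for (r in frontier) {
        if (sum(sampled) + length(nxt) >= config$rds_target) break
        nb <- as.integer(adj[[r]])
        nb <- nb[!sampled[nb]]
        if (!length(nb)) next
        take <- min(config$rds_coupons, length(nb),
                    config$rds_target - sum(sampled) - length(nxt))
        if (take <= 0) break
        rec <- nb[sample.int(length(nb), take)]
        sampled[rec] <- TRUE
        for (s in rec) rows[[length(rows) + 1L]] <- c(s, r, wave)
        nxt <- c(nxt, rec)
      }
      frontier <- nxt
    }
    m <- do.call(rbind, rows)
    out <- data.frame(id = truth$id[m[, 1L]],
                      degree = truth$degree[m[, 1L]],
                      recruiter_id = ifelse(is.na(m[, 2L]), NA_character_,
                                            truth$id[m[, 2L]]),
                      wave = m[, 3L],
                      service_used = truth$service_used[m[, 1L]],
                      stringsAsFactors = FALSE)
    for (src in attr(truth, "config")$sources) {
      out[[src]] <- truth[[src]][m[, 1L]]
    }
    out <- as_rds_sample(out)
    out
  })
}

#' Write the synthetic study files
#'
#' Emits the exact file formats the estimators consume: a capture-history
#' CSV of the observed (captured-at-least-once) individuals, the aggregate
#' capture-profile table, the RDS survey CSV, and a plain-JSON truth file
#' recording the true size for recovery tests. If an RDS sample is supplied
#' and one source is named `"rds"`, that source's indicator in the emitted
#' capture histories is the realised survey membership rather than the
#' simulated propensity draw.
#'
#' @param truth a [simulate_population()] result.
#' @param rds_sample optional [simulate_rds()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths.
#' @export
emit_study_files <- function(truth, rds_sample = NULL, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  cfg <- attr(truth, "config")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  hist <- truth[c("id", cfg$sources)]
  if (!is.null(rds_sample) && "rds" %in% cfg$sources) {
    hist$rds <- as.integer(hist$id %in% rds_sample$id)
  }
  observed <- hist[rowSums(hist[cfg$sources]) > 0, , drop = FALSE]
  paths <- c(histories = file.path(dir, "capture_histories.csv"),
             table = file.path(dir, "capture_table.csv"),
             rds = file.path(dir, "rds.csv"),
             truth = file.path(dir, "truth.json"))
  write_capture_histories(observed, paths[["histories"]])
  write_capture_table(aggregate_histories(observed, cfg$sources),
                      paths[["table"]])
  if (!is.null(rds_sample)) {
    utils::write.csv(rds_sample, paths[["rds"]], row.names = FALSE,
                     quote = FALSE)
  } else {
    paths <- paths[names(paths) != "rds"]
  }
  jsonlite::write_json(list(true_size = attr(truth, "true_size"),
                            seed = cfg$seed,
                            sources = cfg$sources,
                            n_observed = nrow(observed)),
                       paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  paths
}
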