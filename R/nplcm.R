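#' Configuration for the nonparametric latent-class capture-recapture model
#'
#' The model treats each individual's capture history over `J` lists as a
#' product-Bernoulli vector whose per-list capture probabilities depend on a
#' latent class; class weights follow a truncated stick-breaking
#' (Dirichlet-process) prior so the effective number of classes is learned
#' from the data. Heterogeneous capture probability and the list dependence
#' it induces — the classical failure modes of two-source estimators — are
#' absorbed by the mixture.
#'
#' @param max_classes truncation level `K*` (>= 1; `K* = 1` collapses the
#'   model to the homogeneous M0 model). Default `NULL` resolves at fit time
#'   to `min(2^J - 1, 10)`.
#' @param alpha_prior shape and rate of the Gamma prior on the
#'   Dirichlet-process concentration; default `c(0.25, 0.25)`.
#' @param lambda_prior Beta prior on each capture probability; default
#'   `c(1, 1)` (uniform).
#' @param iterations total Gibbs iterations (default 100000).
#' @param burn_in iterations discarded (default 10000; must be < iterations).
#' @param thinning keep every `thinning`-th draw (default 10).
#' @param seed RNG seed; fixed seed gives bit-identical chains.
#' @return An object of class `nplcm_config`.
#' @export
nplcm_config <- function(max_classes = NULL, alpha_prior = c(0.25, 0.25),
                         lambda_prior = c(1, 1), iterations = 100000,
                         burn_in = 10000, thinning = 10, seed = 1L) {
  if (!is.null(max_classes)) {
    stopifnot(max_classes >= 1, max_classes == round(max_classes))
  }
  stopifnot(length(alpha_prior) == 2, all(alpha_prior > 0),
            length(lambda_prior) == 2, all(lambda_prior > 0),
            iterations > burn_in, burn_in >= 0, thinning >= 1)
  structure(list(max_classes = max_classes, alpha_prior = alpha_prior,
                 lambda_prior = lambda_prior,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning), seed = as.integer(seed)),
            class = "nplcm_config")
}

#' Draw the number of never-captured individuals
#'
#' Under the improper `1/N` size prior, the full conditional of the number
#' of all-zero-history individuals `n0` given `n` observed individuals and a
#' zero-history probability `p0` is negative binomial:
#' `n0 ~ NegBinom(size = n, prob = 1 - p0)`. When `p0 = 0` (some list is
#' certain to capture everyone) this forces `n0 = 0`.
#'
#' @param n observed count (>= 1).
#' @param p0 probability of an all-zero capture history, in `[0, 1)`.
#' @return one draw of `n0`.
#' @export
sample_unobserved_count <- function(n, p0) {
  stopifnot(n >= 1, p0 >= 0, p0 < 1)
  stats::rnbinom(1L, size = n, prob = 1 - p0)
}

#' Fit the nonparametric latent-class capture-recapture model
#'
#' Gibbs sampler over: class assignments of observed individuals (by
#' capture profile); the never-captured count `n0` (negative-binomial
#' conditional implied by the `1/N` size prior); class assignments of the
#' `n0` zero-history individuals; capture probabilities (Beta full
#' conditionals); stick-breaking fractions (Beta) and the Dirichlet-process
#' concentration (Gamma full conditional).
#'
#' @param table a [capture_table()] over `J >= 2` sources (warns at `J = 2`,
#'   where the latent-class model is weakly identified).
#' @param config an [nplcm_config()].
#' @return An object of class `nplcm_posterior`: retained draws of
#'   `N = n + n0`, `alpha`, class weights `pi` (matrix, draws x K*) and
#'   capture probabilities `lambda` (array, draws x K* x J), plus the
#'   observed count `n`, source labels, the resolved config, and an
#'   effective-sample-size diagnostic for `N`.
#' @export
fit_nplcm <- function(table, config = nplcm_config()) {
  stopifnot(inherits(table, "capture_table"), inherits(config, "nplcm_config"))
  J <- length(table$sources)
  if (J < 2) stop("latent-class capture-recapture needs at least 2 sources")
  if (J == 2) {
    warning("with only 2 sources the latent-class model is weakly ",
            "identified; interpret the posterior with caution")
  }
  n <- sum(table$counts)
  if (n < 1) stop("capture table holds no observed individuals")
  if (sum(table$counts > 0) == 1L) {
    warning("all individuals share a single capture profile; the posterior ",
            "for N is unlikely to be well behaved")
  }
  K <- if (is.null(config$max_classes)) min(2^J - 1L, 10L) else
    as.integer(config$max_classes)
  cfg <- config
  cfg$max_classes <- K

  # profile design matrix (P x J) and observed cell counts
  X <- do.call(rbind, lapply(strsplit(names(table$counts), ""), as.integer))
  cnt <- unname(table$counts)
  keep <- cnt > 0  # zero cells contribute nothing to the allocation step
  Xo <- X[keep, , drop = FALSE]
  co <- cnt[keep]
  P <- nrow(Xo)

  a_l <- config$lambda_prior[1]; b_l <- config$lambda_prior[2]
  a_a <- config$alpha_prior[1];  b_a <- config$alpha_prior[2]

  n_keep <- (config$iterations - config$burn_in) %/% config$thinning
  draw_N <- integer(n_keep)
  draw_alpha <- numeric(n_keep)
  draw_pi <- matrix(0, n_keep, K)
  draw_lambda <- array(0, c(n_keep, K, J))

  with_local_seed(config$seed, {
    # initial state: uniform weights, capture probabilities at the pooled rate
    lambda <- matrix(pmin(pmax(colSums(cnt * X) / n, 0.05), 0.95),
                     K, J, byrow = TRUE)
    V <- rep(1 / K, K); V[K] <- 1
    pi_k <- stick_weights(V)
    alpha <- 1
    kept <- 0L
    for (it in seq_len(config$iterations)) {
      lg1 <- log(lambda); lg0 <- log1p(-lambda)
      # class log-likelihood of each observed profile: K x P
      L <- lg1 %*% t(Xo) + lg0 %*% t(1 - Xo) + log(pi_k)
      W <- exp(sweep(L, 2L, apply(L, 2L, max)))  # guard against underflow
      # class allocation of observed individuals, profile by profile
      A <- matrix(0L, K, P)
      for (p in seq_len(P)) {
        A[, p] <- stats::rmultinom(1L, co[p], W[, p])
      }
      # never-captured count and its class split
      zero_lik <- exp(rowSums(lg0))           # P(all-zero | class k)
      p0 <- sum(pi_k * zero_lik)
      p0 <- min(p0, 1 - 1e-12)
      n0 <- sample_unobserved_count(n, p0)
      n0k <- if (n0 > 0) {
        drop(stats::rmultinom(1L, n0, pi_k * zero_lik))
      } else integer(K)
      # conjugate updates
      nk <- rowSums(A) + n0k
      s <- A %*% Xo                            # K x J capture tallies
      lambda <- matrix(stats::rbeta(K * J, a_l + s, b_l + (nk - s)), K, J)
      tail_n <- rev(cumsum(rev(nk)))           # nk + all later classes
      V <- stats::rbeta(K, 1 + nk, alpha + tail_n - nk)
      V[K] <- 1
      V <- pmin(V, 1 - 1e-12); V[K] <- 1
      pi_k <- stick_weights(V)
      alpha <- stats::rgamma(1L, a_a + K - 1,
                             b_a - sum(log1p(-V[-K])))
      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thinning == 0L) {
        kept <- kept + 1L
        draw_N[kept] <- n + n0
        draw_alpha[kept] <- alpha
        draw_pi[kept, ] <- pi_k
        draw_lambda[kept, , ] <- lambda
      }
    }
  })

  structure(list(N = draw_N, alpha = draw_alpha, pi = draw_pi,
                 lambda = draw_lambda, n = n, sources = table$sources,
                 config = cfg,
                 diagnostics = list(ess_N = effective_size(draw_N))),
            class = "nplcm_posterior")
}

# pi_k = V_k * prod_{l<k} (1 - V_l); remainder closed by V_K = 1
stick_weights <- function(V) {
  K <- length(V)
  V * c(1, cumprod(1 - V[-K]))
}

# effective sample size by initial positive autocorrelation truncation
effective_size <- function(x) {
  M <- length(x)
  if (M < 10 || stats::var(x) == 0) return(as.numeric(M))
  ac <- stats::acf(x, lag.max = min(M - 1, 200), plot = FALSE)$acf[-1]
  cut <- which(ac <= 0)
  if (length(cut)) ac <- ac[seq_len(cut[1] - 1)]
  max(1, M / (1 + 2 * sum(ac)))
}

#' @export
print.nplcm_posterior <- function(x, ...) {
  q <- stats::quantile(x$N, c(0.025, 0.5, 0.975), names = FALSE)
  cat(sprintf(
    "NPLCM posterior: n = %d observed, %d retained draws (ESS %.0f)\n",
    x$n, length(x$N), x$diagnostics$ess_N))
  cat(sprintf("  N median %.0f, 95%% CrI %.0f-%.0f\n", q[2], q[1], q[3]))
  invisible(x)
}

#' Summarise an NPLCM posterior as a labelled estimate
#'
#' Point estimate is the posterior median; the interval is the central 95%
#' credible interval (asymmetry of the posterior is preserved, so the upper
#' arm is typically longer than the lower one).
#'
#' @param post an `nplcm_posterior` from [fit_nplcm()].
#' @param conf credibility level, default 0.95.
#' @return An [estimate_result()] labelled `"3-source NPLCM"` (or the actual
#'   number of sources).
#' @export
summarize_posterior <- function(post, conf = 0.95) {
  stopifnot(inherits(post, "nplcm_posterior"))
  if (length(post$N) < 100) {
    stop("too few retained draws (", length(post$N),
         "); need at least 100 for a stable summary")
  }
  qs <- stats::quantile(post$N,
                        c((1 - conf) / 2, 0.5, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  estimate_result(paste0(length(post$sources), "-source NPLCM"),
                  qs[2], qs[1], qs[3], conf,
                  inputs = list(n = post$n, sources = post$sources,
                                mean = mean(post$N),
                                ess = post$diagnostics$ess_N,
                                config = unclass(post$config)))
}

#' Posterior predictive check of the fitted capture model
#'
#' Simulates capture-profile tables from retained posterior draws and
#' compares each observed cell count against its 95% predictive interval.
#' Cells outside their interval flag model misfit (e.g. dependence structure
#' that the fitted number of classes cannot absorb).
#'
#' @param post an `nplcm_posterior`.
#' @param table the observed [capture_table()] the model was fitted to.
#' @param draws number of posterior draws to simulate from (default: up to
#'   500, subsampled evenly).
#' @param seed RNG seed for the predictive simulations.
#' @return data frame with one row per observable profile: observed count,
#'   predictive 2.5/50/97.5 percentiles and an `outside` flag.
#' @export
posterior_predictive_check <- function(post, table, draws = 500, seed = 1L) {
  stopifnot(inherits(post, "nplcm_posterior"), inherits(table, "capture_table"))
  M <- length(post$N)
  use <- unique(round(seq(1, M, length.out = min(draws, M))))
  X <- do.call(rbind, lapply(strsplit(names(table$counts), ""), as.integer))
  P <- nrow(X)
  K <- ncol(post$pi)
  rep_counts <- matrix(0L, length(use), P)
  with_local_seed(seed, {
    for (r in seq_along(use)) {
      d <- use[r]
      Nk <- drop(stats::rmultinom(1L, post$N[d], post$pi[d, ]))
      lam <- matrix(post$lambda[d, , ], K, length(post$sources))
      # cell probabilities for every observable profile, per class
      cellp <- exp(log(lam) %*% t(X) + log1p(-lam) %*% t(1 - X))  # K x P
      for (k in which(Nk > 0)) {
        pk <- c(cellp[k, ], 1 - sum(cellp[k, ]))  # last = zero profile
        pk[pk < 0] <- 0
        draw <- drop(stats::rmultinom(1L, Nk[k], pk))
        rep_counts[r, ] <- rep_counts[r, ] + draw[seq_len(P)]
      }
    }
  })
  qs <- apply(rep_counts, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  obs <- unname(table$counts)
  data.frame(profile = names(table$counts), observed = obs,
             pred_low = qs[1, ], pred_median = qs[2, ], pred_high = qs[3, ],
             outside = obs < qs[1, ] | obs > qs[3, ],
             stringsAsFactors = FALSE)
}
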