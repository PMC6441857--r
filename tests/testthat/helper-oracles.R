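# Independent oracles and small fixture builders shared across tests.

# Brute-force homogeneous-model (M0) maximum-likelihood estimate of N by
# 1-D profile likelihood over an integer grid. Independent of the package's
# samplers: uses only the observed count n and the total capture tally.
m0_profile_mle <- function(table, N_max = NULL) {
  J <- length(table$sources)
  n <- sum(table$counts)
  caps <- vapply(names(table$counts),
                 function(pr) sum(as.integer(strsplit(pr, "")[[1]])),
                 numeric(1))
  C <- sum(caps * table$counts)  # total captures over all lists
  if (is.null(N_max)) N_max <- 10L * n
  Ns <- n:N_max
  ll <- vapply(Ns, function(N) {
    p <- C / (N * J)
    lgamma(N + 1) - lgamma(N - n + 1) + C * log(p) + (N * J - C) * log1p(-p)
  }, numeric(1))
  Ns[which.max(ll)]
}

# Hand-coded RDS fixture: n_chains chains of identical length, constant
# degree, i.i.d. indicator draws; recruiter links form each chain.
chain_fixture <- function(n_chains, chain_len, p, degree = 5, seed = 42) {
  n <- n_chains * chain_len
  ids <- sprintf("c%03dm%02d", rep(seq_len(n_chains), each = chain_len),
                 rep(seq_len(chain_len), n_chains))
  recruiter <- ifelse(rep(seq_len(chain_len), n_chains) == 1, NA_character_,
                      sprintf("c%03dm%02d",
                              rep(seq_len(n_chains), each = chain_len),
                              rep(seq_len(chain_len), n_chains) - 1))
  set.seed(seed)
  data.frame(id = ids, degree = degree, recruiter_id = recruiter,
             wave = rep(seq_len(chain_len) - 1L, n_chains),
             y = rbinom(n, 1, p), stringsAsFactors = FALSE)
}

# Exhaustive tally of capture profiles straight from an indicator matrix;
# the independent check for aggregate_histories().
brute_profile_counts <- function(ind) {
  profs <- apply(ind, 1, paste, collapse = "")
  table(profs)
}
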