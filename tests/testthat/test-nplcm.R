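# small helper: a quick homogeneous 3-source table from fixed seed
sim_table <- function(N, p, seed, J = 3) {
  set.seed(seed)
  x <- matrix(rbinom(N * J, 1, p), N, J)
  x <- x[rowSums(x) > 0, , drop = FALSE]
  rec <- data.frame(id = seq_len(nrow(x)), x)
  names(rec)[-1] <- paste0("s", seq_len(J))
  aggregate_histories(rec)
}

test_that("the never-captured draw is forced to zero at p0 = 0", {
  expect_equal(sample_unobserved_count(100, 0), 0)
  expect_error(sample_unobserved_count(100, 1), "p0 < 1")
  set.seed(1)
  draws <- replicate(500, sample_unobserved_count(50, 0.4))
  # NegBinom(size = n, prob = 1 - p0) has mean n * p0 / (1 - p0)
  expect_lt(abs(mean(draws) - 50 * 0.4 / 0.6) / (50 * 0.4 / 0.6), 0.2)
})

test_that("posterior summaries follow the percentile definitions", {
  post <- structure(list(N = rep(500, 200), alpha = numeric(200),
                         pi = matrix(1, 200, 1),
                         lambda = array(0.5, c(200, 1, 3)),
                         n = 400, sources = c("a", "b", "c"),
                         config = nplcm_config(max_classes = 1),
                         diagnostics = list(ess_N = 200)),
                    class = "nplcm_posterior")
  s <- summarize_posterior(post)
  expect_equal(c(s$estimate, s$ci_low, s$ci_high), c(500, 500, 500))

  post$N <- 1:1000
  post$pi <- matrix(1, 1000, 1)
  post$lambda <- array(0.5, c(1000, 1, 3))
  s2 <- summarize_posterior(post)
  expect_equal(s2$estimate, 500.5)
  expect_equal(s2$ci_low, 25.975)
  expect_equal(s2$ci_high, 975.025)

  post$N <- post$N[1:50]
  expect_error(summarize_posterior(post), "too few")
})

test_that("right-skewed posteriors keep their asymmetry in the summary", {
  set.seed(77)
  post <- structure(list(N = round(400 + 100 * rlnorm(1000, 0, 1)),
                         alpha = numeric(1000), pi = matrix(1, 1000, 1),
                         lambda = array(0.5, c(1000, 1, 3)), n = 400,
                         sources = c("a", "b", "c"),
                         config = nplcm_config(max_classes = 1),
                         diagnostics = list(ess_N = 1000)),
                    class = "nplcm_posterior")
  s <- summarize_posterior(post)
  expect_gt(s$ci_high - s$estimate, s$estimate - s$ci_low)
})

test_that("posterior median agrees with the brute-force M0 oracle on
           homogeneous data", {
  tab <- sim_table(N = 1000, p = 0.3, seed = 42)
  mle <- m0_profile_mle(tab)
  fit <- fit_nplcm(tab, nplcm_config(iterations = 20000, burn_in = 4000,
                                     thinning = 4, seed = 11))
  med <- stats::median(fit$N)
  expect_lt(abs(med - mle) / mle, 0.10)
  expect_true(all(fit$N >= sum(tab$counts)))
})

test_that("forcing one class collapses the sampler to the M0 model", {
  tab <- sim_table(N = 400, p = 0.35, seed = 13)
  mle <- m0_profile_mle(tab)
  fit <- fit_nplcm(tab, nplcm_config(max_classes = 1, iterations = 8000,
                                     burn_in = 2000, thinning = 2, seed = 3))
  expect_lt(abs(stats::median(fit$N) - mle) / mle, 0.10)
  # with a single class every stick weight draw is exactly 1
  expect_true(all(fit$pi == 1))
})

test_that("stick-breaking weights form a probability vector in every draw", {
  tab <- sim_table(N = 300, p = 0.3, seed = 5)
  fit <- fit_nplcm(tab, nplcm_config(max_classes = 5, iterations = 2000,
                                     burn_in = 500, thinning = 2, seed = 9))
  expect_true(all(abs(rowSums(fit$pi) - 1) < 1e-12))
  expect_true(all(fit$pi >= 0 & fit$pi <= 1))
  expect_true(all(fit$lambda >= 0 & fit$lambda <= 1))
})

test_that("the posterior for N is invariant to source order", {
  tab <- sim_table(N = 500, p = 0.3, seed = 23)
  # permute source order: rebuild the table with columns swapped
  perm <- c(3, 1, 2)
  counts2 <- tab$counts
  names(counts2) <- vapply(strsplit(names(tab$counts), ""),
                           function(b) paste(b[perm], collapse = ""),
                           character(1))
  tab2 <- capture_table(tab$sources[perm], counts2)
  cfg <- nplcm_config(iterations = 12000, burn_in = 2000, thinning = 2,
                      seed = 7)
  q1 <- stats::quantile(fit_nplcm(tab, cfg)$N, c(0.25, 0.5, 0.75))
  q2 <- stats::quantile(fit_nplcm(tab2, cfg)$N, c(0.25, 0.5, 0.75))
  expect_true(all(abs(q1 - q2) / q1 < 0.05))
})

test_that("fits are bit-reproducible under a fixed seed", {
  tab <- sim_table(N = 300, p = 0.3, seed = 31)
  cfg <- nplcm_config(iterations = 1500, burn_in = 300, thinning = 2,
                      seed = 41)
  expect_identical(fit_nplcm(tab, cfg)$N, fit_nplcm(tab, cfg)$N)
})

test_that("degenerate and weakly identified inputs warn", {
  tab1 <- capture_table(c("a", "b", "c"), c("111" = 50))
  expect_warning(fit_nplcm(tab1, nplcm_config(iterations = 300,
                                              burn_in = 100, seed = 1)),
                 "single capture profile")
  tab2 <- capture_table(c("a", "b"), c("10" = 30, "01" = 25, "11" = 10))
  expect_warning(fit_nplcm(tab2, nplcm_config(iterations = 300,
                                              burn_in = 100, seed = 1)),
                 "weakly")
  expect_error(nplcm_config(iterations = 100, burn_in = 100), "iterations")
})

test_that("near-perfect detection pins the posterior close to n", {
  # one list captures (nearly) everyone: few individuals can be missing
  tab <- capture_table(c("a", "b", "c"),
                       c("100" = 300, "110" = 100, "101" = 100, "111" = 100))
  fit <- fit_nplcm(tab, nplcm_config(iterations = 4000, burn_in = 1000,
                                     thinning = 2, seed = 2))
  n <- sum(tab$counts)
  expect_lt(stats::median(fit$N) / n - 1, 0.05)
})

test_that("posterior predictive checks pass on well-specified data and
           flag forced misspecification", {
  tab <- sim_table(N = 600, p = 0.3, seed = 55)
  fit <- fit_nplcm(tab, nplcm_config(iterations = 6000, burn_in = 1000,
                                     thinning = 2, seed = 6))
  ppc <- posterior_predictive_check(fit, tab, draws = 300, seed = 8)
  expect_true(all(c("profile", "observed", "pred_low", "pred_high",
                    "outside") %in% names(ppc)))
  expect_gte(mean(!ppc$outside), 0.9)

  # strongly dependent two-class world squeezed into one class
  cfg <- synthetic_config(true_size = 3000, class_weights = c(0.5, 0.5),
                          capture_probs = rbind(c(0.85, 0.85, 0.85),
                                                c(0.04, 0.04, 0.04)),
                          seed = 64)
  truth <- simulate_population(cfg)
  obs <- truth[rowSums(truth[cfg$sources]) > 0, ]
  tab2 <- aggregate_histories(obs[c("id", cfg$sources)], cfg$sources)
  fit2 <- fit_nplcm(tab2, nplcm_config(max_classes = 1, iterations = 6000,
                                       burn_in = 1000, thinning = 2,
                                       seed = 6))
  ppc2 <- posterior_predictive_check(fit2, tab2, draws = 300, seed = 8)
  expect_gte(sum(ppc2$outside), 1)
})
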