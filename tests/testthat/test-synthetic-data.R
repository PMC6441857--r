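test_that("zero capture probability captures nobody", {
  cfg <- synthetic_config(true_size = 500, class_weights = 1,
                          capture_probs = rbind(c(0, 0, 0)), seed = 2)
  truth <- simulate_population(cfg)
  expect_equal(sum(truth[cfg$sources]), 0)
})

test_that("homogeneous capture matches the closed-form coverage rate", {
  # K = 1, p = 0.3 on each of 3 lists: P(seen at least once) = 1 - 0.7^3
  cfg <- synthetic_config(true_size = 10000, class_weights = 1,
                          capture_probs = rbind(c(0.3, 0.3, 0.3)), seed = 5)
  truth <- simulate_population(cfg)
  frac <- mean(rowSums(truth[cfg$sources]) > 0)
  p_any <- 1 - 0.7^3
  se <- sqrt(p_any * (1 - p_any) / 10000)
  expect_lt(abs(frac - p_any), 3 * se)
})

test_that("independence holds with the dependence knob off, breaks with it on", {
  cfg <- synthetic_config(true_size = 10000, class_weights = 1,
                          capture_probs = rbind(c(0.3, 0.3, 0.3)),
                          dependence = 0, seed = 8)
  truth <- simulate_population(cfg)
  r12 <- cor(truth[[cfg$sources[1]]], truth[[cfg$sources[2]]])
  expect_lt(abs(r12), 3 / sqrt(10000))
  cfg_dep <- synthetic_config(true_size = 10000, class_weights = 1,
                              capture_probs = rbind(c(0.3, 0.3, 0.3)),
                              dependence = 1.5, seed = 8)
  td <- simulate_population(cfg_dep)
  expect_gt(cor(td[[cfg$sources[1]]], td[[cfg$sources[2]]]), 0.1)
})

test_that("fixed seeds give bit-identical populations and surveys", {
  cfg <- synthetic_config(true_size = 800, rds_target = 150, seed = 33)
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1, t2)
  expect_identical(simulate_rds(t1, cfg), simulate_rds(t2, cfg))
})

test_that("RDS recruitment honours seeds, coupons and the target", {
  cfg <- synthetic_config(true_size = 300, rds_seeds = 1, rds_coupons = 0,
                          rds_target = 50, seed = 4)
  truth <- simulate_population(cfg)
  s <- simulate_rds(truth, cfg)
  expect_equal(nrow(s), 1L)           # no coupons: the seed is the sample
  expect_true(all(is.na(s$recruiter_id)))

  cfg2 <- synthetic_config(true_size = 4000, rds_seeds = 9, rds_coupons = 3,
                           rds_target = 835, seed = 4)
  t2 <- simulate_population(cfg2)
  s2 <- simulate_rds(t2, cfg2)
  expect_lte(nrow(s2), 835)
  expect_gte(max(s2$wave), 1)
  expect_false(anyDuplicated(s2$id) > 0)        # without replacement
  # every participant recruits at most 'coupons' others
  expect_lte(max(table(s2$recruiter_id[!is.na(s2$recruiter_id)])), 3)
  # recruiters joined on an earlier wave than their recruits
  ix <- match(s2$recruiter_id, s2$id)
  ok <- is.na(ix) | s2$wave == s2$wave[ix] + 1
  expect_true(all(ok))

  expect_error(simulate_rds(truth, synthetic_config(true_size = 300,
                                                    rds_target = 301)),
               "exceeds the population")
})

test_that("equal degrees make the weighted and raw RDS proportions equal", {
  cfg <- synthetic_config(true_size = 1500, degree_mean = 6,
                          degree_dispersion = 1e9, rds_target = 300, seed = 6)
  truth <- simulate_population(cfg)
  truth$degree <- 6L  # constant-degree network
  s <- simulate_rds(truth, cfg)
  expect_equal(rds2_proportion(s, "service_used")$estimate,
               mean(s$service_used))
})

test_that("emitted study files round-trip and record the truth", {
  cfg <- synthetic_config(true_size = 600, rds_target = 120, seed = 12)
  truth <- simulate_population(cfg)
  rds <- simulate_rds(truth, cfg)
  dir <- withr::local_tempdir()
  paths <- emit_study_files(truth, rds, dir)
  expect_true(all(file.exists(paths)))
  tab <- read_capture_table(paths[["table"]])
  hist <- read_capture_histories(paths[["histories"]])
  expect_identical(tab$counts, aggregate_histories(hist, cfg$sources)$counts)
  expect_identical(tab$sources, cfg$sources)
  tr <- jsonlite::read_json(paths[["truth"]])
  expect_equal(tr$true_size, 600L)
  # realised survey membership is the third capture
  expect_equal(marginal_count(tab, "rds"), nrow(rds))
  back <- read.csv(paths[["rds"]])
  expect_equal(nrow(back), nrow(rds))
  expect_equal(rds2_proportion(back, "service_used")$estimate,
               rds2_proportion(rds, "service_used")$estimate)
})

test_that("default world hits the intended capture margins", {
  # expected margins of the default two-class world: ~565 / ~540 / ~405
  cfg <- synthetic_config(seed = 19)
  truth <- simulate_population(cfg)
  expected <- colSums(cfg$class_weights * cfg$capture_probs) * cfg$true_size
  for (j in seq_along(cfg$sources)) {
    got <- sum(truth[[cfg$sources[j]]])
    se <- sqrt(expected[j])  # Poisson-scale sampling error
    expect_lt(abs(got - expected[j]), 4 * se)
  }
})

test_that("turnover opens the population as configured", {
  cfg <- synthetic_config(true_size = 2000, turnover = 0.3, seed = 9)
  truth <- simulate_population(cfg)
  expect_gt(nrow(truth), 2000)          # arrivals appended
  arrivals <- truth[-(1:2000), ]
  expect_equal(sum(arrivals[[cfg$sources[1]]]), 0)  # not exposed to round 1
})

test_that("configs with invalid probabilities are rejected", {
  expect_error(synthetic_config(class_weights = c(0.6, 0.6)), "sum to 1")
  expect_error(synthetic_config(capture_probs = rbind(c(1.2, 0.1, 0.1),
                                                      c(0.1, 0.1, 0.1))),
               "\\[0, 1\\]")
  expect_error(synthetic_config(true_size = 0), "true_size")
})
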