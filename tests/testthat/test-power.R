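test_that("the quarterly two-year schedule has sum of squared times 3.75", {
  des <- trial_design()
  expect_equal(des$visit_times, seq(0, 2, 0.25))
  expect_equal(sum((des$visit_times - mean(des$visit_times))^2), 3.75)
  ss <- slope_sample_size(variance_components(1.5, 0.5, 2), des, 0.3)
  expect_equal(ss$sum_sq_time, 3.75)
})

test_that("sample size scales inversely with the squared effect", {
  vc <- variance_components(1.5, 0.5, 2)
  des <- trial_design()
  n1 <- slope_sample_size(vc, des, 0.4)$n_per_arm
  n2 <- slope_sample_size(vc, des, 0.2)$n_per_arm
  expect_gt(n2 / n1, 3.85)  # 4x up to ceiling effects
  expect_lt(n2 / n1, 4.15)
})

test_that("sample size is monotone in effect size and variance components", {
  des <- trial_design()
  n_by_e <- sapply(c(0.2, 0.3, 0.4, 0.5), function(e)
    slope_sample_size(variance_components(1.5, 0.5, 2), des, e)$n_per_arm)
  expect_true(all(diff(n_by_e) < 0))
  n_by_v <- sapply(c(0.2, 0.5, 1), function(v)
    slope_sample_size(variance_components(1.5, v, 2), des, 0.3)$n_per_arm)
  expect_true(all(diff(n_by_v) > 0))
  n_by_r <- sapply(c(1, 2, 4), function(v)
    slope_sample_size(variance_components(1.5, 0.5, v), des, 0.3)$n_per_arm)
  expect_true(all(diff(n_by_r) > 0))
  expect_error(slope_sample_size(variance_components(0, 0.5, 2), des, 0.3),
               "positive")
})

test_that("null trials reject at the nominal rate", {
  vc <- variance_components(1.5, 0.5, 2, intercept_var = 4)
  des <- trial_design()
  mp <- monte_carlo_power(vc, des, effect = 1e-9, n_per_arm = 40, reps = 300,
                          seed = 11)
  expect_lt(abs(mp$power - des$alpha), 2.5 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("doubling the sample size increases empirical power", {
  vc <- variance_components(1.5, 0.5, 2, intercept_var = 4)
  des <- trial_design()
  n <- slope_sample_size(vc, des, 0.4)$n_per_arm
  p1 <- monte_carlo_power(vc, des, 0.4, n, reps = 250, seed = 12)$power
  p2 <- monte_carlo_power(vc, des, 0.4, 2 * n, reps = 250, seed = 12)$power
  expect_gt(p2, p1)
})

test_that("variance components are recovered from simulated trajectories", {
  set.seed(13)
  n <- 400
  t <- seq(0, 2, 0.5)
  nv <- length(t)
  b0 <- rnorm(n, 5, 2); b1 <- rnorm(n, 1.2, 0.6)
  df <- data.frame(subject_id = rep(seq_len(n), each = nv),
                   time = rep(t, n),
                   sara = rep(b0, each = nv) + rep(b1, each = nv) *
                     rep(t, n) + rnorm(nv * n, 0, 0.5))
  vc <- estimate_variance_components(df)
  expect_lt(abs(vc$mean_slope - 1.2), 0.1)
  expect_lt(abs(vc$slope_var - 0.36), 0.08)
  expect_lt(abs(vc$residual_var - 0.25), 0.03)
})

test_that("enrichment sweep accounts for screen failures exactly", {
  co <- shared_cohort()
  stages <- shared_baseline_stages()
  cl1 <- co$clinical[co$clinical$visit_index == 1, ]
  bl <- data.frame(subject_id = stages$subject_id, stage = stages$stage,
                   age = cl1$age[match(stages$subject_id, cl1$subject_id)],
                   sara = cl1$sara[match(stages$subject_id, cl1$subject_id)])
  sl <- co$clinical[, c("subject_id", "time", "sara")]
  des <- trial_design()
  es <- enrichment_sweep(bl, sl, des, effect = 0.3, cutoffs = c(0, 4, 9))
  # cut-off 0 is the identity scenario
  expect_equal(es$screen_failure_rate[es$cutoff == 0], 0)
  expect_equal(es$sample_size_reduction[es$cutoff == 0], 0)
  # screen-failure rate equals the empirical CDF of baseline stage
  for (j in es$cutoff)
    expect_equal(es$screen_failure_rate[es$cutoff == j],
                 100 * mean(bl$stage < j))
  expect_true(all(diff(es$screen_failure_rate) >= 0))
  # the generator couples SARA slope to stage: enrichment shrinks the trial
  expect_lt(es$n_required[es$cutoff == 9], es$n_required[es$cutoff == 0])
  expect_gt(es$mean_slope[es$cutoff == 9], es$mean_slope[es$cutoff == 0])
  # cut-offs above the cohort's stages are refused by the retention rule
  expect_message(es2 <- enrichment_sweep(bl, sl, des, cutoffs = c(0, 30)),
                 "retains")
  expect_false(30 %in% es2$cutoff)
  # age/SARA restriction raises screen failures
  esr <- enrichment_sweep(bl, sl, des, cutoffs = 4,
                          restrict = list(age = c(25, 60), sara = c(3, 18)))
  expect_gt(esr$screen_failure_rate,
            es$screen_failure_rate[es$cutoff == 4])
})
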