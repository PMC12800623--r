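test_that("onset estimation fills only unreported rows and flags provenance", {
  co <- shared_cohort()
  cl <- co$clinical[co$clinical$visit_index == 1, ]
  filled <- estimate_time_from_onset(cl)
  rep_rows <- !is.na(cl$onset_age)
  expect_identical(filled$onset_age[rep_rows], cl$onset_age[rep_rows])
  expect_true(all(filled$onset_source[rep_rows] == "reported"))
  est <- filled$onset_source == "estimated" & !is.na(filled$onset_source)
  expect_true(any(est))
  expect_false(anyNA(filled$time_from_onset[est]))
  # subjects younger than their predicted onset sit pre-onset (negative time)
  young <- est & filled$age < filled$onset_age
  if (any(young)) expect_true(all(filled$time_from_onset[young] < 0))
  # the generating CAG -> onset slope is recovered within its CI
  fit <- attr(filled, "onset_model")
  ci <- confint(fit)["cag_expanded", ]
  expect_gt(co$config$onset_model$cag_slope, ci[1])
  expect_lt(co$config$onset_model$cag_slope, ci[2])
  expect_error(estimate_time_from_onset(cl[is.na(cl$onset_age), ][1:20, ]),
               ">= 10")
})

make_gait_data <- function(n_per = 25, shift = 0, seed = 1) {
  set.seed(seed)
  levels_ <- c("normal", "gait difficulties", "walking aid", "wheelchair")
  do.call(rbind, lapply(seq_along(levels_), function(i) {
    data.frame(stage = rnorm(n_per, 8 + shift * (i - 1), 2),
               gait_status = levels_[i],
               age = rnorm(n_per, 45, 10),
               sex = sample(c("female", "male"), n_per, TRUE),
               stringsAsFactors = FALSE)
  }))
}

test_that("gait ANCOVA detects injected level shifts and not null data", {
  d5 <- make_gait_data(shift = 5, seed = 2)
  res <- stage_by_gait_ancova(d5)
  expect_lt(res$p, 1e-6)
  adjacent <- grepl("normal - gait|gait difficulties - walking|walking aid - wheelchair",
                    res$contrasts$contrast)
  expect_true(all(res$contrasts$p_tukey[adjacent] < 0.05))
  # identical groups: contrast estimates near zero, F not significant
  d0 <- make_gait_data(shift = 0, seed = 3)
  res0 <- stage_by_gait_ancova(d0)
  expect_gt(res0$p, 0.01)
  expect_true(all(abs(res0$contrasts$estimate) < 2))
})

test_that("Tukey adjustment never reports smaller p than the raw contrast", {
  d <- make_gait_data(shift = 1.2, seed = 4)
  res <- stage_by_gait_ancova(d)
  em <- emmeans::emmeans(res$model, ~gait_status)
  raw <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise"),
                               adjust = "none"))
  expect_true(all(res$contrasts$p_tukey >= raw$p.value - 1e-12))
})

test_that("a perfect SARA-stage link yields a standardized beta of one", {
  set.seed(5)
  n <- 120
  d <- data.frame(stage = sample(0:24, n, TRUE),
                  age = rnorm(n, 45, 10),
                  sex = sample(c("female", "male"), n, TRUE),
                  ataxia_status = sample(c("preataxic", "ataxic"), n, TRUE),
                  stringsAsFactors = FALSE)
  d$sara <- 1 + 0.58 * d$stage
  res <- suppressWarnings(stage_regressions(d))  # perfect-fit lm warnings
  whole <- res[res$model == "sara_on_stage_whole", ]
  expect_equal(whole$b, 0.58, tolerance = 1e-8)
  expect_equal(whole$beta, 1, tolerance = 1e-8)
})

test_that("unstandardized and standardized estimates agree in sign and scale", {
  co <- shared_cohort()
  cl <- estimate_time_from_onset(co$clinical[co$clinical$visit_index == 1, ])
  stages <- shared_baseline_stages()
  cl$stage <- stages$stage[match(cl$subject_id, stages$subject_id)]
  res <- stage_regressions(cl)
  has_beta <- !is.na(res$beta)
  expect_true(all(sign(res$b[has_beta]) == sign(res$beta[has_beta]) |
                    res$beta[has_beta] == 0))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  # beta is invariant to affine rescaling of the predictor
  cl2 <- cl
  cl2$stage <- cl2$stage * 10
  res2 <- stage_regressions(cl2)
  w1 <- res[res$model == "sara_on_stage_whole", "beta"]
  w2 <- res2[res2$model == "sara_on_stage_whole", "beta"]
  expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("SARA slope coupling is detectable per group on the default cohort", {
  co <- shared_cohort()
  cl <- co$clinical[co$clinical$visit_index == 1, ]
  stages <- shared_baseline_stages()
  cl$stage <- stages$stage[match(cl$subject_id, stages$subject_id)]
  res <- stage_regressions(cl)
  whole <- res[res$model == "sara_on_stage_whole", ]
  expect_lt(whole$p, 1e-6)
  expect_gt(whole$b, 0.3)  # generator links 0.58 SARA per stage
})
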