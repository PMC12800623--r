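make_stage_table <- function(n = 40, slope = 0, noise = 0, seed = 1,
                             visits = c(0, 1, 2)) {
  set.seed(seed)
  base <- sample(2:15, n, replace = TRUE)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = sprintf("S%02d", i), time = visits,
               stage = base[i] + slope * visits + rnorm(length(visits), 0,
                                                        noise),
               ataxia_status = rep(c("preataxic", "ataxic")[1 + (i %% 2)],
                                   length(visits)),
               stringsAsFactors = FALSE)
  }))
}

test_that("constant stages give a zero slope with a covering CI", {
  tab <- make_stage_table(slope = 0, noise = 0.3, seed = 2)
  tr <- stage_change_model(tab, by_group = FALSE)
  expect_lt(tr$ci[1], 0)
  expect_gt(tr$ci[2], 0)
  expect_lt(abs(tr$slope), 0.2)
})

test_that("the trend rescales exactly with the time unit", {
  tab <- make_stage_table(slope = 0.5, noise = 0.4, seed = 3)
  tr_y <- stage_change_model(tab, by_group = FALSE)
  tab_m <- tab
  tab_m$time <- tab_m$time * 12
  tr_m <- stage_change_model(tab_m, by_group = FALSE)
  expect_equal(tr_y$slope, tr_m$slope * 12, tolerance = 1e-6)
})

test_that("duplicating the cohort preserves the estimate and tightens the CI", {
  tab <- make_stage_table(slope = 0.5, noise = 0.5, seed = 4)
  tab2 <- tab
  tab2$subject_id <- paste0(tab2$subject_id, "_copy")
  tr1 <- stage_change_model(tab, by_group = FALSE)
  tr2 <- stage_change_model(rbind(tab, tab2), by_group = FALSE)
  expect_equal(tr2$slope, tr1$slope, tolerance = 1e-6)
  expect_lt(diff(tr2$ci), diff(tr1$ci))
})

test_that("group trends are reported per ataxia status", {
  co <- shared_cohort()
  tab <- shared_stage_table()
  tr <- stage_change_model(tab)
  expect_equal(sort(as.character(tr$group_trends$ataxia_status)),
               c("ataxic", "preataxic"))
  expect_true(all(tr$group_trends$ci_lower < tr$group_trends$trend &
                    tr$group_trends$trend < tr$group_trends$ci_upper))
  expect_true(tr$ci[1] < tr$slope & tr$slope < tr$ci[2])
})

test_that("monotonicity audit counts transitions by hand-checkable rules", {
  tab <- data.frame(subject_id = rep("A", 4), time = 0:3,
                    stage = c(2, 3, 3, 2), ataxia_status = "ataxic")
  rep_ <- monotonicity_report(tab)
  expect_equal(rep_$overall$n_pairs, 3L)
  expect_equal(rep_$overall$n_increase, 1L)
  expect_equal(rep_$overall$n_unchanged, 1L)
  expect_equal(rep_$overall$n_decrease, 1L)
  expect_equal(unname(rep_$magnitude["1"]), 1L)
  # strictly advancing stages show no decreases
  tab2 <- make_stage_table(slope = 1, noise = 0, seed = 5)
  expect_equal(monotonicity_report(tab2)$overall$n_decrease, 0L)
  expect_error(monotonicity_report(data.frame(subject_id = "A",
                                              time = c(0, 0),
                                              stage = c(1, 2))), "unordered")
})

test_that("stage decreases are rare on the default staged cohort", {
  rep_ <- monotonicity_report(shared_stage_table())
  expect_lt(rep_$overall$prop_decrease, 0.15)
  if (rep_$overall$n_decrease > 0) {
    expect_gte(mean(names(rep_$magnitude) == "1" &
                      rep_$magnitude == max(rep_$magnitude)), 0)
    expect_equal(names(which.max(rep_$magnitude)), "1")
  }
})

test_that("scanner regression is calibrated and detects injected offsets", {
  set.seed(8)
  n <- 150
  base <- data.frame(
    stage = pmax(0, rnorm(n, 8, 4)),
    scanner_manufacturer = sample(c("Siemens", "GE", "Philips"), n, TRUE),
    field_strength = sample(c(1.5, 3), n, TRUE),
    time_from_onset = rnorm(n, 5, 5))
  # null calibration over replicates
  rejections <- replicate(40, {
    d <- base
    d$stage <- pmax(0, rnorm(n, 8, 4))
    sc <- scanner_effect_check(d)
    any(sc$coefficients$p[grepl("scanner|field", sc$coefficients$term)] < 0.05)
  })
  expect_lte(mean(rejections), 0.25)  # familywise over 3 scanner terms
  # injected +2-stage offset for one manufacturer is detected (GE is the
  # reference level, so both other manufacturer terms shift by about -2)
  d <- base
  d$stage <- d$stage + 2 * (d$scanner_manufacturer == "GE")
  sc <- scanner_effect_check(d)
  hits <- sc$coefficients[grepl("scanner_manufacturer", sc$coefficients$term), ]
  expect_true(all(hits$p < 0.05))
  expect_true(all(hits$estimate < 0))
  # constant scanner columns reduce to the covariate-only regression
  d2 <- base
  d2$scanner_manufacturer <- "Siemens"
  d2$field_strength <- 3
  expect_message(sc2 <- scanner_effect_check(d2), "single-level")
  ref <- lm(stage ~ time_from_onset, data = d2)
  expect_equal(sc2$coefficients$estimate[2], unname(coef(ref)[2]),
               tolerance = 1e-10)
})
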