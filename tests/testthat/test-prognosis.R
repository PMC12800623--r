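test_that("the model set enumerates reference, stage and MRI variants", {
  specs <- build_model_set(sca3_regions())
  expect_length(specs, 12L)
  labels <- vapply(specs, `[[`, character(1), "label")
  expect_setequal(labels, c("reference", "stage", sca3_regions(),
                            "all_volumes", "global_roi"))
  one <- build_model_set("pons")
  expect_length(one, 5L)
  expect_true(any(!is.na(vapply(one, `[[`, character(1), "flag"))))
  expect_error(build_model_set(character(0)), "at least one")
  expect_error(build_model_set(c("pons", "pons")), "duplicate")
})

test_that("Nadeau-Bengio correction matches direct formula evaluation", {
  # J = 100 folds with test/train ratio 1/9 inflates 1/J by a factor 12.11
  set.seed(6)
  d <- rnorm(100, 0.3, 1)
  nb <- nadeau_bengio_test(d, n_train = 90, n_test = 10)
  t_direct <- mean(d) / sqrt((1 / 100 + 10 / 90) * var(d))
  expect_equal(nb$t, t_direct, tolerance = 1e-12)
  expect_equal((1 / 100 + 10 / 90) / (1 / 100), 12.11, tolerance = 0.002)
  expect_equal(nb$df, 99)
  # the corrected test is never more liberal than the naive one
  expect_gte(nb$p, nb$p_naive - 1e-12)
  # degenerate branches
  z <- nadeau_bengio_test(rep(0, 10), 9, 1)
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  inf <- nadeau_bengio_test(rep(0.5, 10), 9, 1)
  expect_true(is.infinite(inf$t))
})

shared_prognosis_data <- function() {
  cached("prognosis_data", function() {
    co <- shared_cohort()
    prognosis_data(co$clinical, shared_baseline_stages(), shared_wscores())
  })
}

test_that("atrophy stage gives the largest AIC improvement on coupled data", {
  pd <- shared_prognosis_data()
  specs <- build_model_set(sca3_regions())
  cmp <- fit_and_compare_aic(specs, pd)
  tab <- cmp$table
  expect_equal(tab$delta_aic[tab$label == "reference"], 0)
  expect_lt(tab$delta_aic[tab$label == "stage"],
            min(tab$delta_aic[!tab$label %in% c("stage", "reference")]))
  # the reference model is nested in every MRI spec: ML deviance can only drop
  ll_ref <- as.numeric(logLik(cmp$models$reference))
  for (l in setdiff(tab$label, "reference"))
    expect_gte(as.numeric(logLik(cmp$models[[l]])), ll_ref - 1e-6)
})

test_that("a pure-noise readout earns no AIC support", {
  pd <- shared_prognosis_data()
  set.seed(7)
  noise_by_subj <- setNames(rnorm(length(unique(pd$subject_id))),
                            unique(pd$subject_id))
  pd$w_noise <- noise_by_subj[pd$subject_id]
  specs <- list(list(label = "reference", readouts = character(0),
                     flag = NA_character_),
                list(label = "noise", readouts = "w_noise",
                     flag = NA_character_))
  cmp <- fit_and_compare_aic(specs, pd)
  expect_gte(cmp$table$delta_aic[cmp$table$label == "noise"], -2)
})

test_that("cross-validated RMSE favours the stage model and is reproducible", {
  pd <- shared_prognosis_data()
  specs <- build_model_set(sca3_regions())[c(1, 2, 4)]  # reference/stage/pons
  cv1 <- cv_rmse_max_followup(specs, pd, repeats = 2, folds = 5, seed = 9)
  cv2 <- cv_rmse_max_followup(specs, pd, repeats = 2, folds = 5, seed = 9)
  expect_identical(cv1$rmse, cv2$rmse)
  expect_lt(cv1$rmse["stage"], cv1$rmse["reference"])
  cmp <- compare_rmse(cv1)
  expect_true(all(cmp$p_fdr >= cmp$p - 1e-12))
  expect_true(all(cv1$fold_rmse >= 0, na.rm = TRUE))
})

test_that("the corrected resampled test is calibrated where the naive is not", {
  # two equivalent predictors of null data, repeated CV -> fold differences
  set.seed(10)
  n_sims <- 120
  p_nb <- p_naive <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    n <- 40
    x1 <- rnorm(n); x2 <- rnorm(n); y <- rnorm(n)
    d <- numeric(0)
    for (rep_ in 1:2) {
      fold <- sample(rep_len(1:5, n))
      for (f in 1:5) {
        tr <- fold != f
        m1 <- lm(y ~ x1, data = data.frame(y = y[tr], x1 = x1[tr]))
        m2 <- lm(y ~ x2, data = data.frame(y = y[tr], x2 = x2[tr]))
        e1 <- y[!tr] - predict(m1, data.frame(x1 = x1[!tr]))
        e2 <- y[!tr] - predict(m2, data.frame(x2 = x2[!tr]))
        d <- c(d, sqrt(mean(e1^2)) - sqrt(mean(e2^2)))
      }
    }
    nb <- nadeau_bengio_test(d, n_train = 32, n_test = 8)
    p_nb[s] <- nb$p
    p_naive[s] <- nb$p_naive
  }
  expect_lte(mean(p_nb < 0.05), 0.08)       # at or near nominal alpha
  expect_gt(mean(p_naive < 0.05), mean(p_nb < 0.05))  # naive inflates
})
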