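make_controls <- function(n = 120, seed = 1, age_effects = TRUE) {
  cfg <- cohort_config(n_controls = n, n_patients = 1, seed = seed,
                       volume_model = {
                         vm <- atrostage:::default_volume_model()
                         if (!age_effects) {
                           vm$age_slope <- 0
                           vm$sex_offset <- 0
                           vm$icv_coef <- 0
                         }
                         vm
                       })
  generate_cohort(cfg)$volumes
}

test_that("fitting controls have mean w = 0 and SD = 1 by construction", {
  vol <- make_controls()
  nm <- fit_normative_model(vol)
  w <- compute_wscores(nm, vol[vol$group == "control", ])
  W <- as.matrix(w[, sca3_regions()])
  expect_true(all(abs(colMeans(W)) < 1e-8))
  expect_true(all(abs(apply(W, 2, sd) - 1) < 1e-8))
})

test_that("null covariate effects are recovered on synthetic controls", {
  vol <- make_controls(n = 400, seed = 2, age_effects = FALSE)
  nm <- fit_normative_model(vol)
  vm <- atrostage:::default_volume_model()
  for (r in sca3_regions()) {
    f <- nm$fits[[r]]
    sd_r <- vm$sd[vm$region == r]
    # slopes indistinguishable from zero relative to the noise scale
    expect_lt(abs(f$icv_coefficients["icv"]) * 2 * sd(vol$icv), 0.5 * sd_r)
    expect_lt(abs(f$adjustment_coefficients["age"]) * 2 * sd(vol$age),
              0.5 * sd_r)
    expect_lt(abs(f$residual_sd - sd_r) / sd_r, 0.15)
  }
})

test_that("w-scores are invariant to unit rescaling and row duplication", {
  vol <- make_controls()
  nm1 <- fit_normative_model(vol)
  w1 <- compute_wscores(nm1, vol)
  # unit change: one region in cm^3 everywhere
  vol2 <- vol
  vol2$pons <- vol2$pons / 1000
  nm2 <- fit_normative_model(vol2)
  w2 <- compute_wscores(nm2, vol2)
  expect_equal(w2$pons, w1$pons, tolerance = 1e-10)
  # duplicating every control row leaves coefficients unchanged
  nm3 <- fit_normative_model(rbind(vol, vol))
  expect_equal(nm3$fits$pons$icv_coefficients,
               nm1$fits$pons$icv_coefficients, tolerance = 1e-10)
  expect_equal(nm3$fits$pons$adjustment_coefficients,
               nm1$fits$pons$adjustment_coefficients, tolerance = 1e-10)
})

test_that("degenerate and singular control designs are rejected by name", {
  vol <- make_controls()
  vol$midbrain <- 6000  # constant volume column
  expect_error(fit_normative_model(vol), "midbrain")
  vol2 <- make_controls()
  vol2$sex <- "female"
  expect_error(fit_normative_model(vol2), "single sex")
  expect_error(fit_normative_model(make_controls()[1:10, ]), ">= 20")
})

test_that("held-out controls are calibrated near mean 0, SD 1", {
  vol <- make_controls(n = 750, seed = 4)
  fit_rows <- vol[1:250, ]
  held <- vol[251:750, ]
  nm <- fit_normative_model(fit_rows)
  W <- as.matrix(compute_wscores(nm, held)[, sca3_regions()])
  expect_true(all(abs(colMeans(W)) < 0.15))
  expect_true(all(apply(W, 2, sd) > 0.85 & apply(W, 2, sd) < 1.15))
})

test_that("missing covariates propagate as missing w-scores", {
  vol <- make_controls()
  vol$age[3] <- NA
  nm <- fit_normative_model(vol)
  w <- compute_wscores(nm, vol)
  expect_true(all(is.na(as.numeric(w[3, sca3_regions()]))))
  expect_false(anyNA(as.matrix(w[-3, sca3_regions()])))
})

test_that("a visit lying exactly on both regressions scores w = 0", {
  vol <- make_controls()
  nm <- fit_normative_model(vol)
  f <- nm$fits$pons
  probe <- vol[1, ]
  male <- as.numeric(probe$sex == "male")
  r1_target <- f$adjustment_coefficients[1] +
    f$adjustment_coefficients["age"] * probe$age +
    f$adjustment_coefficients["male"] * male
  probe$pons <- f$icv_coefficients[1] + f$icv_coefficients["icv"] * probe$icv +
    r1_target
  w <- compute_wscores(nm, probe)
  expect_equal(w$pons, 0, tolerance = 1e-10)
})

test_that("summary-statistic Welch test matches t.test on raw data", {
  set.seed(9)
  x <- rnorm(40, 10, 2)
  y <- rnorm(70, 12, 3)
  ref <- t.test(y, x)
  got <- welch_from_summary(mean(x), sd(x), length(x),
                            mean(y), sd(y), length(y))
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})
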