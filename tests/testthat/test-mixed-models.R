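test_that("zscore_columns standardizes with the sample SD and is idempotent", {
  d <- tibble::tibble(x = c(1, 2, 3), y = c(10, 20, 40))
  z <- zscore_columns(d, "x")
  expect_equal(z$x, c(-1, 0, 1))
  expect_lt(max(abs(zscore_columns(z, "x")$x - z$x)), 1e-8)
  expect_error(zscore_columns(tibble::tibble(k = rep(2, 4)), "k"), "'k'")
})

test_that("fixed effects match the OLS oracle when random variances are zero", {
  tab <- simulate_lmm_dataset("b", params = list(sd_pair = 0, sd_lesion = 0,
                                                 sd_control = 0,
                                                 sd_resid = 0.3),
                              seed = 99)
  tab$hemi_lesioned <- as.numeric(tab$hemi_role == "lesioned")
  ols <- stats::lm(pvd ~ hemi_lesioned, data = tab)
  for (est in c("REML", "ML")) {
    fit <- fit_lmm(tab, lmm_spec("pvd", "hemi_lesioned",
                                 random_intercepts = c("pair_id", "lesion_id",
                                                       "control_id"),
                                 estimation = est))
    expect_equal(fit$coefficients$B, unname(coef(ols)), tolerance = 1e-4)
  }
})

test_that("t = B/SE and p = 2*pnorm(-|t|) hold for every coefficient", {
  tab <- simulate_lmm_dataset("b", seed = 3)
  tab$hemi_lesioned <- as.numeric(tab$hemi_role == "lesioned")
  fit <- fit_lmm(tab, lmm_spec("pvd", "hemi_lesioned",
                               random_intercepts = c("pair_id", "lesion_id",
                                                     "control_id")))
  expect_lt(max(abs(fit$coefficients$t -
                      fit$coefficients$B / fit$coefficients$SE)), 1e-10)
  expect_equal(fit$coefficients$p,
               2 * pnorm(-abs(fit$coefficients$t)))
  # normal-approximation anchors
  expect_equal(2 * pnorm(-abs(0)), 1)
  expect_equal(2 * pnorm(-abs(1.959964)), 0.05, tolerance = 1e-4)
})

test_that("the LRT is 2*deltaLogLik with parameter-count df, ML only", {
  tab <- simulate_lmm_dataset("b", seed = 8)
  tab$hemi_lesioned <- as.numeric(tab$hemi_role == "lesioned")
  spec_full <- lmm_spec("pvd", "hemi_lesioned",
                        random_intercepts = c("pair_id", "lesion_id",
                                              "control_id"),
                        estimation = "ML")
  spec_red <- lmm_spec("pvd", "hemi_lesioned", estimation = "ML")
  full <- fit_lmm(tab, spec_full)
  red <- fit_lmm(tab, spec_red)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 3L)
  expect_equal(lrt$chi_square,
               2 * (full$log_likelihood - red$log_likelihood))
  expect_gte(lrt$chi_square, 0)
  expect_equal(lrt$p, pchisq(lrt$chi_square, 3, lower.tail = FALSE))

  reml <- fit_lmm(tab, lmm_spec("pvd", "hemi_lesioned",
                                random_intercepts = "pair_id"))
  expect_error(likelihood_ratio_test(reml, red), "REML")
  expect_error(likelihood_ratio_test(red, red), "more parameters")
})

test_that("a null random structure yields a chi-square near zero", {
  tab <- simulate_lmm_dataset("b", params = list(sd_pair = 0, sd_lesion = 0,
                                                 sd_control = 0,
                                                 sd_resid = 0.3),
                              seed = 12)
  hb <- hypothesis_b(tab, "cortex")
  expect_lt(hb$lrt$chi_square, 4)
  expect_gte(hb$lrt$chi_square, 0)
})

test_that("hypothesis (a) uses the maximal crossed structure with df 5", {
  tab <- simulate_lmm_dataset("a", seed = 21)
  ha <- hypothesis_a(tab, "cortex", "both")
  # 2 variances + 1 covariance for the pair slope/intercept + 2 crossed
  # intercept variances
  expect_equal(ha$lrt$df, 5L)
  expect_match(ha$reml$formula, "case_sim \\| pair_id")
  expect_match(ha$reml$formula, "\\(1 \\| lesion_id\\)")
  # subset models drop the random slope
  has <- hypothesis_a(tab, "cortex", "lesioned")
  expect_equal(has$lrt$df, 3L)
  expect_false(grepl("case_sim \\|", has$reml$formula))
})

test_that("hypothesis (b) is intercepts-only with df 3 and recovers its effect", {
  tab <- simulate_lmm_dataset("b", seed = 31)
  hb <- hypothesis_b(tab, "cwm")
  expect_equal(hb$lrt$df, 3L)
  b <- hb$reml$coefficients
  est <- b$B[b$term == "hemi_lesioned"]
  se <- b$SE[b$term == "hemi_lesioned"]
  expect_lt(abs(est - 0.14), 4 * se)
})

test_that("a zero contrast gives a zero coefficient", {
  # identical volumes for simulated and ground truth
  tab <- simulate_lmm_dataset("a", seed = 41)
  tab2 <- tab |>
    dplyr::group_by(pair_id, hemi_role) |>
    dplyr::mutate(volume_mm3 = volume_mm3[case == "ground_truth"]) |>
    dplyr::ungroup()
  ha <- hypothesis_a(tab2, "cortex", "both")
  expect_lt(abs(ha$reml$coefficients$B[2]), 1e-8)

  # a hemisphere-exchangeable PVD table: every pair appears once as
  # observed and once with the hemisphere labels swapped, so the
  # hemisphere coefficient is zero by symmetry
  tb <- simulate_lmm_dataset("b", seed = 42)
  swapped <- tb |>
    dplyr::mutate(
      hemi_role = ifelse(hemi_role == "lesioned", "contralesional",
                         "lesioned"),
      pair_id = paste0(pair_id, "_sw")
    )
  hb <- hypothesis_b(dplyr::bind_rows(tb, swapped), "cortex")
  expect_lt(abs(hb$reml$coefficients$B[2]), 1e-8)
})

test_that("hypothesis (c) has no lesion grouping and recovers covariate slopes", {
  tab <- simulate_lmm_dataset("c", seed = 51)
  chars <- dplyr::distinct(tab, lesion_id, volume_z, mean_intensity_z,
                           sd_intensity_z)
  names(chars)[2:4] <- c("volume_mm3", "mean_intensity_ui",
                         "sd_intensity_ui")
  hc <- hypothesis_c(tab, chars, "cortex", "lesioned")
  expect_false(grepl("lesion_id", hc$reml$formula))
  expect_match(hc$reml$formula, "\\(1 \\| control_id\\)")
  b <- hc$reml$coefficients
  expect_lt(abs(b$B[b$term == "volume_z"] - 0.28),
            4 * b$SE[b$term == "volume_z"])
  expect_error(hypothesis_c(tab, chars[-1, ], "cortex", "lesioned"),
               "missing")
})

test_that("tidy and glance expose broom-shaped summaries", {
  tab <- simulate_lmm_dataset("b", seed = 61)
  hb <- hypothesis_b(tab, "cortex")
  td <- tidy(hb)
  expect_setequal(
    names(td),
    c("hypothesis", "measure", "hemisphere", "term", "estimate",
      "std.error", "statistic", "p.value")
  )
  gl <- glance(hb)
  expect_equal(gl$lrt_df, 3L)
  vt <- tidy(hb$reml, effects = "ran_pars")
  expect_true(all(c("pair_id", "lesion_id", "control_id", "residual") %in%
                    vt$group))
})
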