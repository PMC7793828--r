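seg_row <- function(id = "s", lhc = 100, rhc = 90, lhw = 80, rhw = 70) {
  tibble::tibble(subject_id = id, lh_cortex_mm3 = lhc, rh_cortex_mm3 = rhc,
                 lh_cwm_mm3 = lhw, rh_cwm_mm3 = rhw,
                 segmenter = "mock", mode = "local")
}

test_that("hemisphere recoding maps laterality onto roles and is an involution", {
  r <- seg_row()
  lh <- recode_hemispheres(r, "lh")
  expect_equal(lh$volume_mm3[lh$hemi_role == "lesioned" &
                               lh$measure == "cortex"], 100)
  expect_equal(lh$volume_mm3[lh$hemi_role == "contralesional" &
                               lh$measure == "cortex"], 90)
  rh <- recode_hemispheres(r, "rh")
  expect_equal(rh$volume_mm3[rh$hemi_role == "lesioned" &
                               rh$measure == "cortex"], 90)
  # flipping laterality swaps the roles back
  expect_equal(sort(lh$volume_mm3), sort(rh$volume_mm3))
  expect_equal(lh$volume_mm3[lh$hemi_role == "lesioned"],
               rh$volume_mm3[rh$hemi_role == "contralesional"])
  expect_error(recode_hemispheres(r, "bilateral"), "bilateral")
})

test_that("PVD matches its defining formula on hand cases", {
  expect_equal(compute_pvd(100000, 100000), 0)
  expect_equal(compute_pvd(105, 95), 10)
  expect_equal(compute_pvd(300, 100), 100)
  expect_error(compute_pvd(0, 0), "undefined")
  expect_error(compute_pvd(-1, 5), ">= 0")
})

test_that("PVD is symmetric, scale-invariant, zero iff equal, bounded by 200", {
  set.seed(31)
  a <- runif(200, 1, 1e6)
  b <- runif(200, 1, 1e6)
  expect_equal(compute_pvd(a, b), compute_pvd(b, a))
  expect_equal(compute_pvd(3.7 * a, 3.7 * b), compute_pvd(a, b),
               tolerance = 1e-12)
  expect_true(all(compute_pvd(a, a) == 0))
  expect_true(all(compute_pvd(a, b)[a != b] > 0))
  expect_true(all(compute_pvd(a, b) < 200))
  # supremum approached as one volume vanishes
  expect_equal(compute_pvd(1e-12, 1), 200, tolerance = 1e-6)
})

test_that("the long table has the exact 8-row-per-pair structure", {
  manifest <- tibble::tibble(
    case_id = c("L1_x_C1", "L2_x_C1"), lesion_id = c("L1", "L2"),
    control_id = "C1", laterality = c("lh", "rh"),
    volume_transplanted_mm3 = c(10, 20), status = "ok"
  )
  sims <- dplyr::bind_rows(seg_row("L1_x_C1", 95, 90, 78, 70),
                           seg_row("L2_x_C1", 99, 88, 80, 69))
  gts <- seg_row("C1", 100, 90, 80, 70)
  tab <- build_long_table(sims, gts, manifest)
  expect_equal(nrow(tab), 16)
  expect_equal(nrow(dplyr::distinct(tab, pair_id, case, hemi_role, measure)),
               16)
  expect_setequal(tab$lesion_id[tab$case == "ground_truth"], "0")
  # ground truth recoded with the simulated case's laterality
  gt_l1 <- tab$volume_mm3[tab$pair_id == "L1_x_C1" &
                            tab$case == "ground_truth" &
                            tab$hemi_role == "lesioned" &
                            tab$measure == "cortex"]
  expect_equal(gt_l1, 100) # laterality lh
  gt_l2 <- tab$volume_mm3[tab$pair_id == "L2_x_C1" &
                            tab$case == "ground_truth" &
                            tab$hemi_role == "lesioned" &
                            tab$measure == "cortex"]
  expect_equal(gt_l2, 90) # laterality rh

  expect_error(build_long_table(sims[1, ], gts, manifest), "L2_x_C1")
})

test_that("pvd_table collapses pairs and keeps the signed diagnostic", {
  manifest <- tibble::tibble(
    case_id = "L1_x_C1", lesion_id = "L1", control_id = "C1",
    laterality = "lh", volume_transplanted_mm3 = 10, status = "ok"
  )
  tab <- build_long_table(seg_row("L1_x_C1", 95, 90, 80, 70),
                          seg_row("C1", 100, 90, 80, 70), manifest)
  pv <- pvd_table(tab)
  expect_equal(nrow(pv), 4)
  les_cortex <- pv[pv$hemi_role == "lesioned" & pv$measure == "cortex", ]
  expect_equal(les_cortex$pvd, compute_pvd(95, 100))
  expect_equal(les_cortex$signed_diff_mm3, -5)
  expect_equal(pv$pvd[pv$hemi_role == "contralesional"], c(0, 0))
})

test_that("trimmed_mean follows the floor rule", {
  expect_equal(trimmed_mean(1:10, 0.2), 5.5)
  expect_equal(trimmed_mean(rep(7, 5)), 7)
  expect_equal(trimmed_mean(c(0, 100), 0.2), 50)
  expect_equal(trimmed_mean(c(3, 1, 2), 0), 2)
  expect_error(trimmed_mean(numeric(0)), "empty")
  expect_error(trimmed_mean(1:3, 0.5), "trim")
})

test_that("trimmed_mean equals mean at trim 0 and never decreases when a new max arrives", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(sample(5:40, 1))
    expect_equal(trimmed_mean(x, 0), mean(x))
    expect_gte(trimmed_mean(c(x, max(x) + 1), 0.2), trimmed_mean(x, 0.2))
  }
})

test_that("pvd_summary reports trimmed mean, median, max and exceedance count", {
  base <- tibble::tibble(pair_id = "p", lesion_id = "L", control_id = "C")
  all0 <- tidyr::expand_grid(base, hemi_role = c("lesioned", "contralesional"),
                             measure = c("cortex", "cwm"))
  all0$pvd <- 0
  s0 <- pvd_summary(all0)
  expect_true(all(s0$trimmed_mean == 0 & s0$median == 0 & s0$max == 0 &
                    s0$n_above_threshold == 0))

  three <- tibble::tibble(pair_id = paste0("p", 1:3), lesion_id = "L",
                          control_id = "C", hemi_role = "lesioned",
                          measure = "cortex", pvd = c(0.5, 1.5, 2.5))
  s3 <- pvd_summary(three)
  expect_equal(s3$n_above_threshold, 2L)
  expect_equal(s3$max, 2.5)

  ten <- tibble::tibble(pair_id = paste0("p", 1:10), lesion_id = "L",
                        control_id = "C", hemi_role = "lesioned",
                        measure = "cortex", pvd = as.numeric(1:10))
  expect_equal(pvd_summary(ten)$trimmed_mean, 5.5)
})
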