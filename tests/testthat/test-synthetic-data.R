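test_that("a noise-free phantom has exactly four intensity levels", {
  ph <- generate_phantom(tiny_spec(0), id = "C")
  expect_equal(sort(unique(as.vector(ph$image$data))), c(0, 40, 80, 120))
})

test_that("phantom ground truth equals brute-force label counting and mirrors", {
  ph <- generate_phantom(tiny_spec(3, seed = 9), id = "C")
  d <- dim(ph$labels)
  lh <- array(rep(seq_len(d[1]) <= d[1] / 2, times = d[2] * d[3]), d)
  vv <- voxel_volume(ph$image)
  gt <- ph$ground_truth
  gtv <- function(h, m) gt$volume_mm3[gt$hemisphere == h & gt$measure == m]
  expect_equal(gtv("lh", "cortex"), sum(ph$labels == 2L & lh) * vv)
  expect_equal(gtv("rh", "cwm"), sum(ph$labels == 3L & !lh) * vv)
  expect_equal(gtv("lh", "cortex"), gtv("rh", "cortex"))
  expect_equal(gtv("lh", "cwm"), gtv("rh", "cwm"))
  expect_equal(gtv("lh", "csf"), gtv("rh", "csf"))
})

test_that("phantom generation is deterministic given its seed", {
  p1 <- generate_phantom(tiny_spec(8, seed = 123), id = "A")
  p2 <- generate_phantom(tiny_spec(8, seed = 123), id = "A")
  expect_identical(p1$image$data, p2$image$data)
  p3 <- generate_phantom(tiny_spec(8, seed = 124), id = "A")
  expect_false(identical(p1$image$data, p3$image$data))
})

test_that("synthetic lesions hit their target volume on the clinical grid", {
  sp <- phantom_spec(grid_shape = c(32L, 48L, 48L),
                     voxel_dims = c(1, 0.5, 0.5), class_noise_sd = 0)
  ph <- generate_phantom(sp, id = "C")
  les <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(25, hemisphere = "lh", seed = 2),
    lesion_id = "L")
  expect_equal(sum(les$mask$data), 100) # 25 mm^3 / 0.25 mm^3
  expect_equal(lesion_volume(les$mask), 25)
})

test_that("realized volume error is at most one voxel off-grid", {
  ph <- generate_phantom(tiny_spec(0), id = "C")
  les <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(100.4, hemisphere = "rh", seed = 4),
    lesion_id = "L")
  expect_lte(abs(lesion_volume(les$mask) - 100.4), voxel_volume(ph$image))
})

test_that("lesion intensity targets are realized in unit-invariant space", {
  ph <- generate_phantom(tiny_spec(6, seed = 13), id = "C")
  les <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(500, mean_intensity_ui = -1.8,
                              sd_intensity_ui = 0.4, hemisphere = "lh",
                              seed = 6), lesion_id = "L")
  z <- unit_invariant_normalize(les$patient, les$mask)
  s <- lesion_intensity_stats(z, les$mask)
  expect_lt(abs(s$mean_intensity_ui - (-1.8)), 0.05)
  expect_lt(abs(s$sd_intensity_ui - 0.4), 0.05)
  expect_equal(determine_laterality(les$mask), "lh")

  homog <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(80, sd_intensity_ui = 0, hemisphere = "rh",
                              seed = 7), lesion_id = "L0")
  expect_equal(length(unique(homog$patient$data[homog$mask$data != 0])), 1L)
})

test_that("lesions are connected (sphere) or split into foci (multifocal)", {
  ph <- generate_phantom(tiny_spec(0), id = "C")
  les <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(300, hemisphere = "lh", seed = 15),
    lesion_id = "L")
  # connectivity: breadth-first flood fill from one lesion voxel reaches all
  d <- dim(les$mask$data)
  idx <- which(les$mask$data != 0)
  reached <- logical(prod(d))
  frontier <- idx[1]
  reached[frontier] <- TRUE
  nx <- d[1]; nxy <- d[1] * d[2]
  while (length(frontier) > 0) {
    ai <- arrayInd(frontier, d)
    nbr <- c(frontier[ai[, 1] > 1] - 1L, frontier[ai[, 1] < d[1]] + 1L,
             frontier[ai[, 2] > 1] - nx, frontier[ai[, 2] < d[2]] + nx,
             frontier[ai[, 3] > 1] - nxy, frontier[ai[, 3] < d[3]] + nxy)
    nbr <- unique(nbr)
    frontier <- nbr[!reached[nbr] & les$mask$data[nbr] != 0]
    reached[frontier] <- TRUE
  }
  expect_equal(sum(reached), length(idx))

  multi <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(300, hemisphere = "lh", shape = "multifocal",
                              n_foci = 3, seed = 16), lesion_id = "M")
  expect_equal(sum(multi$mask$data), 300)
})

test_that("infeasible lesion requests are refused", {
  ph <- generate_phantom(tiny_spec(0), id = "C")
  expect_error(
    generate_synthetic_lesion(
      ph, synthetic_lesion_spec(1e6, hemisphere = "lh"), "L"),
    "exceeds"
  )
})

test_that("the study lesion profile spans the reference volumes", {
  prof <- study_lesion_profile()
  expect_equal(nrow(prof), 16)
  expect_equal(min(prof$target_volume_mm3), 15)
  expect_equal(max(prof$target_volume_mm3), 12081.5)
  expect_true(all(prof$target_volume_mm3 %% 0.25 == 0))
  expect_setequal(unique(prof$hemisphere), c("lh", "rh"))
})

test_that("simulated LMM datasets honor their generative model", {
  # all variances and effects zero -> constant outcome
  tab0 <- simulate_lmm_dataset("b", params = list(intercept = 0.4,
                                                  b_hemisphere = 0,
                                                  sd_pair = 0, sd_lesion = 0,
                                                  sd_control = 0,
                                                  sd_resid = 0),
                               seed = 1)
  expect_true(all(tab0$pvd == 0.4))
  # determinism
  t1 <- simulate_lmm_dataset("a", seed = 5)
  t2 <- simulate_lmm_dataset("a", seed = 5)
  expect_identical(t1, t2)
  expect_false(identical(t1$volume_mm3,
                         simulate_lmm_dataset("a", seed = 6)$volume_mm3))
})

test_that("lesion-level variance grows with the lesion variance component", {
  var_of_lesion_means <- function(sd_lesion, seeds) {
    mean(vapply(seeds, function(s) {
      tab <- simulate_lmm_dataset("b", n_lesions = 8, n_controls = 6,
                                  params = list(sd_lesion = sd_lesion),
                                  seed = s)
      stats::var(tapply(tab$pvd, tab$lesion_id, mean))
    }, numeric(1)))
  }
  lo <- var_of_lesion_means(0.05, 1:40)
  hi <- var_of_lesion_means(0.8, 1:40)
  expect_gt(hi, lo)
})

test_that("an empty transplant measures zero PVD end to end", {
  ctl <- generate_phantom(tiny_spec(5, seed = 3), id = "C")
  empty_patch <- structure(
    list(source_id = "L0", z = numeric(0),
         mask = binary_mask(array(0, dim(ctl$labels)), ctl$image$affine),
         characteristics = NULL),
    class = "lesion_patch"
  )
  cs <- transplant(empty_patch, ctl$image)
  ref <- segment_reference(ctl)
  for (mode in c("local", "global-normalized")) {
    seg_sim <- mock_segment(cs$chimeric, ref, mode)
    seg_gt <- mock_segment(ctl$image, ref, mode)
    for (col in c("lh_cortex_mm3", "rh_cortex_mm3", "lh_cwm_mm3",
                  "rh_cwm_mm3")) {
      expect_equal(compute_pvd(seg_sim[[col]], seg_gt[[col]]), 0)
    }
  }
})
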