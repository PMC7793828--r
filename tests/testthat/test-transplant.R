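test_that("extract_patch z-scores lesion voxels against the non-lesion reference", {
  vol <- line_volume(c(10, 20, 30, 40, 50))
  mask <- line_mask(c(0, 0, 0, 1, 1))
  patch <- extract_patch(vol, mask, lesion_id = "L1")
  # non-lesion reference {10,20,30}: mu = 20, sigma = 10
  expect_equal(patch$z, c(2, 3))
  expect_equal(length(patch$z), sum(mask$data != 0))
  expect_equal(patch$characteristics$volume_native_mm3, 2)
  expect_error(extract_patch(vol, line_mask(rep(0, 5))), "empty")
})

test_that("identity resampling on a matched grid is a no-op", {
  arr <- array(0, c(8, 8, 8))
  arr[3:5, 3:5, 3:5] <- 1
  m <- centered_mask(arr)
  tgt <- centered_volume(array(0, c(8, 8, 8)))
  expect_identical(resample_mask(m, "identity", tgt)$data, m$data)
})

test_that("integer-voxel world translations preserve cuboid masks exactly", {
  arr <- array(0, c(12, 12, 12))
  arr[3:5, 4:6, 5:7] <- 1
  m <- centered_mask(arr)
  tgt <- centered_volume(array(0, c(12, 12, 12)))
  tf <- diag(4)
  tf[1, 4] <- 2 # +2 mm along x on a 1 mm grid
  shifted <- resample_mask(m, tf, tgt)
  expect_equal(sum(shifted$data), sum(m$data))
  expect_equal(shifted$data[5:7, 4:6, 5:7], m$data[3:5, 4:6, 5:7])

  # push fully outside the target field of view
  tf_out <- diag(4)
  tf_out[1, 4] <- 50
  expect_error(resample_mask(m, tf_out, tgt), "outside")
  expect_error(resample_mask(m, matrix(0, 4, 4), tgt), "singular")
})

test_that("transplant applies the inverse z-map in control intensity space", {
  # control reference voxels {100,200,300}: mu = 200, sigma = 100
  ctl <- line_volume(c(100, 200, 300, 0, 0), id = "C")
  ref <- line_mask(c(1, 1, 1, 0, 0))
  patient <- line_volume(c(10, 20, 30, 50, 60), id = "P")
  pmask <- line_mask(c(0, 0, 0, 1, 1))
  patch <- extract_patch(patient, pmask,
                         reference_mask = line_mask(c(1, 1, 1, 0, 0)),
                         lesion_id = "L1")
  expect_equal(patch$z, c(3, 4))
  # laterality needs a proper centered grid; rebuild in 3-D with x spread
  ctl3 <- centered_volume(array(c(100, 200, 300, 0, 0, 0, 0, 0),
                                c(8, 1, 1)), id = "C")
  ref3 <- centered_mask(array(c(1, 1, 1, 0, 0, 0, 0, 0), c(8, 1, 1)))
  pat3 <- centered_volume(array(c(10, 20, 30, 0, 0, 0, 50, 60), c(8, 1, 1)),
                          id = "P")
  pm3 <- centered_mask(array(c(0, 0, 0, 0, 0, 0, 1, 1), c(8, 1, 1)))
  patch3 <- extract_patch(pat3, pm3,
                          reference_mask = centered_mask(
                            array(c(1, 1, 1, 0, 0, 0, 0, 0), c(8, 1, 1))),
                          lesion_id = "L1")
  cs <- transplant(patch3, ctl3, control_reference_mask = ref3)
  expect_equal(cs$chimeric$data[7:8], c(500, 600))
  expect_equal(cs$laterality, "rh")
  expect_equal(cs$volume_transplanted_mm3, 2)
})

test_that("voxels outside the transplanted mask are conserved bit-exactly", {
  mc <- mechanism_case()
  outside <- mc$case$transformed_mask$data == 0
  expect_identical(mc$case$chimeric$data[outside],
                   mc$control$image$data[outside])
  # in particular the whole contralesional hemisphere
  d <- dim(mc$control$image$data)
  rh <- array(rep(seq_len(d[1]) > d[1] / 2, times = d[2] * d[3]), d)
  expect_identical(mc$case$chimeric$data[rh], mc$control$image$data[rh])
})

test_that("a patch returned to its own source reproduces it", {
  ph <- generate_phantom(tiny_spec(2, seed = 5), id = "C")
  les <- generate_synthetic_lesion(
    ph, synthetic_lesion_spec(200, hemisphere = "rh", seed = 8),
    lesion_id = "L")
  patch <- extract_patch(ph$image, les$mask, lesion_id = "L")
  cs <- transplant(patch, ph$image)
  expect_lt(max(abs(cs$chimeric$data - ph$image$data)), 1e-6)
})

test_that("an empty patch yields a chimeric identical to the control", {
  ctl <- generate_phantom(tiny_spec(0, seed = 2), id = "C")
  empty_patch <- structure(
    list(source_id = "L0",
         z = numeric(0),
         mask = binary_mask(array(0, dim(ctl$labels)), ctl$image$affine),
         characteristics = NULL),
    class = "lesion_patch"
  )
  cs <- transplant(empty_patch, ctl$image)
  expect_identical(cs$chimeric$data, ctl$image$data)
  expect_equal(cs$volume_transplanted_mm3, 0)
})

test_that("lesions landing bilaterally on the control grid are rejected", {
  arr <- array(0, c(8, 4, 4))
  arr[3:6, 2, 2] <- 1 # straddles world x = 0 symmetrically
  pat <- centered_volume(array(rnorm(128, 100, 10), c(8, 4, 4)), id = "P")
  patch <- extract_patch(pat, centered_mask(arr), lesion_id = "L")
  ctl <- centered_volume(array(rnorm(128, 100, 10), c(8, 4, 4)), id = "C")
  expect_error(transplant(patch, ctl), "bilateral")
})

test_that("the crossed dataset is lesion-major, control-minor and complete", {
  ph <- lapply(1:3, function(i) {
    generate_phantom(tiny_spec(1, seed = 30L + i), id = sprintf("P%d", i))
  })
  patches <- lapply(seq_along(ph), function(i) {
    les <- generate_synthetic_lesion(
      ph[[i]], synthetic_lesion_spec(100, hemisphere = "lh", seed = 40L + i),
      lesion_id = sprintf("L%d", i))
    extract_patch(les$patient, les$mask, lesion_id = sprintf("L%d", i))
  })
  ctls <- lapply(1:2, function(i) {
    generate_phantom(tiny_spec(1, seed = 50L + i), id = sprintf("C%d", i))$image
  })
  out <- build_crossed_dataset(patches[1:2], ctls)
  expect_equal(nrow(out$manifest), 4)
  expect_equal(out$manifest$case_id,
               c("L1_x_C1", "L1_x_C2", "L2_x_C1", "L2_x_C2"))
  expect_true(all(out$manifest$status == "ok"))

  out0 <- build_crossed_dataset(list(), ctls)
  expect_equal(length(out0$cases), 0)
  expect_equal(nrow(out0$manifest), 0)

  expect_error(build_crossed_dataset(patches[c(1, 1)], ctls), "duplicate")
})

test_that("transplant failures are recorded in non-strict mode, fatal in strict", {
  # a patch whose mask straddles the midline fails on laterality
  arr <- array(0, c(8, 4, 4))
  arr[3:6, 2, 2] <- 1
  pat <- centered_volume(array(rnorm(128, 100, 10), c(8, 4, 4)), id = "P")
  bad <- extract_patch(pat, centered_mask(arr), lesion_id = "Lbad")
  ctl <- centered_volume(array(rnorm(128, 100, 10), c(8, 4, 4)), id = "C")
  out <- build_crossed_dataset(list(bad), list(ctl))
  expect_equal(length(out$cases), 0)
  expect_match(out$manifest$status, "bilateral")
  expect_error(build_crossed_dataset(list(bad), list(ctl), strict = TRUE),
               "Lbad")
})

test_that("identical inputs produce byte-identical chimeric NIfTI files", {
  mc1 <- mechanism_case()
  mc2 <- mechanism_case()
  f1 <- withr::local_tempfile(fileext = ".nii.gz")
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(mc1$case$chimeric, f1)
  write_nifti(mc2$case$chimeric, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
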