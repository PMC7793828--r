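#' Specify a synthetic brain phantom
#'
#' The phantom stands in for the (unshared) control T1w scans: two
#' mirror-symmetric hemispheres, each built from three nested ellipsoids —
#' an outer CSF shell, a grey-matter (cortex) shell, and a white-matter
#' core — on a regular grid with background air at intensity 0. Tissue
#' volumes are known exactly from the label map, giving the segmenter a
#' ground truth no real scan can provide.
#'
#' The default is a 64-voxel cube at 1 mm isotropic: large enough that
#' lesions spanning the study's 15–12,000 mm^3 volume range fit inside one
#' hemisphere's tissue, small enough that a fully crossed 16 x 11 run with
#' the mock segmenter completes in well under a minute. `voxel_dims =
#' c(1, 0.5, 0.5)` reproduces clinical-resolution voxel granularity
#' (0.25 mm^3) for volume arithmetic.
#'
#' @param grid_shape Integer vector of 3 voxel counts (default 64^3).
#' @param voxel_dims Voxel size in mm (default 1 mm isotropic).
#' @param center_offset_mm Distance of each hemisphere center from the
#'   mid-sagittal plane along world x (default 15.5 mm).
#' @param csf_semiaxes,gm_semiaxes,wm_semiaxes Semi-axes (mm) of the nested
#'   ellipsoids (x, y, z).
#' @param class_means Named intensities for `csf`, `gm`, `wm` (arbitrary
#'   units, strictly increasing as on T1w).
#' @param class_noise_sd Gaussian noise SD applied within each tissue
#'   class; 0 gives a noise-free phantom with exactly four intensity
#'   levels.
#' @param seed Integer seed for the noise stream.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         voxel_dims = c(1, 1, 1),
                         center_offset_mm = NULL,
                         csf_semiaxes = NULL,
                         gm_semiaxes = NULL,
                         wm_semiaxes = NULL,
                         class_means = c(csf = 40, gm = 80, wm = 120),
                         class_noise_sd = 12,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8L),
            length(voxel_dims) == 3L, all(voxel_dims > 0),
            all(diff(class_means[c("csf", "gm", "wm")]) > 0),
            class_noise_sd >= 0)
  # geometry defaults scale with the grid's physical half-extent, so any
  # grid size yields a proportionate two-hemisphere brain
  he <- voxel_dims * (grid_shape - 1) / 2
  if (is.null(center_offset_mm)) center_offset_mm <- 0.49 * he[1]
  if (is.null(csf_semiaxes)) csf_semiaxes <- c(0.48 * he[1], 0.76 * he[2:3])
  if (is.null(gm_semiaxes)) gm_semiaxes <- c(0.43 * he[1], 0.70 * he[2:3])
  if (is.null(wm_semiaxes)) wm_semiaxes <- c(0.25 * he[1], 0.41 * he[2:3])
  if (!all(csf_semiaxes >= gm_semiaxes) || !all(gm_semiaxes > wm_semiaxes)) {
    stop("ellipsoids must nest: csf >= gm > wm semi-axes", call. = FALSE)
  }
  half_extent <- voxel_dims * (grid_shape - 1) / 2
  if (center_offset_mm + csf_semiaxes[1] > half_extent[1] + voxel_dims[1] / 2 ||
      any(csf_semiaxes[2:3] > half_extent[2:3] + voxel_dims[2:3] / 2)) {
    stop("ellipsoids do not fit inside the grid", call. = FALSE)
  }
  if (center_offset_mm - csf_semiaxes[1] >= 0) {
    # hemispheres entirely off-midline is fine; the check below is the
    # important one: no tissue voxel may sit exactly on x = 0
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_dims = voxel_dims,
         center_offset_mm = center_offset_mm, csf_semiaxes = csf_semiaxes,
         gm_semiaxes = gm_semiaxes, wm_semiaxes = wm_semiaxes,
         class_means = class_means, class_noise_sd = class_noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Centered RAS+ affine: grid center at the world origin.
phantom_affine <- function(grid_shape, voxel_dims) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_dims
  aff[1:3, 4] <- -voxel_dims * (grid_shape - 1) / 2
  aff
}

#' Generate a brain phantom
#'
#' Realizes a [phantom_spec()] into an intensity image, a label map, and a
#' ground-truth volume table. Labels: 0 background, 1 CSF, 2 GM, 3 WM.
#' Intensities are the class mean plus seeded Gaussian noise (background
#' stays exactly 0). Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param id Label for the phantom.
#' @return A `phantom`: `image` ([image_volume()]), `labels` (integer
#'   array), `spec`, and `ground_truth` — a tibble with `hemisphere`
#'   (`lh`/`rh`), `measure` (`cortex`, `cwm`, `csf`), `volume_mm3`.
#' @export
generate_phantom <- function(spec, id = "phantom") {
  gs <- spec$grid_shape
  aff <- phantom_affine(gs, spec$voxel_dims)
  # world coordinates of every voxel center
  xs <- aff[1, 4] + spec$voxel_dims[1] * (seq_len(gs[1]) - 1)
  ys <- aff[2, 4] + spec$voxel_dims[2] * (seq_len(gs[2]) - 1)
  zs <- aff[3, 4] + spec$voxel_dims[3] * (seq_len(gs[3]) - 1)
  if (any(abs(xs) < 1e-9)) {
    # a voxel column exactly on the midline would belong to neither
    # hemisphere; the centered even-grid default avoids this
    stop("grid places voxel centers exactly on the mid-sagittal plane",
         call. = FALSE)
  }
  wx <- array(rep(xs, times = gs[2] * gs[3]), dim = gs)
  wy <- array(rep(rep(ys, each = gs[1]), times = gs[3]), dim = gs)
  wz <- array(rep(zs, each = gs[1] * gs[2]), dim = gs)

  labels <- array(0L, dim = gs)
  for (side in c(-1, 1)) {
    cx <- side * spec$center_offset_mm
    insideness <- function(semi) {
      ((wx - cx) / semi[1])^2 + (wy / semi[2])^2 + (wz / semi[3])^2
    }
    in_csf <- insideness(spec$csf_semiaxes) <= 1
    in_gm <- insideness(spec$gm_semiaxes) <= 1
    in_wm <- insideness(spec$wm_semiaxes) <= 1
    labels[in_csf & labels == 0L] <- 1L
    labels[in_gm] <- 2L
    labels[in_wm] <- 3L
  }
  if (any(labels[abs(wx) < 1e-9] != 0L)) {
    stop("tissue voxel on the mid-sagittal plane", call. = FALSE)
  }

  img <- array(0, dim = gs)
  means <- spec$class_means[c("csf", "gm", "wm")]
  withr::with_seed(spec$seed, {
    for (k in 1:3) {
      sel <- labels == k
      n <- sum(sel)
      img[sel] <- means[k] +
        if (spec$class_noise_sd > 0) stats::rnorm(n, 0, spec$class_noise_sd)
        else 0
    }
  })

  vv <- prod(spec$voxel_dims)
  gt <- tidyr::expand_grid(
    hemisphere = c("lh", "rh"),
    measure = c("csf", "cortex", "cwm")
  )
  lab_for <- c(csf = 1L, cortex = 2L, cwm = 3L)
  gt$volume_mm3 <- purrr::map2_dbl(gt$hemisphere, gt$measure, function(h, m) {
    side_sel <- if (h == "lh") wx < 0 else wx > 0
    sum(labels == lab_for[[m]] & side_sel) * vv
  })

  structure(
    list(image = image_volume(img, aff, id = id), labels = labels,
         spec = spec, ground_truth = gt),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom '%s'> %s voxels; GM %s mm^3, WM %s mm^3 per side\n",
              x$image$id, paste(dim(x$labels), collapse = "x"),
              format(x$ground_truth$volume_mm3[x$ground_truth$measure == "cortex"][1]),
              format(x$ground_truth$volume_mm3[x$ground_truth$measure == "cwm"][1])))
  invisible(x)
}

#' Specify a synthetic lesion
#'
#' Controls the three characteristics the analysis models: volume, mean
#' intensity, and intensity SD (the latter two in unit-invariant space),
#' plus hemisphere and focality.
#'
#' @param target_volume_mm3 Target lesion volume in mm^3 (the study-scale
#'   range is roughly 15–12,000 mm^3).
#' @param mean_intensity_ui Target mean intensity in unit-invariant space
#'   (z-units of the host image's non-lesion intensity distribution).
#' @param sd_intensity_ui Target intensity SD in the same space (>= 0; 0
#'   gives a perfectly homogeneous lesion).
#' @param hemisphere `"lh"` or `"rh"`.
#' @param shape `"sphere"` (one connected focus) or `"multifocal"`
#'   (`n_foci` separate foci whose volumes sum to the target).
#' @param n_foci Number of foci for multifocal lesions.
#' @param seed Integer seed for growth and intensity streams.
#' @return A `synthetic_lesion_spec` list.
#' @export
synthetic_lesion_spec <- function(target_volume_mm3, mean_intensity_ui = -1.5,
                                  sd_intensity_ui = 0.5,
                                  hemisphere = c("lh", "rh"),
                                  shape = c("sphere", "multifocal"),
                                  n_foci = 3L, seed = 1L) {
  hemisphere <- match.arg(hemisphere)
  shape <- match.arg(shape)
  stopifnot(target_volume_mm3 > 0, sd_intensity_ui >= 0, n_foci >= 1L)
  structure(
    list(target_volume_mm3 = target_volume_mm3,
         mean_intensity_ui = mean_intensity_ui,
         sd_intensity_ui = sd_intensity_ui, hemisphere = hemisphere,
         shape = shape, n_foci = as.integer(n_foci), seed = as.integer(seed)),
    class = "synthetic_lesion_spec"
  )
}

# Grow a connected region of exactly n_target voxels by seeded random
# dilation from a random interior voxel, restricted to `allowed` (logical
# array) minus `taken`. Returns linear indices, or NULL if infeasible.
grow_region <- function(allowed, taken, n_target, dims) {
  avail <- allowed & !taken
  start_pool <- which(avail)
  if (length(start_pool) < n_target) return(NULL)
  start <- start_pool[sample.int(length(start_pool), 1L)]
  selected <- integer(0)
  in_region <- logical(length(avail))
  frontier <- start
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  while (length(selected) < n_target && length(frontier) > 0) {
    take <- min(n_target - length(selected), length(frontier))
    picked <- if (take < length(frontier)) {
      sample(frontier, take)
    } else frontier
    in_region[picked] <- TRUE
    selected <- c(selected, picked)
    # expand from the full shell (including unpicked frontier stays pending)
    pending <- setdiff(frontier, picked)
    idx <- arrayInd(picked, dims)
    nbrs <- c(
      picked[idx[, 1] > 1] - 1L, picked[idx[, 1] < dims[1]] + 1L,
      picked[idx[, 2] > 1] - nx, picked[idx[, 2] < dims[2]] + nx,
      picked[idx[, 3] > 1] - nxy, picked[idx[, 3] < dims[3]] + nxy
    )
    nbrs <- unique(c(pending, nbrs))
    frontier <- nbrs[avail[nbrs] & !in_region[nbrs]]
  }
  if (length(selected) < n_target) return(NULL)
  selected
}

#' Generate a synthetic lesion inside a phantom
#'
#' Grows a connected (or multifocal) region of the requested volume inside
#' the requested hemisphere's tissue (GM or WM) by seeded random dilation,
#' then fills it with intensities whose realized unit-invariant mean and
#' sample SD match the spec exactly (intensity draws are standardized
#' before the inverse z-map, so the realized statistics are the targets up
#' to floating point). Returns both the lesion mask and the lesioned
#' "patient-like" copy of the phantom.
#'
#' @param phantom A [generate_phantom()] result.
#' @param spec A [synthetic_lesion_spec()].
#' @param lesion_id Identifier for the lesion.
#' @return A list: `mask` ([binary_mask()]), `patient` ([image_volume()]),
#'   `spec`.
#' @export
generate_synthetic_lesion <- function(phantom, spec, lesion_id = "lesion") {
  vv <- voxel_volume(phantom$image)
  n_target <- max(1L, as.integer(round(spec$target_volume_mm3 / vv)))
  gs <- dim(phantom$labels)
  aff <- phantom$image$affine
  xs <- aff[1, 4] + phantom$spec$voxel_dims[1] * (seq_len(gs[1]) - 1)
  side_ok <- if (spec$hemisphere == "lh") xs < 0 else xs > 0
  allowed <- (phantom$labels == 2L | phantom$labels == 3L) &
    array(rep(side_ok, times = gs[2] * gs[3]), dim = gs)
  if (!any(allowed)) {
    stop("requested hemisphere has no tissue", call. = FALSE)
  }
  if (sum(allowed) < n_target) {
    stop(sprintf("target volume %.2f mm^3 exceeds hemisphere tissue volume %.2f mm^3",
                 spec$target_volume_mm3, sum(allowed) * vv), call. = FALSE)
  }

  withr::with_seed(spec$seed, {
    taken <- array(FALSE, dim = gs)
    if (spec$shape == "sphere") {
      counts <- n_target
    } else {
      # split the voxel budget over foci (each at least 1 voxel)
      k <- min(spec$n_foci, n_target)
      w <- stats::runif(k, 0.5, 1.5)
      counts <- pmax(1L, as.integer(round(n_target * w / sum(w))))
      counts[1] <- counts[1] + (n_target - sum(counts))
      if (counts[1] < 1L) counts <- rep(n_target %/% k, k) # degenerate guard
    }
    sel_all <- integer(0)
    for (ct in counts) {
      sel <- grow_region(allowed, taken, ct, gs)
      if (is.null(sel)) {
        stop("could not grow a connected region of the requested volume",
             call. = FALSE)
      }
      taken[sel] <- TRUE
      sel_all <- c(sel_all, sel)
    }

    mask_arr <- array(0, dim = gs)
    mask_arr[sel_all] <- 1
    # reference stats of the host image over non-lesion voxels
    ref_vals <- phantom$image$data[mask_arr == 0]
    mu <- mean(ref_vals)
    sigma <- stats::sd(ref_vals)
    n <- length(sel_all)
    z <- if (n == 1L || spec$sd_intensity_ui == 0) {
      rep(spec$mean_intensity_ui, n)
    } else {
      e <- stats::rnorm(n)
      spec$mean_intensity_ui + spec$sd_intensity_ui * (e - mean(e)) / stats::sd(e)
    }
    patient_arr <- phantom$image$data
    patient_arr[sel_all] <- mu + sigma * z
  })

  list(
    mask = binary_mask(mask_arr, aff, id = lesion_id),
    patient = image_volume(patient_arr, aff,
                           id = paste0("patient_", lesion_id)),
    spec = spec
  )
}

#' Simulate a dataset from a hypothesis-family generative model
#'
#' Draws a crossed-design dataset (every lesion paired with every control)
#' from the Gaussian linear mixed model matching one of the three
#' hypothesis families, for parameter-recovery testing:
#'
#' * family `"a"` — hemispheric volume as a function of case
#'   (ground-truth vs simulated), with a random case slope and intercept
#'   per pair and crossed random intercepts for lesion and control; four
#'   rows per pair (2 case x 2 hemisphere).
#' * family `"b"` — PVD as a function of hemisphere role
#'   (lesioned vs contralesional), random intercepts for pair, lesion and
#'   control; two rows per pair.
#' * family `"c"` — PVD as a function of three standardized lesion
#'   covariates (volume, mean intensity, intensity SD), random intercept
#'   for control only; one row per pair.
#'
#' @param family `"a"`, `"b"` or `"c"`.
#' @param n_lesions,n_controls Design size (the study scale is 16 x 11).
#' @param params Named list overriding the family defaults (see
#'   `lmm_sim_defaults()`).
#' @param seed Integer seed.
#' @return A tibble with the design columns and the outcome (`volume_mm3`
#'   for family a, `pvd` otherwise); the generative parameters are
#'   attached as attribute `"true_params"`.
#' @export
simulate_lmm_dataset <- function(family = c("a", "b", "c"),
                                 n_lesions = 16L, n_controls = 11L,
                                 params = list(), seed = 1L) {
  family <- match.arg(family)
  stopifnot(n_lesions >= 2L, n_controls >= 2L)
  p <- utils::modifyList(lmm_sim_defaults(family), params)
  sds <- p[grepl("^sd_", names(p))]
  if (any(unlist(sds) < 0)) stop("variance components must be >= 0", call. = FALSE)

  lesions <- sprintf("L%02d", seq_len(n_lesions))
  controls <- sprintf("C%02d", seq_len(n_controls))
  design <- tidyr::expand_grid(lesion_id = lesions, control_id = controls)
  design$pair_id <- paste0(design$lesion_id, "_x_", design$control_id)

  sd_of <- function(nm) if (is.null(p[[nm]])) 0 else p[[nm]]
  withr::with_seed(seed, {
    u_lesion <- stats::setNames(stats::rnorm(n_lesions, 0, sd_of("sd_lesion")),
                                lesions)
    u_control <- stats::setNames(stats::rnorm(n_controls, 0, p$sd_control),
                                 controls)
    u_pair <- stats::setNames(stats::rnorm(nrow(design), 0, sd_of("sd_pair")),
                              design$pair_id)

    if (family == "a") {
      s_pair <- stats::setNames(stats::rnorm(nrow(design), 0, p$sd_case_slope),
                                design$pair_id)
      tab <- tidyr::expand_grid(pair_id = design$pair_id,
                                case = c("ground_truth", "simulated"),
                                hemi_role = c("lesioned", "contralesional"))
      tab <- dplyr::left_join(tab, design, by = "pair_id")
      is_sim <- as.numeric(tab$case == "simulated")
      tab$volume_mm3 <- p$intercept + p$b_case * is_sim +
        u_pair[tab$pair_id] + s_pair[tab$pair_id] * is_sim +
        u_lesion[tab$lesion_id] + u_control[tab$control_id] +
        stats::rnorm(nrow(tab), 0, p$sd_resid)
    } else if (family == "b") {
      tab <- tidyr::expand_grid(pair_id = design$pair_id,
                                hemi_role = c("contralesional", "lesioned"))
      tab <- dplyr::left_join(tab, design, by = "pair_id")
      is_les <- as.numeric(tab$hemi_role == "lesioned")
      tab$pvd <- p$intercept + p$b_hemisphere * is_les +
        u_pair[tab$pair_id] + u_lesion[tab$lesion_id] +
        u_control[tab$control_id] + stats::rnorm(nrow(tab), 0, p$sd_resid)
    } else {
      covs <- tibble::tibble(
        lesion_id = lesions,
        volume_z = as.numeric(scale(stats::rnorm(n_lesions))),
        mean_intensity_z = as.numeric(scale(stats::rnorm(n_lesions))),
        sd_intensity_z = as.numeric(scale(stats::rnorm(n_lesions)))
      )
      tab <- dplyr::left_join(design, covs, by = "lesion_id")
      tab$pvd <- p$intercept + p$b_volume * tab$volume_z +
        p$b_mean_intensity * tab$mean_intensity_z +
        p$b_sd_intensity * tab$sd_intensity_z +
        u_control[tab$control_id] + stats::rnorm(nrow(tab), 0, p$sd_resid)
    }
  })
  tab <- tibble::as_tibble(tab)
  attr(tab, "true_params") <- p
  tab
}

#' Reference lesion profile at study scale
#'
#' The default cohort of 16 focal lesions used for study-scale synthetic
#' runs: voxel-counting volumes spanning 15–12,081.5 mm^3 (every volume a
#' multiple of 0.25 mm^3, i.e. drawn on a 1 x 0.5 x 0.5 mm grid) and a
#' 7 lh / 9 rh laterality split, matching the scale and spread of focal
#' traumatic lesions visible on acute pediatric T1w MRI. Intensity targets
#' in unit-invariant space are drawn once per lesion from a seeded stream:
#' mean in U(-2.5, 0.5) (TBI lesions are predominantly T1-hypointense) and
#' SD in U(0.1, 0.9).
#'
#' @param n_lesions Number of lesions; the first 16 come from the
#'   reference profile, further ones are drawn log-uniformly on the same
#'   volume range.
#' @param seed Integer seed for the intensity (and any extra-volume)
#'   draws.
#' @return A tibble: `lesion_id`, `target_volume_mm3`, `hemisphere`,
#'   `mean_intensity_ui`, `sd_intensity_ui`.
#' @export
study_lesion_profile <- function(n_lesions = 16L, seed = 1L) {
  vols <- c(25, 1030, 3063.75, 505.75, 12081.5, 60.25, 63, 35, 2059.25,
            8815, 83.5, 3858.5, 391.5, 15, 37.5, 407)
  hemis <- c("lh", "lh", "rh", "lh", "lh", "lh", "rh", "rh", "rh", "rh",
             "lh", "rh", "rh", "lh", "rh", "rh")
  withr::with_seed(seed, {
    if (n_lesions > 16L) {
      extra <- n_lesions - 16L
      vols <- c(vols, exp(stats::runif(extra, log(15), log(12081.5))))
      hemis <- c(hemis, sample(c("lh", "rh"), extra, replace = TRUE))
    }
    vols <- vols[seq_len(n_lesions)]
    hemis <- hemis[seq_len(n_lesions)]
    tibble::tibble(
      lesion_id = sprintf("L%02d", seq_len(n_lesions)),
      target_volume_mm3 = vols,
      hemisphere = hemis,
      mean_intensity_ui = stats::runif(n_lesions, -2.5, 0.5),
      sd_intensity_ui = stats::runif(n_lesions, 0.1, 0.9)
    )
  })
}

#' Generate a synthetic study cohort
#'
#' Builds everything a study-scale run needs from seeds alone: `n_controls`
#' control phantoms (identical geometry, independent noise realizations),
#' `n_lesions` patient-like phantoms each carrying one synthetic lesion
#' from [study_lesion_profile()], and the extracted lesion patches ready
#' for [build_crossed_dataset()]. Identical geometry across subjects means
#' the identity transform is the correct patient-to-control registration,
#' isolating the intensity-transfer step from registration error.
#'
#' @param n_lesions,n_controls Cohort size (study scale is 16 x 11).
#' @param base_spec A [phantom_spec()] shared by all subjects (its `seed`
#'   field is overridden per subject).
#' @param profile Lesion profile tibble (default
#'   `study_lesion_profile(n_lesions, seed)`).
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return A list: `patches` (list of [extract_patch()] results),
#'   `controls` (list of [generate_phantom()] results), `profile`.
#' @export
generate_cohort <- function(n_lesions = 16L, n_controls = 11L,
                            base_spec = phantom_spec(),
                            profile = NULL, seed = 1L) {
  if (is.null(profile)) profile <- study_lesion_profile(n_lesions, seed)
  stopifnot(nrow(profile) == n_lesions)
  controls <- lapply(seq_len(n_controls), function(i) {
    sp <- base_spec
    sp$seed <- as.integer(seed * 1000L + i)
    generate_phantom(sp, id = sprintf("C%02d", i))
  })
  patches <- lapply(seq_len(n_lesions), function(i) {
    sp <- base_spec
    sp$seed <- as.integer(seed * 1000L + 500L + i)
    host <- generate_phantom(sp, id = sprintf("P%02d", i))
    lspec <- synthetic_lesion_spec(
      target_volume_mm3 = profile$target_volume_mm3[i],
      mean_intensity_ui = profile$mean_intensity_ui[i],
      sd_intensity_ui = profile$sd_intensity_ui[i],
      hemisphere = profile$hemisphere[i],
      seed = as.integer(seed * 1000L + 800L + i)
    )
    les <- generate_synthetic_lesion(host, lspec,
                                     lesion_id = profile$lesion_id[i])
    extract_patch(les$patient, les$mask, lesion_id = profile$lesion_id[i])
  })
  list(patches = patches, controls = controls, profile = profile)
}

#' Generative-model defaults per hypothesis family
#'
#' Effect sizes echo the scale of the study design they emulate: a case
#' effect of a few hundred mm^3 against hemispheric volumes of ~2e5 mm^3
#' for family a, hemisphere effects of ~0.1–0.2 PVD percentage points for
#' family b, and covariate slopes of ~0.3 points per SD for family c.
#'
#' @param family `"a"`, `"b"` or `"c"`.
#' @return Named list of generative parameters.
#' @export
lmm_sim_defaults <- function(family = c("a", "b", "c")) {
  family <- match.arg(family)
  switch(family,
    a = list(intercept = 2e5, b_case = -560, sd_pair = 2000,
             sd_case_slope = 1500, sd_lesion = 1000, sd_control = 15000,
             sd_resid = 500),
    b = list(intercept = 0.45, b_hemisphere = 0.14, sd_pair = 0.15,
             sd_lesion = 0.2, sd_control = 0.1, sd_resid = 0.25),
    c = list(intercept = 0.45, b_volume = 0.28, b_mean_intensity = -0.14,
             b_sd_intensity = -0.23, sd_control = 0.1, sd_resid = 0.3)
  )
}
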