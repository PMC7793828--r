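# Vectorized trilinear sampling of a 3-D array at continuous 0-based voxel
# coordinates. Coordinates outside the grid sample 0.
trilinear_sample <- function(arr, coords) {
  d <- dim(arr)
  n <- nrow(coords)
  out <- numeric(n)
  f <- floor(coords)
  w <- coords - f
  # accumulate over the 8 corners
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ci <- f[, 1] + dx
    cj <- f[, 2] + dy
    ck <- f[, 3] + dz
    wt <- (if (dx == 1) w[, 1] else 1 - w[, 1]) *
          (if (dy == 1) w[, 2] else 1 - w[, 2]) *
          (if (dz == 1) w[, 3] else 1 - w[, 3])
    inb <- ci >= 0 & ci < d[1] & cj >= 0 & cj < d[2] & ck >= 0 & ck < d[3] &
           wt > 0
    if (any(inb)) {
      lin <- ci[inb] + d[1] * (cj[inb] + d[2] * ck[inb]) + 1
      out[inb] <- out[inb] + wt[inb] * arr[lin]
    }
  }
  out
}

# Continuous source-voxel coordinates (0-based) of every target voxel under
# a world-to-world transform mapping source world -> target world.
source_voxel_coords <- function(source, target, transform) {
  d <- dim(target$data)
  idx0 <- arrayInd(seq_len(prod(d)), d) - 1L
  tgt_world <- target$affine %*% rbind(t(idx0), 1)
  if (is.character(transform) && identical(transform, "identity")) {
    src_world <- tgt_world
  } else {
    tf <- unname(as.matrix(transform))
    if (!all(dim(tf) == c(4L, 4L))) {
      stop("`transform` must be \"identity\" or a 4x4 world-to-world matrix",
           call. = FALSE)
    }
    dtf <- det(tf)
    if (!is.finite(dtf) || abs(dtf) < 1e-12) {
      stop("singular transform", call. = FALSE)
    }
    src_world <- solve(tf) %*% tgt_world
  }
  src_vox <- solve(source$affine) %*% src_world
  t(src_vox)[, 1:3, drop = FALSE]
}

same_grid_identity <- function(transform, a, b) {
  is.character(transform) && identical(transform, "identity") &&
    identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= 1e-4
}

#' Resample a binary mask onto a target grid
#'
#' Trilinearly interpolates the {0,1} mask field onto the target grid under
#' a world-to-world affine (mapping source world coordinates to target
#' world coordinates), then binarizes at `threshold`. The 0.5 default is
#' volume-preserving for integer-voxel translations. With
#' `transform = "identity"` and matching grids the input is returned
#' unchanged (no interpolation at all).
#'
#' @param mask A [binary_mask()] on the source grid.
#' @param transform `"identity"` or an invertible 4x4 matrix mapping source
#'   world coordinates (mm, RAS+) to target world coordinates.
#' @param target An [image_volume()] defining the output grid.
#' @param threshold Binarization threshold in (0, 1); default 0.5.
#' @return A [binary_mask()] on the target grid.
#' @export
resample_mask <- function(mask, transform = "identity", target,
                          threshold = 0.5) {
  if (same_grid_identity(transform, mask, target)) {
    return(mask)
  }
  coords <- source_voxel_coords(mask, target, transform)
  vals <- trilinear_sample(mask$data, coords)
  out <- array(as.double(vals >= threshold), dim = dim(target$data))
  if (sum(mask$data != 0) > 0 && sum(out) == 0) {
    stop("resampled mask is empty: lesion fell outside the target field of view",
         call. = FALSE)
  }
  binary_mask(out, target$affine, id = paste0(mask$id, "_on_", target$id))
}

#' Extract a transplantable lesion patch
#'
#' Normalizes the patient image into unit-invariant space (see
#' [unit_invariant_normalize()]) and stores the z-scored intensities at the
#' lesion voxels together with the mask and the lesion's descriptive
#' characteristics. Because the intensities are z-scores relative to the
#' patient's non-lesion tissue, they can be mapped into any control image's
#' intensity distribution at transplant time, retaining the lesion's
#' texture while matching the destination scan's units.
#'
#' @param patient Patient [image_volume()] in native space.
#' @param mask Non-empty lesion [binary_mask()] on the patient grid.
#' @param reference_mask Reference set for normalization (`NULL` = whole
#'   image).
#' @param lesion_id Identifier; defaults to the mask id.
#' @return A `lesion_patch`: `source_id`, `z` (per-voxel unit-invariant
#'   intensities, one per nonzero mask voxel in array order), `mask`, and
#'   `characteristics` (one-row tibble).
#' @export
extract_patch <- function(patient, mask, reference_mask = NULL,
                          lesion_id = mask$id) {
  if (sum(mask$data != 0) == 0L) stop("lesion mask is empty", call. = FALSE)
  norm_vol <- unit_invariant_normalize(patient, mask, reference_mask)
  z <- norm_vol$data[mask$data != 0]
  chars <- tibble::tibble(
    lesion_id = as.character(lesion_id),
    volume_native_mm3 = lesion_volume(mask),
    laterality = determine_laterality(mask),
    mean_intensity_ui = mean(z),
    sd_intensity_ui = if (length(z) == 1L) 0 else stats::sd(z)
  )
  structure(
    list(source_id = as.character(lesion_id), z = z, mask = mask,
         characteristics = chars),
    class = "lesion_patch"
  )
}

#' @export
print.lesion_patch <- function(x, ...) {
  cat(sprintf("<lesion_patch '%s'> %d voxels, %.2f mm^3, %s\n",
              x$source_id, length(x$z),
              x$characteristics$volume_native_mm3,
              x$characteristics$laterality))
  invisible(x)
}

#' Transplant a lesion patch into a control image
#'
#' Builds a chimeric image: the control volume with the patch's lesion
#' written in. The patch's unit-invariant intensities `z` are mapped into
#' the control's intensity units by the inverse z-map
#' `mu_c + sigma_c * z`, where `mu_c`, `sigma_c` are the mean and sample SD
#' of the control over `control_reference_mask` (whole image by default).
#' Outside the transformed lesion mask the chimeric image equals the
#' control bit-exactly — no feathering or blending — so any measured
#' difference outside the mask (in particular in the contralesional
#' hemisphere) is attributable to the measurement algorithm, not to the
#' simulation.
#'
#' Lesions that land bilaterally on the control grid are rejected, matching
#' the exclusion of bilateral lesions from the lesioned/contralesional
#' contrast.
#'
#' @param patch A [extract_patch()] result.
#' @param control Control [image_volume()].
#' @param control_reference_mask Reference set on the control grid (`NULL`
#'   = whole image).
#' @param transform World-to-world transform from patient to control space
#'   (`"identity"` or 4x4 matrix); see [resample_mask()].
#' @param bilateral_fraction Passed to [determine_laterality()].
#' @param case_id Identifier; default `"<lesion>_x_<control>"`.
#' @return A `simulated_case`: `case_id`, `control_id`, `lesion_id`,
#'   `chimeric` ([image_volume()]), `transformed_mask`, `laterality`
#'   (`"lh"`/`"rh"`), `volume_transplanted_mm3`.
#' @export
transplant <- function(patch, control, control_reference_mask = NULL,
                       transform = "identity", bilateral_fraction = 0.02,
                       case_id = NULL) {
  if (is.null(case_id)) {
    case_id <- paste0(patch$source_id, "_x_", control$id)
  }
  n_src <- sum(patch$mask$data != 0)
  if (n_src == 0L) {
    # empty transplant: the chimeric image IS the control (null case)
    empty <- binary_mask(array(0, dim = dim(control$data)), control$affine,
                         id = paste0(patch$source_id, "_on_", control$id))
    return(structure(
      list(case_id = case_id, control_id = control$id,
           lesion_id = patch$source_id,
           chimeric = image_volume(control$data, control$affine, id = case_id),
           transformed_mask = empty, laterality = NA_character_,
           volume_transplanted_mm3 = 0),
      class = "simulated_case"
    ))
  }

  tmask <- resample_mask(patch$mask, transform, control)
  sel <- tmask$data != 0

  # resample the z-field; identity on a matched grid is an exact copy
  if (same_grid_identity(transform, patch$mask, control)) {
    zfield <- array(0, dim = dim(control$data))
    zfield[patch$mask$data != 0] <- patch$z
    z_at <- zfield[sel]
  } else {
    zfield <- array(0, dim = dim(patch$mask$data))
    zfield[patch$mask$data != 0] <- patch$z
    coords <- source_voxel_coords(patch$mask, control, transform)[sel, , drop = FALSE]
    zw <- trilinear_sample(zfield, coords)
    ww <- trilinear_sample(patch$mask$data, coords)
    # normalized interpolation: avoid diluting edge intensities toward 0
    z_at <- ifelse(ww > 0, zw / ww, 0)
  }

  # the chimeric image's non-lesioned voxels are the reference set, so the
  # region about to be overwritten is excluded; this makes the transfer the
  # exact inverse of extraction when a patch returns to its own source
  if (is.null(control_reference_mask)) {
    ref_vals <- control$data[!sel]
  } else {
    check_same_grid(control, control_reference_mask)
    ref_vals <- control$data[control_reference_mask$data != 0 & !sel]
  }
  mu_c <- mean(ref_vals)
  sigma_c <- stats::sd(ref_vals)
  if (!is.finite(sigma_c) || sigma_c <= 0) {
    stop("control has zero intensity variance over the reference set",
         call. = FALSE)
  }

  lat <- determine_laterality(tmask, bilateral_fraction)
  if (lat == "bilateral") {
    stop(sprintf("lesion '%s' lands bilaterally on control '%s'; rejected",
                 patch$source_id, control$id), call. = FALSE)
  }

  chim <- control$data
  chim[sel] <- mu_c + sigma_c * z_at
  structure(
    list(case_id = case_id, control_id = control$id,
         lesion_id = patch$source_id,
         chimeric = image_volume(chim, control$affine, id = case_id),
         transformed_mask = tmask, laterality = lat,
         volume_transplanted_mm3 = lesion_volume(tmask)),
    class = "simulated_case"
  )
}

#' @export
print.simulated_case <- function(x, ...) {
  cat(sprintf("<simulated_case '%s'> lesion %s in control %s (%s, %.2f mm^3)\n",
              x$case_id, x$lesion_id, x$control_id, x$laterality,
              x$volume_transplanted_mm3))
  invisible(x)
}

#' Build the fully crossed simulated-lesion dataset
#'
#' Transplants every lesion patch into every control image, in
#' deterministic lesion-major, control-minor order: with `n_l` lesions and
#' `n_c` controls the result has exactly `n_l * n_c` cases. Each case's
#' manifest row records the pairing, laterality, transplanted volume, and a
#' status; in non-strict mode an individual transplant failure (e.g. a
#' bilateral landing) is recorded and the run continues.
#'
#' @param patches List of [extract_patch()] results with unique ids.
#' @param controls List of [image_volume()]s with unique ids.
#' @param transform A single transform (see [transplant()]) or a function
#'   `function(lesion_id, control_id)` returning one per pairing.
#' @param control_reference_masks Optional named list (by control id) of
#'   reference masks.
#' @param strict If `TRUE`, any transplant error aborts the run.
#' @param bilateral_fraction Passed to [transplant()].
#' @return A list with `cases` (named list of `simulated_case`, failed
#'   pairings omitted) and `manifest` (tibble: `case_id`, `lesion_id`,
#'   `control_id`, `laterality`, `volume_transplanted_mm3`, `status`).
#' @export
build_crossed_dataset <- function(patches, controls, transform = "identity",
                                  control_reference_masks = NULL,
                                  strict = FALSE, bilateral_fraction = 0.02) {
  lesion_ids <- vapply(patches, function(p) p$source_id, character(1))
  control_ids <- vapply(controls, function(cv) cv$id, character(1))
  if (anyDuplicated(lesion_ids)) stop("duplicate lesion ids", call. = FALSE)
  if (anyDuplicated(control_ids)) stop("duplicate control ids", call. = FALSE)

  cases <- list()
  rows <- vector("list", length(patches) * length(controls))
  r <- 0L
  for (p in patches) {
    for (cv in controls) {
      r <- r + 1L
      case_id <- paste0(p$source_id, "_x_", cv$id)
      tf <- if (is.function(transform)) transform(p$source_id, cv$id) else transform
      ref <- if (!is.null(control_reference_masks)) {
        control_reference_masks[[cv$id]]
      } else NULL
      res <- tryCatch(
        transplant(p, cv, control_reference_mask = ref, transform = tf,
                   bilateral_fraction = bilateral_fraction, case_id = case_id),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        if (strict) {
          stop(sprintf("transplant failed for case '%s': %s", case_id,
                       conditionMessage(res)), call. = FALSE)
        }
        rows[[r]] <- tibble::tibble(
          case_id = case_id, lesion_id = p$source_id, control_id = cv$id,
          laterality = NA_character_, volume_transplanted_mm3 = NA_real_,
          status = paste0("error: ", conditionMessage(res))
        )
      } else {
        cases[[case_id]] <- res
        rows[[r]] <- tibble::tibble(
          case_id = case_id, lesion_id = p$source_id, control_id = cv$id,
          laterality = res$laterality,
          volume_transplanted_mm3 = res$volume_transplanted_mm3,
          status = "ok"
        )
      }
    }
  }
  list(cases = cases, manifest = dplyr::bind_rows(rows))
}
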