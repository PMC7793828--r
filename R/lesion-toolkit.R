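#' Lesion volume from a binary mask
#'
#' The count of nonzero mask voxels multiplied by the voxel volume, i.e. the
#' standard voxel-counting volume of a manually drawn lesion mask. An empty
#' mask has volume 0.
#'
#' @param mask A [binary_mask()].
#' @return Lesion volume in mm^3.
#' @examples
#' m <- binary_mask(array(c(rep(1, 3), rep(0, 5)), c(2, 2, 2)))
#' lesion_volume(m) # 3 voxels x 1 mm^3
#' @export
lesion_volume <- function(mask) {
  sum(mask$data != 0) * voxel_volume(mask)
}

#' Normalize an image into unit-invariant intensity space
#'
#' T1-weighted MR intensities are not quantitative, so intensities from
#' different scans cannot be compared directly. This maps a volume into a
#' unit-invariant space by demeaning and scaling with the statistics of the
#' non-lesioned voxels: `z = (x - mu) / sigma`, where `mu` and `sigma` are
#' the mean and sample SD (n - 1 denominator) of intensities at reference
#' voxels *excluding* any lesion voxels. The map is applied to the whole
#' volume, so reference non-lesion voxels of the output have mean 0 and SD 1.
#'
#' The reference set is caller-supplied: the default whole-image reference
#' reads "all non-lesioned voxels" literally (background included); pass a
#' brain mask to restrict to intracranial voxels. The choice is recorded in
#' the returned volume's id.
#'
#' @param vol An [image_volume()].
#' @param lesion_mask A [binary_mask()] of voxels to exclude from the
#'   reference statistics (may be empty).
#' @param reference_mask A [binary_mask()] defining the reference set, or
#'   `NULL` (default) for the whole image.
#' @return An [image_volume()] of z-scored intensities; attributes
#'   `ui_mean` and `ui_sd` carry the statistics used.
#' @examples
#' vol <- image_volume(array(c(10, 20, 30, 40), c(4, 1, 1)))
#' les <- binary_mask(array(c(0, 0, 0, 1), c(4, 1, 1)))
#' zed <- unit_invariant_normalize(vol, les)
#' zed$data[1:3] # -1, 0, 1
#' @export
unit_invariant_normalize <- function(vol, lesion_mask, reference_mask = NULL) {
  check_same_grid(vol, lesion_mask)
  if (is.null(reference_mask)) {
    ref <- array(1, dim = dim(vol$data))
    ref_label <- "whole-image"
  } else {
    check_same_grid(vol, reference_mask)
    ref <- reference_mask$data
    ref_label <- reference_mask$id
  }
  sel <- ref != 0 & lesion_mask$data == 0
  if (!any(sel)) {
    stop("reference set is empty after excluding lesion voxels", call. = FALSE)
  }
  x <- vol$data[sel]
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("reference intensities have zero variance; cannot normalize",
         call. = FALSE)
  }
  out <- image_volume((vol$data - mu) / sigma, vol$affine,
                      id = paste0(vol$id, "_ui[", ref_label, "]"))
  attr(out, "ui_mean") <- mu
  attr(out, "ui_sd") <- sigma
  out
}

#' Lesion intensity statistics in unit-invariant space
#'
#' Mean and sample SD of normalized intensities over the lesion voxels.
#' These are the two intensity covariates used to model lesion-induced
#' error as a function of lesion appearance. A single-voxel lesion has
#' SD 0 by convention.
#'
#' @param norm_vol A volume produced by [unit_invariant_normalize()].
#' @param mask A non-empty [binary_mask()] of lesion voxels.
#' @return A one-row tibble with columns `mean_intensity_ui`,
#'   `sd_intensity_ui`, `n_voxels`.
#' @export
lesion_intensity_stats <- function(norm_vol, mask) {
  check_same_grid(norm_vol, mask)
  sel <- mask$data != 0
  n <- sum(sel)
  if (n == 0L) stop("lesion mask is empty", call. = FALSE)
  x <- norm_vol$data[sel]
  tibble::tibble(
    mean_intensity_ui = mean(x),
    sd_intensity_ui = if (n == 1L) 0 else stats::sd(x),
    n_voxels = n
  )
}

#' Determine lesion laterality
#'
#' Classifies each nonzero mask voxel by the sign of its world x coordinate
#' (RAS+: x < 0 is the left hemisphere, x > 0 the right; voxels exactly on
#' the mid-sagittal plane are ignored). If the minority hemisphere holds
#' more than `bilateral_fraction` of the classified voxels, the lesion is
#' bilateral; otherwise the majority hemisphere is returned. Bilateral
#' lesions preclude a lesioned/contralesional contrast and are excluded
#' downstream.
#'
#' @param mask A non-empty [binary_mask()] whose affine maps to RAS+ world.
#' @param bilateral_fraction Minority-hemisphere proportion above which a
#'   lesion is called bilateral (default 0.02, absorbing midline-straddling
#'   edge voxels).
#' @return One of `"lh"`, `"rh"`, `"bilateral"`.
#' @export
determine_laterality <- function(mask, bilateral_fraction = 0.02) {
  idx <- which(mask$data != 0)
  if (length(idx) == 0L) stop("mask is empty", call. = FALSE)
  wx <- world_coords(mask, idx)[, 1]
  n_l <- sum(wx < 0)
  n_r <- sum(wx > 0)
  if (n_l + n_r == 0L) {
    stop("all mask voxels lie exactly on the midline; laterality undefined",
         call. = FALSE)
  }
  minority <- min(n_l, n_r) / (n_l + n_r)
  if (minority > bilateral_fraction) return("bilateral")
  if (n_l >= n_r) "lh" else "rh"
}

#' Characterize a lesion
#'
#' One-stop descriptive characterization: voxel-counting volume, laterality,
#' and intensity statistics in the unit-invariant space of the supplied
#' image. Returns the tabular row exported per lesion.
#'
#' @param vol The image the mask was drawn on (patient native space, or a
#'   chimeric image for transplanted lesions).
#' @param mask The lesion [binary_mask()].
#' @param reference_mask Reference set for normalization; `NULL` = whole
#'   image (see [unit_invariant_normalize()]).
#' @param lesion_id Identifier; defaults to the mask id.
#' @param bilateral_fraction Passed to [determine_laterality()].
#' @return A one-row tibble: `lesion_id`, `volume_native_mm3`, `laterality`,
#'   `mean_intensity_ui`, `sd_intensity_ui`.
#' @export
characterize_lesion <- function(vol, mask, reference_mask = NULL,
                                lesion_id = mask$id,
                                bilateral_fraction = 0.02) {
  norm_vol <- unit_invariant_normalize(vol, mask, reference_mask)
  stats <- lesion_intensity_stats(norm_vol, mask)
  tibble::tibble(
    lesion_id = as.character(lesion_id),
    volume_native_mm3 = lesion_volume(mask),
    laterality = determine_laterality(mask, bilateral_fraction),
    mean_intensity_ui = stats$mean_intensity_ui,
    sd_intensity_ui = stats$sd_intensity_ui
  )
}
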