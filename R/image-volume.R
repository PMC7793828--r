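#' Construct a 3-D image volume
#'
#' An `image_volume` is the package's container for a 3-D scalar intensity
#' grid together with its voxel-index-to-world affine. The world frame is
#' RAS+ in millimetres, with the mid-sagittal plane at world x = 0; voxel
#' indices are 0-based when mapped through the affine.
#'
#' @param data A 3-D numeric array of intensities (arbitrary units).
#' @param affine A 4x4 numeric matrix mapping 0-based voxel indices
#'   `(i, j, k, 1)` to world RAS+ coordinates in mm.
#' @param id Character label for the volume.
#' @return An object of class `image_volume` with fields `data`, `affine`,
#'   `voxel_dims` (mm, derived from the affine column norms) and `id`.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 4)), diag(4), id = "empty")
#' voxel_dims(vol)
#' @export
image_volume <- function(data, affine = diag(4), id = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    nd <- if (is.array(data)) length(dim(data)) else NA_integer_
    stop("`data` must be a 3-D array; got ", nd, " dimensions", call. = FALSE)
  }
  if (any(dim(data) < 1L)) {
    stop("all three dimensions must be >= 1", call. = FALSE)
  }
  affine <- validate_affine(affine)
  storage.mode(data) <- "double"
  structure(
    list(
      data = data,
      affine = affine,
      voxel_dims = affine_voxel_dims(affine),
      id = as.character(id)
    ),
    class = "image_volume"
  )
}

validate_affine <- function(affine) {
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) {
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  }
  storage.mode(affine) <- "double"
  vd <- affine_voxel_dims(affine)
  if (any(vd <= 0)) {
    stop("affine columns imply non-positive voxel dimensions", call. = FALSE)
  }
  affine
}

affine_voxel_dims <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf(
    "<image_volume '%s'> %s voxels, %.3g x %.3g x %.3g mm\n",
    x$id, paste(dim(x$data), collapse = " x "),
    x$voxel_dims[1], x$voxel_dims[2], x$voxel_dims[3]
  ))
  invisible(x)
}

#' Construct a binary mask on an image grid
#'
#' @param data A 3-D array whose values are exactly 0 or 1 (logical arrays
#'   are accepted and coerced).
#' @param affine As in [image_volume()].
#' @param id Character label.
#' @return An object of class `binary_mask` (also an `image_volume`).
#' @export
binary_mask <- function(data, affine = diag(4), id = "mask") {
  if (is.logical(data)) {
    data <- array(as.double(data), dim = dim(data))
  }
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  }
  vol <- image_volume(data, affine, id)
  class(vol) <- c("binary_mask", class(vol))
  vol
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf(
    "<binary_mask '%s'> %s voxels, %d set\n",
    x$id, paste(dim(x$data), collapse = " x "), sum(x$data != 0)
  ))
  invisible(x)
}

#' Assert that two volumes share a voxel grid
#'
#' Pairing a mask with an image requires identical grid shape and an affine
#' agreeing entrywise within `tol`. Grids are never auto-resampled: silent
#' resampling is the classic source of off-by-one volume errors, so any
#' mismatch is an error at the point of pairing.
#'
#' @param a,b `image_volume` (or `binary_mask`) objects.
#' @param tol Per-entry affine tolerance (default 1e-4).
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf(
      "grid shapes differ: '%s' is %s, '%s' is %s",
      a$id, paste(dim(a$data), collapse = "x"),
      b$id, paste(dim(b$data), collapse = "x")
    ), call. = FALSE)
  }
  if (max(abs(a$affine - b$affine)) > tol) {
    stop(sprintf("affines of '%s' and '%s' differ beyond tolerance %g",
                 a$id, b$id, tol), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D NIfTI-1 file (optionally gzipped) into an [image_volume()].
#' The grid and affine are returned exactly as stored; the only intensity
#' transformation applied is the format's own `scl_slope`/`scl_inter`
#' scaling convention. 4-D (or higher) images are rejected rather than
#' squeezed: the pipeline is defined on 3-D T1w volumes only.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param id Label for the volume; defaults to the file name.
#' @return An [image_volume()].
#' @export
read_nifti <- function(path, id = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3-D image, got %d dimensions (%s) in %s",
                 length(d), paste(d, collapse = " x "), path), call. = FALSE)
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  image_volume(
    array(as.double(img), dim = d), aff,
    id = if (is.null(id)) sub("\\.nii(\\.gz)?$", "", basename(path)) else id
  )
}

#' Read a NIfTI-1 mask
#'
#' As [read_nifti()], then validates/binarizes values to {0,1}. Any nonzero
#' stored value counts as 1 (masks are sometimes stored with value 255).
#'
#' @inheritParams read_nifti
#' @return A [binary_mask()].
#' @export
read_nifti_mask <- function(path, id = NULL) {
  vol <- read_nifti(path, id = id)
  binary_mask(array(as.double(vol$data != 0), dim = dim(vol$data)),
              vol$affine, id = vol$id)
}

#' Write a NIfTI-1 volume
#'
#' Writes intensities as float64 so that a read/write round trip reproduces
#' the data bit-exactly and the affine within 1e-6.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(vol, path) {
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  }
  img <- RNifti::asNifti(vol$data, datatype = "double")
  aff <- vol$affine
  attr(aff, "code") <- 2L
  RNifti::sform(img) <- aff
  ok <- tryCatch({
    RNifti::writeNifti(img, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  if (!file.exists(path)) stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

#' Volume of one voxel in cubic millimetres
#'
#' The absolute value of the determinant of the affine's upper-left 3x3
#' block: `dx * dy * dz` for an axis-aligned grid, and invariant under
#' rotation of the affine.
#'
#' @param vol An [image_volume()] or [binary_mask()].
#' @return Scalar voxel volume in mm^3.
#' @examples
#' vol <- image_volume(array(0, c(2, 2, 2)), diag(c(1, 0.5, 0.5, 1)))
#' voxel_volume(vol) # 0.25
#' @export
voxel_volume <- function(vol) {
  abs(det(vol$affine[1:3, 1:3]))
}

#' @rdname image_volume
#' @param vol An `image_volume`.
#' @export
voxel_dims <- function(vol) vol$voxel_dims

# World coordinates (n x 3) of given 1-based voxel linear indices.
world_coords <- function(vol, linear_idx) {
  d <- dim(vol$data)
  idx0 <- arrayInd(linear_idx, d) - 1L # 0-based voxel indices
  xyz1 <- cbind(idx0, 1)
  t(vol$affine %*% t(xyz1))[, 1:3, drop = FALSE]
}
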