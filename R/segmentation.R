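STATS_KEYS <- c(lh_cortex_mm3 = "lhCortexVol",
                rh_cortex_mm3 = "rhCortexVol",
                lh_cwm_mm3 = "lhCerebralWhiteMatterVol",
                rh_cwm_mm3 = "rhCerebralWhiteMatterVol")

#' Parse a segmenter summary-stats file
#'
#' Reads the plain-text summary dialect used by surface segmenters:
#' comment lines start with `#`, and whole-brain measures appear as
#' `# Measure <name>, <key>, <description>, <value>, mm^3`. The four keys
#' extracted are `lhCortexVol`, `rhCortexVol`, `lhCerebralWhiteMatterVol`
#' and `rhCerebralWhiteMatterVol`; all other measures are ignored, and the
#' order of lines is irrelevant.
#'
#' @param path Path to the stats file.
#' @param subject_id Subject identifier; defaults to the file name.
#' @return A one-row tibble: `subject_id`, `lh_cortex_mm3`,
#'   `rh_cortex_mm3`, `lh_cwm_mm3`, `rh_cwm_mm3`, `segmenter`, `mode`.
#' @export
parse_stats_file <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("stats file not found: ", path, call. = FALSE)
  if (is.null(subject_id)) subject_id <- sub("\\.stats$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  measures <- grep("^#\\s*Measure\\b", lines, value = TRUE)
  vols <- stats::setNames(rep(NA_real_, 4L), names(STATS_KEYS))
  for (ln in measures) {
    body <- sub("^#\\s*Measure\\s*", "", ln)
    fields <- trimws(strsplit(body, ",")[[1]])
    if (length(fields) < 4) next
    key <- fields[2]
    hit <- match(key, STATS_KEYS)
    if (!is.na(hit)) {
      val <- suppressWarnings(as.numeric(fields[4]))
      if (is.na(val)) {
        stop(sprintf("malformed value field for measure '%s': '%s'",
                     key, fields[4]), call. = FALSE)
      }
      vols[hit] <- val
    }
  }
  missing <- STATS_KEYS[is.na(vols)]
  if (length(missing) > 0) {
    stop("stats file missing measure key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    subject_id = subject_id,
    lh_cortex_mm3 = vols[["lh_cortex_mm3"]],
    rh_cortex_mm3 = vols[["rh_cortex_mm3"]],
    lh_cwm_mm3 = vols[["lh_cwm_mm3"]],
    rh_cwm_mm3 = vols[["rh_cwm_mm3"]],
    segmenter = "external", mode = "external"
  )
}

#' Write a segmenter summary-stats file
#'
#' The inverse of [parse_stats_file()], used to create fixtures and to
#' round-trip mock results through the external-adapter path.
#'
#' @param result One-row tibble with the four volume columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stats_file <- function(result, path) {
  hdr <- c("# Title Segmentation Statistics", "#")
  rows <- sprintf("# Measure %s, %s, %s, %.6f, mm^3",
                  c("Cortex", "Cortex", "CerebralWhiteMatter",
                    "CerebralWhiteMatter"),
                  STATS_KEYS,
                  c("Left hemisphere cortical gray matter volume",
                    "Right hemisphere cortical gray matter volume",
                    "Left hemisphere cerebral white matter volume",
                    "Right hemisphere cerebral white matter volume"),
                  c(result$lh_cortex_mm3, result$rh_cortex_mm3,
                    result$lh_cwm_mm3, result$rh_cwm_mm3))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Reference intensities for the mock segmenter
#'
#' Extracts from a phantom the information the mock segmenter classifies
#' against: the tissue class mean intensities and the mean/SD of the
#' phantom's brain voxels (every labelled voxel), which define the target
#' distribution of the global intensity-normalization mode.
#'
#' @param phantom A [generate_phantom()] result.
#' @return A `segment_reference` list: `class_means` (named `csf`, `gm`,
#'   `wm`), `bg_mean`, `brain_mean`, `brain_sd`.
#' @export
segment_reference <- function(phantom) {
  brain <- phantom$image$data[phantom$labels > 0L]
  structure(
    list(class_means = phantom$spec$class_means[c("csf", "gm", "wm")],
         bg_mean = 0,
         brain_mean = mean(brain),
         brain_sd = stats::sd(brain)),
    class = "segment_reference"
  )
}

#' Mock volumetric segmenter
#'
#' A deliberately simple, fully transparent segmenter that measures
#' hemispheric cortex (GM) and cerebral-white-matter volumes from a
#' T1w-like volume by intensity classification, with two modes that
#' bracket the behaviour of interest:
#'
#' * `"local"` — each brain voxel is assigned to the nearest of the known
#'   CSF/GM/WM class mean intensities (fixed thresholds midway between
#'   class means). Classification is purely per-voxel, so a lesion cannot
#'   influence any voxel outside itself: contralesional volumes are exact.
#' * `"global-normalized"` — before classification, the whole image is
#'   affinely rescaled so that its brain-voxel mean and SD match the
#'   reference phantom's. A lesion shifts the image-wide mean and SD, so
#'   the rescaling — and hence every voxel's effective class boundary —
#'   moves everywhere, transmitting lesion-induced error into the
#'   contralesional hemisphere. This operationalizes the mechanism by
#'   which image-global intensity normalization steps in real pipelines
#'   can propagate focal abnormalities into global measures.
#'
#' Brain voxels are those with raw intensity above the background/CSF
#' midpoint; the hemisphere split is the world x = 0 plane, with voxels
#' exactly on the plane assigned to neither hemisphere.
#'
#' @param vol An [image_volume()].
#' @param reference A [segment_reference()].
#' @param mode `"local"` or `"global-normalized"`.
#' @param subject_id Identifier for the result row; defaults to `vol$id`.
#' @return A one-row tibble as in [parse_stats_file()], with
#'   `segmenter = "mock"`.
#' @export
mock_segment <- function(vol, reference,
                         mode = c("local", "global-normalized"),
                         subject_id = vol$id) {
  mode <- match.arg(mode)
  cm <- reference$class_means
  if (any(diff(cm) <= 0) || reference$bg_mean >= cm[1]) {
    stop("class mean intensities must be strictly increasing (bg < csf < gm < wm)",
         call. = FALSE)
  }
  t_bg <- (reference$bg_mean + cm[["csf"]]) / 2
  t_csf_gm <- (cm[["csf"]] + cm[["gm"]]) / 2
  t_gm_wm <- (cm[["gm"]] + cm[["wm"]]) / 2

  x <- vol$data
  brain <- x > t_bg
  if (!any(brain)) stop("no brain voxels above background threshold",
                        call. = FALSE)
  vals <- x[brain]
  if (mode == "global-normalized") {
    m_img <- mean(vals)
    s_img <- stats::sd(vals)
    if (!is.finite(s_img) || s_img <= 0) {
      stop("degenerate brain intensity distribution; cannot normalize",
           call. = FALSE)
    }
    vals <- (vals - m_img) / s_img * reference$brain_sd + reference$brain_mean
  }
  cls <- ifelse(vals >= t_gm_wm, 3L, ifelse(vals >= t_csf_gm, 2L, 1L))

  wx <- world_coords(vol, which(brain))[, 1]
  vv <- voxel_volume(vol)
  count <- function(side, k) {
    sel <- if (side == "lh") wx < 0 else wx > 0
    sum(cls == k & sel) * vv
  }
  res <- tibble::tibble(
    subject_id = subject_id,
    lh_cortex_mm3 = count("lh", 2L), rh_cortex_mm3 = count("rh", 2L),
    lh_cwm_mm3 = count("lh", 3L), rh_cwm_mm3 = count("rh", 3L),
    segmenter = "mock", mode = mode
  )
  # brain extraction happens before any rescaling, so the total classified
  # volume is mode-invariant even when classes shift between modes
  attr(res, "brain_volume_mm3") <- sum(brain) * vv
  res
}

#' Run an external segmenter through a command template
#'
#' Thin adapter around a shell command. The template may contain the
#' placeholders `{subject_id}`, `{t1_path}` and `{out_dir}`; after the
#' command exits successfully the adapter parses
#' `<out_dir>/<subject_id>.stats`. The command line and exit status are
#' attached to the result as attribute `"run_log"`. Never used by the
#' package's own analyses (the mock segmenter is); provided so real
#' segmenter outputs can flow through the identical downstream tabulation.
#'
#' @param subject_id Subject identifier.
#' @param t1_path Path to the input T1w NIfTI.
#' @param out_dir Output directory (created if absent).
#' @param command_template Shell command with placeholders.
#' @param timeout Seconds before the command is killed (default 3600).
#' @return As [parse_stats_file()].
#' @export
run_external_segmenter <- function(subject_id, t1_path, out_dir,
                                   command_template, timeout = 3600) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cmd <- command_template
  subs <- c(subject_id = subject_id, t1_path = t1_path, out_dir = out_dir)
  for (nm in names(subs)) {
    cmd <- gsub(paste0("{", nm, "}"), subs[[nm]], cmd, fixed = TRUE)
  }
  status <- system(cmd, timeout = timeout)
  if (!identical(status, 0L)) {
    stop(sprintf("external segmenter failed (exit status %s): %s",
                 status, cmd), call. = FALSE)
  }
  stats_path <- file.path(out_dir, paste0(subject_id, ".stats"))
  if (!file.exists(stats_path)) {
    stop(sprintf("segmenter exited 0 but stats file is absent: %s",
                 stats_path), call. = FALSE)
  }
  res <- parse_stats_file(stats_path, subject_id = subject_id)
  attr(res, "run_log") <- list(command = cmd, exit_status = status)
  res
}
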