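#' Recode left/right volumes to lesioned/contralesional
#'
#' The analysis is blind to left vs right: what matters is whether a
#' hemisphere carries the (simulated) lesion. Given a segmentation result
#' and the lesion's laterality, returns the four volumes keyed by
#' hemisphere role. The matched ground-truth case must be recoded with the
#' same laterality so the mapping is preserved across the pair.
#'
#' @param result One-row segmentation tibble (see [mock_segment()]).
#' @param laterality `"lh"` or `"rh"` (bilateral is an error).
#' @return A tibble with 4 rows: `hemi_role` (`lesioned` /
#'   `contralesional`), `measure` (`cortex` / `cwm`), `volume_mm3`.
#' @export
recode_hemispheres <- function(result, laterality) {
  if (!laterality %in% c("lh", "rh")) {
    stop("laterality must be 'lh' or 'rh'; bilateral cases are excluded",
         call. = FALSE)
  }
  les <- laterality
  con <- if (laterality == "lh") "rh" else "lh"
  tibble::tibble(
    hemi_role = rep(c("lesioned", "contralesional"), each = 2L),
    measure = rep(c("cortex", "cwm"), times = 2L),
    volume_mm3 = c(result[[paste0(les, "_cortex_mm3")]],
                   result[[paste0(les, "_cwm_mm3")]],
                   result[[paste0(con, "_cortex_mm3")]],
                   result[[paste0(con, "_cwm_mm3")]])
  )
}

#' Percent volume difference
#'
#' `PVD = 100 * |v1 - v2| / ((v1 + v2) / 2)`: the absolute volume
#' difference as a percentage of the mean of the two volumes. Symmetric in
#' its arguments, invariant to rescaling both volumes, zero iff the
#' volumes are equal, and bounded above by 200 (approached as one volume
#' tends to zero).
#'
#' @param v_sim,v_gt Volumes in mm^3 (both >= 0, not both zero).
#' @return PVD in percent. Vectorized.
#' @examples
#' compute_pvd(105, 95) # 10
#' @export
compute_pvd <- function(v_sim, v_gt) {
  if (any(v_sim < 0 | v_gt < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (any(v_sim + v_gt == 0)) {
    stop("PVD undefined when both volumes are zero", call. = FALSE)
  }
  100 * abs(v_sim - v_gt) / ((v_sim + v_gt) / 2)
}

#' Build the long measurement table
#'
#' Assembles the repeated-measures structure the mixed models consume: for
#' every simulated case (one lesion applied to one control), eight rows —
#' 2 case types (simulated / ground truth) x 2 hemisphere roles x 2
#' measures — where the ground-truth rows are the unmodified control's
#' volumes recoded with the *same* laterality as the simulated case.
#' Ground-truth rows carry `lesion_id = "0"` (no lesion was applied).
#'
#' @param sim_results Segmentation tibble for simulated cases, one row per
#'   `subject_id` matching `manifest$case_id`.
#' @param gt_results Segmentation tibble for controls, one row per
#'   `subject_id` matching `manifest$control_id`.
#' @param manifest Manifest tibble from [build_crossed_dataset()]; only
#'   rows with `status == "ok"` are tabulated.
#' @return A tibble of `8 * n_pairs` rows: `pair_id`, `case`, `hemi_role`,
#'   `measure`, `volume_mm3`, `lesion_id`, `control_id`.
#' @export
build_long_table <- function(sim_results, gt_results, manifest) {
  ok <- manifest[manifest$status == "ok", , drop = FALSE]
  rows <- purrr::pmap(
    list(ok$case_id, ok$lesion_id, ok$control_id, ok$laterality),
    function(case_id, lesion_id, control_id, laterality) {
      sim <- sim_results[sim_results$subject_id == case_id, , drop = FALSE]
      gt <- gt_results[gt_results$subject_id == control_id, , drop = FALSE]
      if (nrow(sim) != 1L) {
        stop("missing or duplicated simulated segmentation for pair ",
             case_id, call. = FALSE)
      }
      if (nrow(gt) != 1L) {
        stop("missing or duplicated ground-truth segmentation for pair ",
             case_id, " (control ", control_id, ")", call. = FALSE)
      }
      dplyr::bind_rows(
        dplyr::mutate(recode_hemispheres(sim, laterality),
                      case = "simulated", lesion_id = lesion_id),
        dplyr::mutate(recode_hemispheres(gt, laterality),
                      case = "ground_truth", lesion_id = "0")
      ) |>
        dplyr::mutate(pair_id = case_id, control_id = control_id)
    }
  )
  dplyr::bind_rows(rows) |>
    dplyr::select("pair_id", "case", "hemi_role", "measure", "volume_mm3",
                  "lesion_id", "control_id")
}

#' PVD table from the long measurement table
#'
#' Collapses each (pair, hemisphere role, measure) cell of the long table
#' to a single PVD between the simulated and ground-truth volumes. The
#' signed difference (simulated minus ground truth, mm^3) is kept as a
#' diagnostic column since the direction of error is interpretable even
#' though PVD itself is unsigned.
#'
#' @param long_table Output of [build_long_table()].
#' @return A tibble with `pair_id`, `lesion_id`, `control_id`,
#'   `hemi_role`, `measure`, `pvd`, `signed_diff_mm3`.
#' @export
pvd_table <- function(long_table) {
  wide <- long_table |>
    dplyr::select("pair_id", "control_id", "case", "hemi_role", "measure",
                  "volume_mm3") |>
    tidyr::pivot_wider(names_from = "case", values_from = "volume_mm3")
  lesions <- long_table |>
    dplyr::filter(.data$case == "simulated") |>
    dplyr::distinct(.data$pair_id, .data$lesion_id)
  wide |>
    dplyr::left_join(lesions, by = "pair_id") |>
    dplyr::mutate(
      pvd = compute_pvd(.data$simulated, .data$ground_truth),
      signed_diff_mm3 = .data$simulated - .data$ground_truth
    ) |>
    dplyr::select("pair_id", "lesion_id", "control_id", "hemi_role",
                  "measure", "pvd", "signed_diff_mm3")
}

#' Trimmed mean
#'
#' Discards the `floor(trim * n)` smallest and largest values and averages
#' the rest (no interpolation between order statistics). With `trim = 0`
#' this is the arithmetic mean.
#'
#' @param values Non-empty numeric vector.
#' @param trim Proportion per tail in `[0, 0.5)` (default 0.2).
#' @return The trimmed mean.
#' @examples
#' trimmed_mean(1:10) # 5.5
#' @export
trimmed_mean <- function(values, trim = 0.2) {
  n <- length(values)
  if (n == 0L) stop("empty input", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  k <- floor(trim * n)
  mean(sort(values)[(k + 1):(n - k)])
}

#' Summarize PVD by hemisphere role and measure
#'
#' The descriptive summary reported alongside the models: per (hemisphere
#' role x measure), the 20% trimmed mean, the median, the maximum, and the
#' count of cases whose PVD exceeds a threshold (1% by default).
#'
#' @param pvds Output of [pvd_table()].
#' @param trim Trim proportion for [trimmed_mean()].
#' @param threshold_pct Count cases with PVD strictly above this (percent).
#' @return A tibble: `hemi_role`, `measure`, `trimmed_mean`, `median`,
#'   `max`, `n_above_threshold`, `n`.
#' @export
pvd_summary <- function(pvds, trim = 0.2, threshold_pct = 1) {
  if (nrow(pvds) == 0L) stop("empty PVD table", call. = FALSE)
  pvds |>
    dplyr::group_by(.data$hemi_role, .data$measure) |>
    dplyr::summarise(
      trimmed_mean = trimmed_mean(.data$pvd, trim = trim),
      median = stats::median(.data$pvd),
      max = max(.data$pvd),
      n_above_threshold = sum(.data$pvd > threshold_pct),
      n = dplyr::n(),
      .groups = "drop"
    )
}
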