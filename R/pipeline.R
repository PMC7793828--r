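PIPELINE_CONFIG_KEYS <- c(
  "out_dir", "seed", "n_lesions", "n_controls", "grid_shape", "voxel_dims",
  "class_noise_sd", "segmenter", "segmenter_mode", "hypotheses", "trim",
  "bilateral_fraction", "strict", "write_images", "transform",
  "lesions_dir", "controls_dir", "segmenter_command"
)

pipeline_config_defaults <- function() {
  list(
    out_dir = "lesionbench_run", seed = 1L, n_lesions = 3L, n_controls = 2L,
    grid_shape = c(48L, 48L, 48L), voxel_dims = c(1, 1, 1),
    class_noise_sd = 12, segmenter = "mock",
    segmenter_mode = "global-normalized", hypotheses = c("a", "b", "c"),
    trim = 0.2, bilateral_fraction = 0.02, strict = FALSE,
    write_images = TRUE, transform = "identity"
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills defaults, and
#' validates it. All problems are reported at once in a single error,
#' and unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated, default-filled configuration (class
#'   `run_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file or list",
                             call. = FALSE)
  errors <- character()
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown config key(s): ",
                               paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(pipeline_config_defaults(),
                           config[intersect(names(config),
                                            PIPELINE_CONFIG_KEYS)])
  if (!is.numeric(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    errors <- c(errors, "seed must be an integer")
  }
  for (k in c("n_lesions", "n_controls")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] < 1) {
      errors <- c(errors, paste0(k, " must be a positive integer"))
    }
  }
  if (!is.numeric(cfg$trim) || cfg$trim < 0 || cfg$trim >= 0.5) {
    errors <- c(errors, "trim must be in [0, 0.5)")
  }
  if (!is.numeric(cfg$bilateral_fraction) || cfg$bilateral_fraction < 0 ||
      cfg$bilateral_fraction >= 0.5) {
    errors <- c(errors, "bilateral_fraction must be in [0, 0.5)")
  }
  if (!cfg$segmenter %in% c("mock", "external")) {
    errors <- c(errors, "segmenter must be 'mock' or 'external'")
  }
  if (!cfg$segmenter_mode %in% c("local", "global-normalized")) {
    errors <- c(errors,
                "segmenter_mode must be 'local' or 'global-normalized'")
  }
  bad_h <- setdiff(cfg$hypotheses, c("a", "b", "c"))
  if (length(bad_h) > 0) {
    errors <- c(errors, paste0("unknown hypothesis family: ",
                               paste(bad_h, collapse = ", ")))
  }
  for (k in c("lesions_dir", "controls_dir")) {
    if (!is.null(cfg[[k]]) && !dir.exists(cfg[[k]])) {
      errors <- c(errors, paste0(k, " does not exist: ", cfg[[k]]))
    }
  }
  if (identical(cfg$segmenter, "external") &&
      is.null(cfg$segmenter_command)) {
    errors <- c(errors, "segmenter = 'external' requires segmenter_command")
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

read_lesion_inputs <- function(lesions_dir) {
  masks <- list.files(lesions_dir, pattern = "_mask\\.nii(\\.gz)?$",
                      full.names = TRUE)
  if (length(masks) == 0) {
    stop("no '*_mask.nii[.gz]' files in ", lesions_dir, call. = FALSE)
  }
  lapply(masks, function(mp) {
    id <- sub("_mask\\.nii(\\.gz)?$", "", basename(mp))
    tp <- sub("_mask\\.", "_t1.", mp)
    if (!file.exists(tp)) {
      stop("missing T1 image for lesion '", id, "': ", tp, call. = FALSE)
    }
    extract_patch(read_nifti(tp, id = id), read_nifti_mask(mp, id = id),
                  lesion_id = id)
  })
}

#' Run the full simulated-lesion pipeline
#'
#' Executes the study replica end to end from one configuration:
#'
#' 1. **simulate** — obtain lesion patches and control images (from
#'    `lesions_dir`/`controls_dir` if configured, otherwise generated
#'    synthetically via [generate_cohort()]) and build the fully crossed
#'    chimeric dataset.
#' 2. **characterize** — per-case and per-lesion characteristics
#'    (volume, laterality, unit-invariant intensity statistics on the
#'    chimeric images).
#' 3. **segment** — hemispheric cortex/cWM volumes for every chimeric
#'    case and every control (ground truth), with the configured
#'    segmenter and mode.
#' 4. **tabulate** — long measurement table, PVD table, PVD summary.
#' 5. **fit** — the configured hypothesis families for both measures.
#'
#' Stage outputs are written under `out_dir` (CSV tables; NIfTI images if
#' `write_images`), and a machine-readable JSON run record (config echo,
#' per-stage row counts, model estimates, LRTs, warnings) is both returned
#' and written. A stage whose output CSV already exists is re-read rather
#' than recomputed unless `force = TRUE`; the record contains no
#' timestamps, so identical configs and seeds reproduce identical records.
#'
#' @param config A [validate_config()] result, path, or list.
#' @param force Recompute stages whose outputs already exist.
#' @param quiet Suppress progress messages.
#' @return The run record (list, class `lesionbench_run`), invisibly
#'   containing the stage tables in `$tables`.
#' @export
run_pipeline <- function(config, force = FALSE, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()

  if (cfg$segmenter == "external") cfg$write_images <- TRUE

  synth <- is.null(cfg$lesions_dir) && is.null(cfg$controls_dir)
  if (!synth && cfg$segmenter == "mock") {
    stop("the mock segmenter needs synthetic phantoms for its reference ",
         "intensities; use segmenter = 'external' with image directories",
         call. = FALSE)
  }

  # -- stage 1: simulate ------------------------------------------------
  say("[simulate] building crossed dataset")
  base_spec <- phantom_spec(grid_shape = cfg$grid_shape,
                            voxel_dims = cfg$voxel_dims,
                            class_noise_sd = cfg$class_noise_sd,
                            seed = cfg$seed)
  if (synth) {
    cohort <- generate_cohort(cfg$n_lesions, cfg$n_controls,
                              base_spec = base_spec, seed = cfg$seed)
    patches <- cohort$patches
    control_phantoms <- cohort$controls
    control_imgs <- lapply(control_phantoms, function(p) p$image)
  } else {
    patches <- read_lesion_inputs(cfg$lesions_dir)
    t1s <- list.files(cfg$controls_dir, pattern = "\\.nii(\\.gz)?$",
                      full.names = TRUE)
    control_imgs <- lapply(t1s, read_nifti)
    control_phantoms <- NULL
  }
  crossed <- build_crossed_dataset(patches, control_imgs,
                                   transform = cfg$transform,
                                   strict = cfg$strict,
                                   bilateral_fraction = cfg$bilateral_fraction)
  manifest <- crossed$manifest
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  n_failed <- sum(manifest$status != "ok")
  if (n_failed > 0) {
    warnings_log <- c(warnings_log,
                      sprintf("%d transplant(s) failed; see manifest", n_failed))
  }
  if (cfg$write_images) {
    img_dir <- file.path(cfg$out_dir, "cases")
    dir.create(img_dir, showWarnings = FALSE)
    for (cs in crossed$cases) {
      chim_path <- file.path(img_dir, paste0(cs$case_id, ".nii.gz"))
      if (force || !file.exists(chim_path)) {
        write_nifti(cs$chimeric, chim_path)
        write_nifti(cs$transformed_mask,
                    file.path(img_dir, paste0(cs$case_id, "_mask.nii.gz")))
      }
    }
  }

  # -- stage 2: characterize -------------------------------------------
  say("[characterize] lesion characteristics")
  case_chars <- purrr::map(crossed$cases, function(cs) {
    dplyr::mutate(
      characterize_lesion(cs$chimeric, cs$transformed_mask,
                          lesion_id = cs$lesion_id,
                          bilateral_fraction = cfg$bilateral_fraction),
      case_id = cs$case_id, control_id = cs$control_id
    )
  }) |> dplyr::bind_rows()
  lesion_chars <- case_chars |>
    dplyr::group_by(.data$lesion_id) |>
    dplyr::summarise(volume_mm3 = mean(.data$volume_native_mm3),
                     mean_intensity_ui = mean(.data$mean_intensity_ui),
                     sd_intensity_ui = mean(.data$sd_intensity_ui),
                     .groups = "drop")
  utils::write.csv(case_chars,
                   file.path(cfg$out_dir, "case_characteristics.csv"),
                   row.names = FALSE)
  utils::write.csv(lesion_chars,
                   file.path(cfg$out_dir, "lesion_characteristics.csv"),
                   row.names = FALSE)

  # -- stage 3: segment -------------------------------------------------
  say("[segment] ", cfg$segmenter, " (", cfg$segmenter_mode, ")")
  seg_path <- file.path(cfg$out_dir, "segmentation.csv")
  if (!force && file.exists(seg_path)) {
    seg_all <- tibble::as_tibble(utils::read.csv(seg_path,
                                                 stringsAsFactors = FALSE))
  } else if (cfg$segmenter == "mock") {
    refs <- stats::setNames(lapply(control_phantoms, segment_reference),
                            vapply(control_imgs, function(x) x$id,
                                   character(1)))
    gt_results <- purrr::map(control_imgs, function(ci) {
      mock_segment(ci, refs[[ci$id]], mode = cfg$segmenter_mode)
    }) |> dplyr::bind_rows()
    sim_results <- purrr::map(crossed$cases, function(cs) {
      mock_segment(cs$chimeric, refs[[cs$control_id]],
                   mode = cfg$segmenter_mode, subject_id = cs$case_id)
    }) |> dplyr::bind_rows()
    seg_all <- dplyr::bind_rows(
      dplyr::mutate(sim_results, role = "simulated"),
      dplyr::mutate(gt_results, role = "ground_truth")
    )
    utils::write.csv(seg_all, seg_path, row.names = FALSE)
  } else {
    img_dir <- file.path(cfg$out_dir, "cases")
    subjects <- c(
      stats::setNames(
        file.path(img_dir, paste0(names(crossed$cases), ".nii.gz")),
        names(crossed$cases)
      )
    )
    sim_results <- purrr::imap(subjects, function(t1, sid) {
      run_external_segmenter(sid, t1, file.path(cfg$out_dir, "seg", sid),
                             cfg$segmenter_command)
    }) |> dplyr::bind_rows()
    gt_results <- purrr::map(control_imgs, function(ci) {
      t1 <- file.path(cfg$out_dir, "controls", paste0(ci$id, ".nii.gz"))
      if (!file.exists(t1)) {
        dir.create(dirname(t1), recursive = TRUE, showWarnings = FALSE)
        write_nifti(ci, t1)
      }
      run_external_segmenter(ci$id, t1,
                             file.path(cfg$out_dir, "seg", ci$id),
                             cfg$segmenter_command)
    }) |> dplyr::bind_rows()
    seg_all <- dplyr::bind_rows(
      dplyr::mutate(sim_results, role = "simulated"),
      dplyr::mutate(gt_results, role = "ground_truth")
    )
    utils::write.csv(seg_all, seg_path, row.names = FALSE)
  }

  # -- stage 4: tabulate ------------------------------------------------
  say("[tabulate] long table and PVD")
  long_tab <- build_long_table(
    dplyr::filter(seg_all, .data$role == "simulated"),
    dplyr::filter(seg_all, .data$role == "ground_truth"),
    manifest
  )
  pvds <- pvd_table(long_tab)
  pvd_sum <- pvd_summary(pvds, trim = cfg$trim)
  utils::write.csv(long_tab, file.path(cfg$out_dir, "long_table.csv"),
                   row.names = FALSE)
  utils::write.csv(pvds, file.path(cfg$out_dir, "pvd.csv"),
                   row.names = FALSE)
  utils::write.csv(pvd_sum, file.path(cfg$out_dir, "pvd_summary.csv"),
                   row.names = FALSE)

  # -- stage 5: fit -----------------------------------------------------
  fits <- list()
  for (h in cfg$hypotheses) {
    for (m in c("cortex", "cwm")) {
      say("[fit] hypothesis ", h, ", ", m)
      key <- paste0(h, "_", m)
      fits[[key]] <- switch(
        h,
        a = hypothesis_a(long_tab, measure = m),
        b = hypothesis_b(pvds, measure = m),
        c = hypothesis_c(pvds, lesion_chars, measure = m,
                         hemisphere = "lesioned")
      )
    }
  }
  if (length(fits) > 0) {
    model_tab <- dplyr::bind_rows(lapply(fits, tidy))
    model_glance <- dplyr::bind_rows(lapply(fits, glance))
    utils::write.csv(model_tab, file.path(cfg$out_dir, "model_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(model_glance, file.path(cfg$out_dir, "model_fits.csv"),
                     row.names = FALSE)
  } else {
    model_tab <- tibble::tibble()
    model_glance <- tibble::tibble()
  }

  record <- list(
    package_version = as.character(utils::packageVersion("lesionbench")),
    config = unclass(cfg),
    stages = list(
      simulate = list(n_cases = sum(manifest$status == "ok"),
                      n_failed = n_failed),
      characterize = list(n_lesions = nrow(lesion_chars)),
      segment = list(n_results = nrow(seg_all)),
      tabulate = list(n_long_rows = nrow(long_tab),
                      n_pvd_rows = nrow(pvds))
    ),
    pvd_summary = pvd_sum,
    model_estimates = model_tab,
    model_fits = model_glance,
    warnings = warnings_log
  )
  jsonlite::write_json(record, file.path(cfg$out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  record$tables <- list(manifest = manifest, long_table = long_tab,
                        pvd = pvds, lesion_characteristics = lesion_chars)
  record$fits <- fits
  class(record) <- "lesionbench_run"
  invisible(record)
}

#' @export
print.lesionbench_run <- function(x, ...) {
  cat(sprintf("<lesionbench_run> %d cases, %d long-table rows, %d model fits\n",
              x$stages$simulate$n_cases, x$stages$tabulate$n_long_rows,
              nrow(x$model_fits)))
  invisible(x)
}
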