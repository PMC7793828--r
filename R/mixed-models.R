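#' Specify a linear mixed model
#'
#' A declarative model description consumed by [fit_lmm()]: fixed-effect
#' terms, crossed random intercepts, and optional random slopes (with or
#' without a slope–intercept correlation). Groupings are crossed, not
#' nested: every grouping column is treated as an independent partition of
#' the rows.
#'
#' @param outcome Outcome column name.
#' @param fixed Character vector of fixed-effect column names (an
#'   intercept is always included).
#' @param random_intercepts Character vector of grouping columns that get
#'   a random intercept.
#' @param random_slopes Named character vector `c(grouping = term)` of
#'   random slopes; the grouping also receives an intercept.
#' @param correlated Should slope and intercept be correlated within a
#'   grouping (default `TRUE`)? On non-convergence [fit_lmm()] drops the
#'   correlation automatically.
#' @param estimation `"REML"` (for reported estimates) or `"ML"` (for
#'   likelihood-ratio model comparison).
#' @return An `lmm_spec` list.
#' @export
lmm_spec <- function(outcome, fixed = character(),
                     random_intercepts = character(),
                     random_slopes = character(), correlated = TRUE,
                     estimation = c("REML", "ML")) {
  estimation <- match.arg(estimation)
  structure(
    list(outcome = outcome, fixed = fixed,
         random_intercepts = random_intercepts,
         random_slopes = random_slopes, correlated = correlated,
         estimation = estimation),
    class = "lmm_spec"
  )
}

lmm_formula <- function(spec, correlated = spec$correlated) {
  rhs <- c("1", spec$fixed)
  slope_groups <- names(spec$random_slopes)
  for (g in setdiff(spec$random_intercepts, slope_groups)) {
    rhs <- c(rhs, sprintf("(1 | %s)", g))
  }
  for (g in slope_groups) {
    term <- spec$random_slopes[[g]]
    rhs <- c(rhs, if (correlated) {
      sprintf("(1 + %s | %s)", term, g)
    } else {
      sprintf("(1 | %s) + (0 + %s | %s)", g, term, g)
    })
  }
  stats::as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

check_spec_columns <- function(data, spec) {
  groups <- union(spec$random_intercepts, names(spec$random_slopes))
  needed <- unique(c(spec$outcome, spec$fixed, unname(spec$random_slopes),
                     groups))
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("columns not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (g in groups) {
    if (length(unique(data[[g]])) < 2L) {
      stop(sprintf("grouping '%s' has fewer than 2 levels", g), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Z-score columns of a data frame
#'
#' Replaces each named column by `(x - mean(x)) / sd(x)` (sample SD),
#' computed over the rows present — i.e. over exactly the observations
#' entering a model when called on the modeled subset. Standardizing
#' covariates of very different scales onto z-units is what lets the
#' mixed-model optimizer converge and makes slopes comparable.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric column names.
#' @return `data` with the named columns standardized.
#' @export
zscore_columns <- function(data, columns) {
  for (cl in columns) {
    x <- data[[cl]]
    if (is.null(x)) stop("column not found: ", cl, call. = FALSE)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("column '%s' has zero variance; cannot z-score", cl),
           call. = FALSE)
    }
    data[[cl]] <- (x - mean(x)) / s
  }
  data
}

# Number of model parameters: fixed effects + random var-cov components +
# residual variance. The residual is common to nested comparisons and
# cancels in LRT df.
n_params_lmer <- function(fit) {
  length(lme4::fixef(fit)) + length(lme4::getME(fit, "theta")) + 1L
}

#' Fit a linear mixed model (or fixed-effects-only linear model)
#'
#' Fits the model described by an [lmm_spec()] with `lme4::lmer` (REML or
#' ML). A spec with no random terms is fitted with `stats::lm`, giving the
#' fixed-effects-only baseline for likelihood-ratio comparisons. Fixed
#' effects are reported with normal-approximation p-values,
#' `p = 2 * pnorm(-|t|)` — no degrees-of-freedom correction.
#'
#' If a model with a correlated random slope fails to converge, it is
#' automatically refitted with the slope–intercept correlation removed and
#' the fallback is flagged in the result. Boundary estimates (zero
#' variances) are reported, not treated as failures.
#'
#' @param data A data frame containing every column the spec names.
#' @param spec An [lmm_spec()].
#' @return An `lmm_fit`: `coefficients` (tibble: term, B, SE, t, p),
#'   `varcomp` (tibble of random-effect SDs/correlations and the residual
#'   SD), `log_likelihood`, `n_parameters`, `n_obs`, `converged`,
#'   `fallback_uncorrelated`, `estimation`, `formula`, and the underlying
#'   `fit` object.
#' @export
fit_lmm <- function(data, spec) {
  check_spec_columns(data, spec)
  has_random <- length(spec$random_intercepts) > 0 ||
    length(spec$random_slopes) > 0

  if (!has_random) {
    f <- stats::as.formula(paste(spec$outcome, "~",
                                 paste(c("1", spec$fixed), collapse = " + ")))
    fit <- stats::lm(f, data = data)
    smry <- summary(fit)$coefficients
    coefs <- tibble::tibble(
      term = rownames(smry), B = unname(smry[, 1]), SE = unname(smry[, 2]),
      t = unname(smry[, 1] / smry[, 2])
    )
    coefs$p <- 2 * stats::pnorm(-abs(coefs$t))
    return(structure(
      list(coefficients = coefs,
           varcomp = tibble::tibble(grouping = "residual", term = "sd",
                                    value = summary(fit)$sigma),
           log_likelihood = as.numeric(stats::logLik(fit)),
           n_parameters = length(stats::coef(fit)) + 1L,
           n_obs = stats::nobs(fit), converged = TRUE,
           fallback_uncorrelated = FALSE, estimation = "ML",
           formula = gsub("\\s+", " ", paste(deparse(f), collapse = " ")), fit = fit),
      class = "lmm_fit"
    ))
  }

  fit_once <- function(correlated) {
    f <- lmm_formula(spec, correlated)
    msgs <- character()
    fit <- withCallingHandlers(
      lme4::lmer(f, data = data, REML = spec$estimation == "REML"),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        # lme4 reports boundary (singular) fits via message(); boundary
        # variance estimates are reported, not treated as failures
        invokeRestart("muffleMessage")
      }
    )
    conv_fail <- any(grepl("failed to converge|convergence", msgs,
                           ignore.case = TRUE)) ||
      !is.null(fit@optinfo$conv$lme4$code)
    list(fit = fit, formula = f, converged = !conv_fail)
  }

  has_corr_slope <- spec$correlated && length(spec$random_slopes) > 0
  res <- fit_once(spec$correlated)
  fallback <- FALSE
  if (!res$converged && has_corr_slope) {
    res2 <- fit_once(FALSE)
    if (res2$converged) {
      res <- res2
      fallback <- TRUE
    }
  }
  fit <- res$fit

  smry <- stats::coef(summary(fit))
  coefs <- tibble::tibble(
    term = rownames(smry), B = unname(smry[, "Estimate"]),
    SE = unname(smry[, "Std. Error"]),
    t = unname(smry[, "Estimate"] / smry[, "Std. Error"])
  )
  coefs$p <- 2 * stats::pnorm(-abs(coefs$t))

  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- tibble::tibble(
    grouping = ifelse(vc$grp == "Residual", "residual", vc$grp),
    term = ifelse(is.na(vc$var2), ifelse(is.na(vc$var1), "sd", vc$var1),
                  paste(vc$var1, vc$var2, sep = ":")),
    value = ifelse(is.na(vc$var2), vc$sdcor, vc$sdcor) # SD or correlation
  )

  structure(
    list(coefficients = coefs, varcomp = varcomp,
         log_likelihood = as.numeric(stats::logLik(fit)),
         n_parameters = n_params_lmer(fit),
         n_obs = stats::nobs(fit), converged = res$converged,
         fallback_uncorrelated = fallback, estimation = spec$estimation,
         formula = gsub("\\s+", " ", paste(deparse(res$formula), collapse = " ")), fit = fit),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("<lmm_fit> %s [%s, logLik %.2f, %d params, n = %d%s]\n",
              x$formula, x$estimation, x$log_likelihood, x$n_parameters,
              x$n_obs,
              if (x$fallback_uncorrelated) ", uncorrelated fallback" else ""))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' Likelihood-ratio test between nested model fits
#'
#' `chi^2 = 2 * (logLik_full - logLik_reduced)` on `df` = difference in
#' parameter counts, used to ask whether the random effects are warranted:
#' the full mixed model against the fixed-effects-only baseline. Both fits
#' must use ML — REML likelihoods of models differing in fixed or random
#' structure are not comparable.
#'
#' @param full,reduced `lmm_fit` objects fitted by ML on the same rows,
#'   with `reduced` nested in `full`.
#' @return An `lrt_result` tibble: `chi_square`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$estimation != "ML" || reduced$estimation != "ML") {
    stop("likelihood-ratio tests require ML fits, not REML", call. = FALSE)
  }
  if (full$n_obs != reduced$n_obs) {
    stop("fits use different numbers of observations; not comparable",
         call. = FALSE)
  }
  df <- full$n_parameters - reduced$n_parameters
  if (df < 1L) stop("full model must have more parameters than reduced",
                    call. = FALSE)
  chi <- 2 * (full$log_likelihood - reduced$log_likelihood)
  if (chi < -1e-8) {
    stop("full-model log-likelihood below reduced model's: models not nested?",
         call. = FALSE)
  }
  chi <- max(chi, 0)
  structure(
    tibble::tibble(chi_square = chi, df = df,
                   p = stats::pchisq(chi, df, lower.tail = FALSE)),
    class = c("lrt_result", "tbl_df", "tbl", "data.frame")
  )
}

# Restrict to one measure if the table distinguishes measures at all
# (simulated single-measure tables need no filtering).
filter_measure <- function(dat, measure) {
  if ("measure" %in% names(dat)) {
    dat <- dplyr::filter(dat, .data$measure == !!measure)
    if (nrow(dat) == 0L) stop("no rows for measure '", measure, "'",
                              call. = FALSE)
  }
  dat
}

# Fit the (REML report, ML full, ML fixed-only reduced, LRT) bundle shared
# by all hypothesis families.
fit_hypothesis_bundle <- function(data, spec_reml, hypothesis, measure,
                                  hemisphere) {
  spec_ml <- spec_reml
  spec_ml$estimation <- "ML"
  spec_red <- lmm_spec(spec_reml$outcome, spec_reml$fixed, estimation = "ML")
  reml <- fit_lmm(data, spec_reml)
  ml <- fit_lmm(data, spec_ml)
  reduced <- fit_lmm(data, spec_red)
  structure(
    list(hypothesis = hypothesis, measure = measure, hemisphere = hemisphere,
         reml = reml, ml = ml, reduced = reduced,
         lrt = likelihood_ratio_test(ml, reduced), data = data),
    class = "lmm_hypothesis"
  )
}

#' @export
print.lmm_hypothesis <- function(x, ...) {
  cat(sprintf("<lmm_hypothesis %s> measure = %s, hemisphere = %s\n",
              x$hypothesis, x$measure, x$hemisphere))
  print(x$reml)
  cat(sprintf("LRT vs fixed-only: chi^2(%d) = %.2f, p = %.3g\n",
              x$lrt$df, x$lrt$chi_square, x$lrt$p))
  invisible(x)
}

#' Hypothesis (a): does simulating a lesion change measured volume?
#'
#' Models hemispheric volume as a function of case (simulated-lesion vs
#' ground-truth) with crossed random effects for the lesion and control
#' images used to construct each simulated case. Across both hemispheres
#' the maximal model has a random case slope (and intercept) per pair —
#' case is a within-pair effect — plus random intercepts for lesion and
#' control. Within a single hemisphere there is only one observation per
#' pair and case, so the pair grouping keeps only a random intercept.
#'
#' @param long_table Output of [build_long_table()].
#' @param measure `"cortex"` or `"cwm"`.
#' @param hemisphere `"both"` (default), `"lesioned"`, or
#'   `"contralesional"`.
#' @return An `lmm_hypothesis` bundle: REML fit for reporting, ML fit and
#'   fixed-effects-only baseline with their likelihood-ratio test.
#' @export
hypothesis_a <- function(long_table, measure = c("cortex", "cwm"),
                         hemisphere = c("both", "lesioned",
                                        "contralesional")) {
  measure <- match.arg(measure)
  hemisphere <- match.arg(hemisphere)
  dat <- filter_measure(long_table, measure)
  if (hemisphere != "both") {
    dat <- dplyr::filter(dat, .data$hemi_role == hemisphere)
  }
  dat <- dplyr::mutate(dat,
                       case_sim = as.numeric(.data$case == "simulated"))
  spec <- if (hemisphere == "both") {
    lmm_spec("volume_mm3", fixed = "case_sim",
             random_intercepts = c("lesion_id", "control_id"),
             random_slopes = c(pair_id = "case_sim"), correlated = TRUE)
  } else {
    lmm_spec("volume_mm3", fixed = "case_sim",
             random_intercepts = c("pair_id", "lesion_id", "control_id"))
  }
  fit_hypothesis_bundle(dat, spec, "a", measure, hemisphere)
}

#' Hypothesis (b): is the error larger in the lesioned hemisphere?
#'
#' Models PVD as a function of hemisphere role (lesioned vs
#' contralesional) with random intercepts for pair, lesion and control.
#' There is only one observation per pair and hemisphere, so no random
#' slope is identifiable and the maximal model is intercepts-only.
#'
#' @param pvds Output of [pvd_table()].
#' @param measure `"cortex"` or `"cwm"`.
#' @return An `lmm_hypothesis` bundle (see [hypothesis_a()]).
#' @export
hypothesis_b <- function(pvds, measure = c("cortex", "cwm")) {
  measure <- match.arg(measure)
  dat <- pvds |>
    filter_measure(measure) |>
    dplyr::mutate(hemi_lesioned = as.numeric(.data$hemi_role == "lesioned"))
  spec <- lmm_spec("pvd", fixed = "hemi_lesioned",
                   random_intercepts = c("pair_id", "lesion_id",
                                         "control_id"))
  fit_hypothesis_bundle(dat, spec, "b", measure, "both")
}

#' Hypothesis (c): which lesion characteristics drive the error?
#'
#' Models PVD within one hemisphere role as a function of three
#' standardized lesion covariates — volume, mean intensity and intensity
#' SD (the latter two in unit-invariant space) — with a random intercept
#' for the control image only. The lesion grouping is deliberately absent:
#' its variance is what the covariates are meant to explain. Covariates
#' are z-scored over the modeled rows.
#'
#' @param pvds Output of [pvd_table()].
#' @param characteristics Tibble with one row per lesion: `lesion_id`,
#'   `volume_mm3`, `mean_intensity_ui`, `sd_intensity_ui` (e.g. from
#'   [characterize_lesion()], renaming the volume column).
#' @param measure `"cortex"` or `"cwm"`.
#' @param hemisphere `"lesioned"` or `"contralesional"`.
#' @return An `lmm_hypothesis` bundle (see [hypothesis_a()]).
#' @export
hypothesis_c <- function(pvds, characteristics,
                         measure = c("cortex", "cwm"),
                         hemisphere = c("lesioned", "contralesional")) {
  measure <- match.arg(measure)
  hemisphere <- match.arg(hemisphere)
  needed <- c("lesion_id", "volume_mm3", "mean_intensity_ui",
              "sd_intensity_ui")
  missing <- setdiff(needed, names(characteristics))
  if (length(missing) > 0) {
    stop("characteristics table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dat <- filter_measure(pvds, measure)
  if ("hemi_role" %in% names(dat)) {
    dat <- dplyr::filter(dat, .data$hemi_role == hemisphere)
  }
  dat <- dplyr::left_join(dat, characteristics[, needed], by = "lesion_id")
  if (anyNA(dat$volume_mm3)) {
    stop("characteristics missing for lesion(s): ",
         paste(unique(dat$lesion_id[is.na(dat$volume_mm3)]), collapse = ", "),
         call. = FALSE)
  }
  dat <- zscore_columns(dat, c("volume_mm3", "mean_intensity_ui",
                               "sd_intensity_ui"))
  names(dat)[match(c("volume_mm3", "mean_intensity_ui", "sd_intensity_ui"),
                   names(dat))] <-
    c("volume_z", "mean_intensity_z", "sd_intensity_z")
  spec <- lmm_spec("pvd",
                   fixed = c("volume_z", "mean_intensity_z",
                             "sd_intensity_z"),
                   random_intercepts = "control_id")
  fit_hypothesis_bundle(dat, spec, "c", measure, hemisphere)
}
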