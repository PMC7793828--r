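#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixed-model fit
#'
#' @param x An `lmm_fit` from [fit_lmm()].
#' @param effects `"fixed"` (default) for coefficients or `"ran_pars"` for
#'   variance components.
#' @param ... Unused.
#' @return A tibble in broom column conventions: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (fixed effects), or `group`,
#'   `term`, `estimate` (variance components, on the SD/correlation scale).
#' @export
tidy.lmm_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    tibble::tibble(term = x$coefficients$term,
                   estimate = x$coefficients$B,
                   std.error = x$coefficients$SE,
                   statistic = x$coefficients$t,
                   p.value = x$coefficients$p)
  } else {
    tibble::tibble(group = x$varcomp$grouping, term = x$varcomp$term,
                   estimate = x$varcomp$value)
  }
}

#' @rdname tidy.lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, n_parameters = x$n_parameters,
                 nobs = x$n_obs, converged = x$converged,
                 estimation = x$estimation,
                 fallback_uncorrelated = x$fallback_uncorrelated)
}

#' Tidy a hypothesis bundle
#'
#' Fixed effects of the reporting (REML) fit, annotated with the
#' hypothesis family, measure, and hemisphere subset.
#'
#' @param x An `lmm_hypothesis` from [hypothesis_a()], [hypothesis_b()] or
#'   [hypothesis_c()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lmm_hypothesis <- function(x, ...) {
  dplyr::mutate(tidy(x$reml), hypothesis = x$hypothesis,
                measure = x$measure, hemisphere = x$hemisphere,
                .before = 1)
}

#' @rdname tidy.lmm_hypothesis
#' @export
glance.lmm_hypothesis <- function(x, ...) {
  tibble::tibble(hypothesis = x$hypothesis, measure = x$measure,
                 hemisphere = x$hemisphere,
                 logLik_ml = x$ml$log_likelihood,
                 lrt_chi_square = x$lrt$chi_square, lrt_df = x$lrt$df,
                 lrt_p = x$lrt$p, converged = x$reml$converged,
                 fallback_uncorrelated = x$reml$fallback_uncorrelated)
}
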