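#' Plot the PVD distribution by hemisphere role
#'
#' Boxplots of percent volume difference split by hemisphere role and
#' faceted by measure — the visual counterpart of [pvd_summary()].
#'
#' @param pvds Output of [pvd_table()].
#' @return A ggplot object.
#' @export
plot_pvd <- function(pvds) {
  ggplot2::ggplot(pvds,
                  ggplot2::aes(x = .data$hemi_role, y = .data$pvd,
                               fill = .data$hemi_role)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "percent volume difference (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a hypothesis bundle
#'
#' Fixed-effect estimates of the reporting fit with normal-approximation
#' 95% intervals (B +/- 1.96 SE).
#'
#' @param object An `lmm_hypothesis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lmm_hypothesis <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error)
    ) +
    ggplot2::labs(
      title = sprintf("Hypothesis (%s), %s, %s hemisphere(s)",
                      object$hypothesis, object$measure, object$hemisphere),
      x = "estimate (95% normal CI)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume
#'
#' Quick-look raster of one k-slice of an [image_volume()], optionally
#' with a mask outline overlaid.
#'
#' @param vol An [image_volume()].
#' @param k Slice index (1-based along the third axis); defaults to the
#'   middle slice.
#' @param mask Optional [binary_mask()] on the same grid.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, k = NULL, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  df <- tidyr::expand_grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$intensity <- as.vector(vol$data[, , k])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s [slice k = %d]", vol$id, k),
                  x = NULL, y = NULL) +
    ggplot2::theme_void() +
    ggplot2::theme(plot.title = ggplot2::element_text(size = 10))
  if (!is.null(mask)) {
    check_same_grid(vol, mask)
    mdf <- df
    mdf$m <- as.vector(mask$data[, , k])
    mdf <- mdf[mdf$m != 0, , drop = FALSE]
    if (nrow(mdf) > 0) {
      p <- p + ggplot2::geom_tile(data = mdf, fill = "red", alpha = 0.4)
    }
  }
  p
}
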