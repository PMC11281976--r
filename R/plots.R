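#' Morphospace scatter plot with loading arrows
#'
#' PC-vs-PC scatter of specimens, coloured by group, with variable loadings
#' drawn as arrows from the origin (scaled to the plot). Purely
#' presentational; no numerical output depends on plotting.
#'
#' @param x A `pca_model`.
#' @param groups Optional factor/character vector of group labels, one per
#'   specimen.
#' @param axes Which two components to draw (default PC1-PC2).
#' @param arrow_scale Multiplier applied to the loading arrows.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pca_model <- function(x, groups = NULL, axes = c(1, 2),
                           arrow_scale = NULL, ...) {
  s <- x$scores[, axes, drop = FALSE]
  lab <- sprintf("PC%d (%.2f%%)", axes, x$pct_variance[axes])
  col <- 1
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    col <- as.integer(groups) + 1L
  }
  graphics::plot(s, xlab = lab[1], ylab = lab[2], col = col, pch = 19, ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  L <- x$loadings[, axes, drop = FALSE]
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * max(abs(s)) / max(abs(L))
  }
  graphics::arrows(0, 0, L[, 1] * arrow_scale, L[, 2] * arrow_scale,
                   length = 0.08, col = "grey40")
  graphics::text(L[, 1] * arrow_scale * 1.08, L[, 2] * arrow_scale * 1.08,
                 rownames(L), cex = 0.7, col = "grey30")
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(groups),
                     col = seq_along(levels(groups)) + 1L, pch = 19,
                     cex = 0.8, bty = "n")
  }
  invisible(x)
}

#' Allometry regression plot
#'
#' PC1 scores against log geometric mean with the fitted line and a 95%
#' confidence band for the mean response.
#'
#' @param x An `allometry_fit`.
#' @param scores_pc1,size The data the fit was computed from (scores and a
#'   [size_vector()] or log-GM vector).
#' @param groups Optional group labels for colouring.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.allometry_fit <- function(x, scores_pc1, size, groups = NULL, ...) {
  log_gm <- if (is.data.frame(size)) size$log_gm else as.numeric(size)
  col <- 1
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    col <- as.integer(groups) + 1L
  }
  graphics::plot(log_gm, scores_pc1, xlab = "log(GM)", ylab = "PC1 score",
                 col = col, pch = 19, ...)
  xs <- seq(min(log_gm), max(log_gm), length.out = 100)
  fit <- stats::lm(scores_pc1 ~ log_gm)
  pred <- stats::predict(fit, data.frame(log_gm = xs), interval = "confidence")
  graphics::polygon(c(xs, rev(xs)), c(pred[, "lwr"], rev(pred[, "upr"])),
                    col = grDevices::adjustcolor("grey50", alpha.f = 0.3),
                    border = NA)
  graphics::abline(fit, lwd = 2)
  graphics::mtext(sprintf("R² = %s, p = %.3g", format_pct(x$r_squared),
                          x$p_value), side = 3, cex = 0.8)
  invisible(x)
}
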