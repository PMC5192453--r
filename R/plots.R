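#' Score plot (T_pred vs T_orth)
#'
#' Predictive scores horizontal, first orthogonal (OPLS) or second predictive
#' (PLS/PCA) scores vertical; one point per sample, colored by group.
#' @param model a `latent_model`.
#' @param labels group labels, one per sample.
#' @param main plot title.
#' @return invisibly, the plotted coordinates.
#' @export
plot_scores <- function(model, labels = NULL, main = NULL) {
  t1 <- model$T_pred[, 1L]
  t2 <- if (!is.null(model$T_orth) && ncol(model$T_orth) >= 1L) model$T_orth[, 1L]
        else if (ncol(model$T_pred) >= 2L) model$T_pred[, 2L]
        else rep(0, length(t1))
  ylab <- if (!is.null(model$T_orth) && ncol(model$T_orth) >= 1L) "T_orth" else "t2"
  col <- if (is.null(labels)) "black" else as.integer(factor(labels)) + 1L
  graphics::plot(t1, t2, col = col, pch = 19, xlab = "T_pred", ylab = ylab,
                 main = main %||% sprintf("%s score plot", toupper(model$kind)))
  graphics::abline(h = 0, v = 0, col = "gray70", lty = 2)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19, cex = 0.8)
  invisible(cbind(t1, t2))
}

#' Loading plot (covariance heights colored by correlation)
#'
#' Bar heights are the bucket/response covariances; colors encode the Pearson
#' R from blue (-1) through gray (0) to red (+1).
#' @param profile a `loading_profile`.
#' @param main plot title.
#' @export
plot_loadings <- function(profile, main = "Loading plot") {
  stopifnot(inherits(profile, "loading_profile"))
  ramp <- grDevices::colorRamp(c("blue", "gray85", "red"))
  rgbv <- ramp((pmax(pmin(profile$r, 1), -1) + 1) / 2)
  cols <- grDevices::rgb(rgbv[, 1], rgbv[, 2], rgbv[, 3], maxColorValue = 255)
  graphics::plot(profile$center, profile$covariance, type = "h", col = cols,
                 xlab = "ppm", ylab = "cov(bucket, y)", main = main,
                 xlim = rev(range(profile$center)))  # NMR convention: ppm decreasing
  invisible(NULL)
}
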