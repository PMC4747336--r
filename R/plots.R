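# Optional figures (require ggplot2, in Suggests).

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the ggplot2 package", call. = FALSE)
}

#' Empirical CDF of per-subject prior weights
#'
#' Reproduces the cohort summary figure: each subject is one increment;
#' matched and mismatched-prior estimates are overlaid when both given.
#'
#' @param deltas_matched Per-subject deltas under matched priors.
#' @param deltas_mismatched Optional deltas under mismatched priors.
#' @return A ggplot object.
#' @export
plot_delta_ecdf <- function(deltas_matched, deltas_mismatched = NULL) {
  .need_ggplot()
  df <- data.frame(delta = deltas_matched, priors = "matched")
  if (!is.null(deltas_mismatched))
    df <- rbind(df, data.frame(delta = deltas_mismatched, priors = "mismatched"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta, colour = .data$priors)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = expression(delta~"(prior weight)"),
                  y = "cumulative proportion of subjects") +
    ggplot2::theme_minimal()
}

#' Fitted likelihood ellipses over the frame
#'
#' Draws each direction's 1-sd ellipse (in frame-pixel coordinates) for a
#' fitted subject model, the standard visual check of the likelihood fits.
#'
#' @param model A `subject_model`.
#' @param grid The [working_grid()].
#' @param n_points Points per ellipse outline.
#' @return A ggplot object.
#' @export
plot_likelihood_ellipses <- function(model, grid, n_points = 60) {
  .need_ggplot()
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(cos(theta), sin(theta))
  paths <- lapply(model$ellipses, function(e) {
    pts <- t(e$mu + t(chol(e$sigma)) %*% circ)   # 1-sd contour in cm
    px <- cm_to_px(pts, grid)
    data.frame(direction = e$direction, x = px[, 1], y = px[, 2])
  })
  df <- do.call(rbind, paths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$direction)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(xlim = c(0, grid$frame_px[1]),
                         ylim = c(grid$frame_px[2], 0)) +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Likelihood ellipses, subject %s (kappa = %.1f)",
                                  model$subject_id, model$kappa)) +
    ggplot2::theme_minimal()
}
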