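# Quick-look plots (ggplot2, Suggests-only).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_("ggplot2 is required for plotting")
  }
}

#' Plot a pressure frame as a heat map
#'
#' @param frame `H x W` pressure matrix (kPa); row 1 is the top of the mat.
#' @param title optional title.
#' @return a ggplot object.
#' @export
plot_frame <- function(frame, title = NULL) {
  need_ggplot()
  d <- expand.grid(row = seq_len(nrow(frame)), col = seq_len(ncol(frame)))
  d$p <- as.vector(frame)
  ggplot2::ggplot(d, ggplot2::aes(x = col, y = row,
                                  fill = p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "kPa") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a 3D pose as top and side views
#'
#' @param pose `J x 3` keypoint matrix (mm).
#' @param title optional title.
#' @return a ggplot object.
#' @export
plot_pose <- function(pose, title = NULL) {
  need_ggplot()
  p <- unclass(pose)
  d <- rbind(
    data.frame(a = p[, 1], b = p[, 2], view = "top (x-y)"),
    data.frame(a = p[, 1], b = p[, 3], view = "side (x-z)"))
  d$joint <- rep(rownames(p) %||% seq_len(nrow(p)), 2)
  ggplot2::ggplot(d, ggplot2::aes(x = a, y = b)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~view, scales = "free_y") +
    ggplot2::labs(title = title, x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("col", "row", "p", "a", "b", "view", "mpjpe_mm"))
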