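# Quick-look plotting.

#' Plot a flip-angle map slice
#'
#' Renders one axial slice of the simulated flip-angle map (masked voxels
#' only) as a ggplot2 raster. Requires ggplot2.
#'
#' @param sim A `ptx_sim` from [bloch_simulate()] or [sta_simulate()].
#' @param slice Slice index along the third axis (default: middle).
#' @return A ggplot object.
#' @export
plot_fa_map <- function(sim, slice = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  gs <- sim$grid_shape
  fa <- array(NA_real_, gs)
  fa[sim$mask_index] <- sim$fa
  if (is.null(slice)) slice <- ceiling(gs[3L] / 2)
  df <- expand.grid(x = seq_len(gs[1L]), y = seq_len(gs[2L]))
  df$fa <- as.vector(fa[, , slice])
  ggplot2::ggplot(df[!is.na(df$fa), ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fa)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "FA [deg]") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Flip-angle map, slice %d", slice),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an optimization history
#'
#' Cost-term traces over iterations for a [ptx_fit].
#'
#' @param fit A `ptx_fit` from [optimize_pulse()].
#' @param terms Which history columns to show.
#' @return A ggplot object.
#' @export
plot_history <- function(fit, terms = c("pen_rmse", "total")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  h <- fit$history
  long <- do.call(rbind, lapply(terms, function(tm)
    data.frame(iter = h$iter, term = tm, value = h[[tm]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iter, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "cost term") +
    ggplot2::theme_minimal()
}
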