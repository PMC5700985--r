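# Quick-look plots for the main result types (ggplot2).

#' Plot the HDR statistics of a threshold sweep
#'
#' Region count, mean area and HDR-covered area fraction against the
#' relative density threshold; an optional vertical line marks a selected
#' threshold.
#'
#' @param sweep a [sweep_thresholds()] result.
#' @param threshold optional selected threshold to mark.
#' @return A ggplot object.
#' @export
plot_threshold_sweep <- function(sweep, threshold = NULL) {
  stopifnot(inherits(sweep, "sofi_sweep"))
  tab <- sweep$table
  long <- tibble::tibble(
    threshold = rep(tab$threshold, 3L),
    metric = rep(c("n_regions", "mean_area_px2", "relative_area"),
                 each = nrow(tab)),
    value = c(tab$n_regions, tab$mean_area_px2, tab$relative_area))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1L) +
    ggplot2::labs(x = "density threshold (x delta_avg)", y = NULL)
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(threshold),
                                 linetype = "dashed")
  }
  p
}

#' Plot a molecular density map
#'
#' @param map a [compute_density_map()] result.
#' @param relative plot densities in multiples of `delta_avg` (default)
#'   rather than emitters per pixel area.
#' @return A ggplot object.
#' @export
plot_density_map <- function(map, relative = TRUE) {
  stopifnot(inherits(map, "sofi_density_map"))
  v <- if (relative) relative_density(map) else map$N
  v[!map$mask] <- NA_real_
  p_nm <- map$grid_pitch_nm
  d <- tibble::tibble(
    x_nm = rep((seq_len(ncol(v)) - 1L) * p_nm, each = nrow(v)),
    y_nm = rep((seq_len(nrow(v)) - 1L) * p_nm, times = ncol(v)),
    density = as.vector(v))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_nm, y = .data$y_nm,
                                  fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x [nm]", y = "y [nm]",
                  fill = if (relative) "N / delta_avg" else "N / px")
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.sofi_sweep <- function(object, ...) plot_threshold_sweep(object, ...)

#' @export
autoplot.sofi_density_map <- function(object, ...) plot_density_map(object, ...)

#' @importFrom rlang .data
NULL
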