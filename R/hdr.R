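#' Label 8-connected components of a binary image
#'
#' Foreground pixels touching edge- or corner-wise belong to one component
#' (8-connectivity), so diagonally linked high-density networks are not
#' split. Components are found as connected components of the pixel
#' adjacency graph.
#'
#' @param fg logical matrix (TRUE = foreground).
#' @return Integer matrix of the same shape; 0 = background, components are
#'   numbered from 1.
#' @export
label_components <- function(fg) {
  stopifnot(is.logical(fg), is.matrix(fg))
  lab <- matrix(0L, nrow(fg), ncol(fg))
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  H <- nrow(fg); W <- ncol(fg)
  vid <- integer(H * W)
  vid[idx] <- seq_along(idx)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  edges <- integer(0)
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    sel <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[sel] - 1L) * H + r2[sel]
    sel2 <- vid[nb] > 0L
    edges <- c(edges, rbind(vid[idx[sel][sel2]], vid[nb[sel2]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

#' Segment high-density regions at one threshold
#'
#' High-density regions (HDRs) are the 8-connected components of the set of
#' masked-in pixels whose relative density `N / delta_avg` is at or above
#' the threshold. Single-pixel components are retained: the threshold sweep
#' itself, not a hidden size cutoff, governs detection.
#'
#' @param map a [compute_density_map()] result.
#' @param threshold relative density threshold (multiple of `delta_avg`),
#'   >= 0.
#' @return A tibble with one row per region: `label`, `area_px`, `area_um2`,
#'   `equiv_diameter_nm` (diameter of the circle with the region's area),
#'   `centroid_x_nm`, `centroid_y_nm`, `mean_density` (relative units).
#' @export
segment_hdrs <- function(map, threshold) {
  stopifnot(inherits(map, "sofi_density_map"), threshold >= 0)
  rel <- map$N / map$delta_avg
  lab <- label_components(map$mask & rel >= threshold)
  idx <- which(lab > 0L)
  pitch <- map$grid_pitch_nm
  if (length(idx) == 0L) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), equiv_diameter_nm = numeric(),
                          centroid_x_nm = numeric(), centroid_y_nm = numeric(),
                          mean_density = numeric()))
  }
  l <- lab[idx]
  area <- tabulate(l)
  row <- (idx - 1L) %% nrow(lab)       # 0-based pixel coordinates
  col <- (idx - 1L) %/% nrow(lab)
  tibble::tibble(
    label = seq_along(area),
    area_px = area,
    area_um2 = area * (pitch / 1000)^2,
    equiv_diameter_nm = 2 * sqrt(area / pi) * pitch,
    centroid_x_nm = as.numeric(tapply(col, l, mean)) * pitch,
    centroid_y_nm = as.numeric(tapply(row, l, mean)) * pitch,
    mean_density = as.numeric(tapply(rel[idx], l, mean)))
}

#' Sweep the full range of density thresholds
#'
#' Applies [segment_hdrs()] at every threshold of a regular grid from 0 up
#' to the highest density level in the map, collecting per-threshold HDR
#' statistics: region count, mean area, mean equivalent diameter and the
#' fraction of the ROI (the masked-in area) covered by HDRs.
#'
#' @param map a [compute_density_map()] result.
#' @param t_max top of the threshold range in multiples of `delta_avg`;
#'   defaults to the maximum relative density in the masked map.
#' @param step threshold grid step in multiples of `delta_avg`.
#' @return An object of class `sofi_sweep`: a list with `table` (tibble with
#'   columns `threshold`, `n_regions`, `mean_area_px2`, `mean_equiv_diameter_nm`,
#'   `relative_area`), `regions` (list of [segment_hdrs()] tibbles),
#'   `delta_avg`, `grid_pitch_nm`, `roi_area_px` and `step`.
#' @export
sweep_thresholds <- function(map, t_max = NULL, step = 0.1) {
  stopifnot(inherits(map, "sofi_density_map"), step > 0)
  if (is.null(t_max)) t_max <- max(map$N[map$mask]) / map$delta_avg
  if (t_max < 0) stop("t_max must be non-negative")
  ts <- seq(0, by = step, length.out = floor(t_max / step) + 1L)
  if (ts[length(ts)] < t_max - 1e-12) ts <- c(ts, t_max)
  roi_area <- sum(map$mask)
  regions <- lapply(ts, function(t) segment_hdrs(map, t))
  stat <- function(f) vapply(regions, f, 0)
  tab <- tibble::tibble(
    threshold = ts,
    n_regions = vapply(regions, nrow, 0L),
    mean_area_px2 = stat(function(r) if (nrow(r)) mean(r$area_px) else NA_real_),
    mean_equiv_diameter_nm =
      stat(function(r) if (nrow(r)) mean(r$equiv_diameter_nm) else NA_real_),
    relative_area = stat(function(r) sum(r$area_px)) / roi_area)
  structure(list(table = tab, regions = regions, delta_avg = map$delta_avg,
                 grid_pitch_nm = map$grid_pitch_nm, roi_area_px = roi_area,
                 step = step),
            class = "sofi_sweep")
}

#' @export
print.sofi_sweep <- function(x, ...) {
  cat(sprintf(
    "<sofi_sweep> %d thresholds in [0, %.3g] x delta_avg (step %.3g), ROI %d px\n",
    nrow(x$table), max(x$table$threshold), x$step, x$roi_area_px))
  print(x$table, n = 5)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.sofi_sweep <- function(x, ...) x$table

# coerce user input (sofi_sweep or data.frame) to the fitted curve
.sweep_curve <- function(sweep) {
  if (inherits(sweep, "sofi_sweep")) return(sweep$table[c("threshold", "n_regions")])
  if (is.data.frame(sweep) &&
      all(c("threshold", "n_regions") %in% names(sweep))) {
    return(sweep[c("threshold", "n_regions")])
  }
  stop("sweep must be a sofi_sweep or a data.frame with columns threshold, n_regions")
}

#' Automatic density-threshold selection
#'
#' The region-count-vs-threshold curve of a spatially random molecule
#' distribution is bell-shaped: counts rise as the background fragments and
#' fall as fragments drop below detection. A Gaussian
#' `G(t) = A exp(-(t - m)^2 / (2 s^2))` is fitted to the curve by least
#' squares (initialized at the curve's peak) and the selected threshold is
#' the smallest `t > m` where the fitted count falls below one region —
#' in closed form `m + s sqrt(2 ln A)` — i.e. the density above which a
#' random distribution is expected to produce no region. The continuous
#' solution is snapped up to the threshold grid. If the fitted curve never
#' exceeds one region (`A <= 1`), the fitted center `m` is returned.
#'
#' @param sweep a [sweep_thresholds()] result (or a data frame with columns
#'   `threshold` and `n_regions`).
#' @return The selected threshold (relative density, grid value), with
#'   attributes `continuous` (un-snapped solution) and `fit`
#'   (named vector `A`, `m`, `s`).
#' @export
select_optimal_threshold <- function(sweep) {
  cur <- .sweep_curve(sweep)
  t <- cur$threshold; n <- as.numeric(cur$n_regions)
  if (length(t) < 4L) stop("threshold grid too short to fit a Gaussian")
  imax <- which.max(n)
  if (n[imax] <= 0) stop("degenerate region-count curve: no regions at any threshold")
  if (imax == length(t)) {
    stop("region-count curve has no interior maximum (still rising at t_max)")
  }
  above <- t[n >= n[imax] / 2]
  s0 <- max((max(above) - min(above)) / 2.355, diff(range(t)) / 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      n ~ A * exp(-(t - m)^2 / (2 * s^2)),
      start = list(A = n[imax], m = t[imax], s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit to the region-count curve failed: ",
                             conditionMessage(e), call. = FALSE))
  p <- coef(fit); A <- p[["A"]]; m <- p[["m"]]; s <- abs(p[["s"]])
  t_cont <- if (A <= 1) m else m + s * sqrt(2 * log(A))
  i <- which(t >= t_cont - 1e-9)[1L]
  t_sel <- if (is.na(i)) t[length(t)] else t[i]
  structure(t_sel, continuous = t_cont, fit = c(A = A, m = m, s = s))
}

#' Per-group summary of HDR statistics at a threshold
#'
#' Extracts each sample's HDR statistics at the grid threshold nearest `at`
#' and summarizes them per group with the usual box-plot statistics
#' (median, interquartile range, most extreme values).
#'
#' @param sweeps list of [sweep_thresholds()] results.
#' @param groups character or factor of group labels, one per sweep.
#' @param at relative density threshold at which to compare groups.
#' @return A tibble with columns `group`, `metric` (`n_regions`,
#'   `mean_area_px2`, `mean_equiv_diameter_nm`, `relative_area`), `median`,
#'   `iqr_low`, `iqr_high`, `min`, `max`, `n_samples`.
#' @export
summarize_hdr_groups <- function(sweeps, groups, at) {
  stopifnot(length(sweeps) >= 1L, length(groups) == length(sweeps),
            all(vapply(sweeps, inherits, TRUE, "sofi_sweep")), at >= 0)
  groups <- as.character(groups)
  metrics <- c("n_regions", "mean_area_px2", "mean_equiv_diameter_nm",
               "relative_area")
  rows <- lapply(seq_along(sweeps), function(i) {
    tab <- sweeps[[i]]$table
    j <- which.min(abs(tab$threshold - at))
    vals <- as.numeric(tab[j, metrics])
    tibble::tibble(group = groups[i], metric = metrics, value = vals)
  })
  d <- do.call(rbind, rows)
  out <- lapply(split(d, list(d$group, d$metric), drop = TRUE), function(g) {
    v <- g$value[!is.na(g$value)]
    stats <- if (length(v)) {
      c(median(v), quantile(v, c(0.25, 0.75), names = FALSE), min(v), max(v))
    } else rep(NA_real_, 5L)
    tibble::tibble(group = g$group[1L], metric = g$metric[1L],
                   median = stats[1L], iqr_low = stats[2L],
                   iqr_high = stats[3L], min = stats[4L], max = stats[5L],
                   n_samples = nrow(g))
  })
  res <- do.call(rbind, out)
  res[order(res$group, res$metric), ]
}
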