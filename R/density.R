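#' Spatial moments of the Gaussian PSF powers
#'
#' The point-spread function of an order-n cumulant image is the n-th power
#' of the system PSF `U(r)`. For a peak-normalized 2D Gaussian the spatial
#' moment `mu_n` is the sum of `U^n(r)` over the density-map grid,
#' `mu_n ~ 2 pi sigma^2 / (n * pitch^2)`, so cumulant amplitudes can be
#' converted to emitters per grid-pixel area. Evaluated numerically on a
#' `+/- 4 sigma` support; the analytic ratios `mu_2/mu_3 = 3/2` and
#' `mu_2/mu_4 = 2` hold to the truncation error.
#'
#' @param sigma_nm Gaussian PSF standard deviation in nm.
#' @param grid_pitch_nm pitch of the density-map grid in nm.
#' @return A list of class `sofi_psf_moments` with fields `sigma_nm`,
#'   `grid_pitch_nm` and `mu` (named vector `mu1..mu4`, strictly decreasing).
#' @export
psf_moments <- function(sigma_nm, grid_pitch_nm) {
  if (sigma_nm <= 0) stop("sigma_nm must be positive")
  if (grid_pitch_nm <= 0) stop("grid_pitch_nm must be positive")
  r <- seq(0, 4 * sigma_nm, by = grid_pitch_nm)
  x <- c(-rev(r[-1L]), r)
  U <- exp(-outer(x^2, x^2, `+`) / (2 * sigma_nm^2))
  mu <- vapply(1:4, function(n) sum(U^n), 0)
  names(mu) <- paste0("mu", 1:4)
  structure(list(sigma_nm = sigma_nm, grid_pitch_nm = grid_pitch_nm, mu = mu),
            class = "sofi_psf_moments")
}

#' Manually specified PSF moments
#'
#' Builds a `sofi_psf_moments` object from explicit moment values, e.g. for
#' forward-model checks where `mu_n = 1` is convenient.
#'
#' @param mu numeric vector of length 4 (`mu1..mu4`).
#' @param sigma_nm,grid_pitch_nm optional metadata.
#' @return A `sofi_psf_moments` object.
#' @export
psf_moments_manual <- function(mu, sigma_nm = NA_real_,
                               grid_pitch_nm = NA_real_) {
  stopifnot(is.numeric(mu), length(mu) == 4L, all(mu > 0))
  names(mu) <- paste0("mu", 1:4)
  structure(list(sigma_nm = sigma_nm, grid_pitch_nm = grid_pitch_nm, mu = mu),
            class = "sofi_psf_moments")
}

#' Estimate per-pixel blinking parameters from cumulant ratios
#'
#' Balanced-SOFI inversion of the blinking statistics. With
#' `K1 = mu2 g3 / (mu3 g2)` and `K2 = mu2 g4 / (mu4 g2)`, a population of
#' identical Bernoulli emitters of brightness `eps` and on-time ratio `rho`
#' satisfies `K1 = eps (1 - 2 rho)` and `K2 = eps^2 (1 - 6 rho + 6 rho^2)`,
#' which inverts to
#' `eps = sqrt(3 K1^2 - 2 K2)` and
#' `rho = (3 K1^2 - K1 sqrt(3 K1^2 - 2 K2) - 2 K2) / (2 (3 K1^2 - 2 K2))`.
#'
#' The cumulant ratios of a single virtual pixel are extremely noisy where
#' the signal is weak; since the blinking parameters are only resolvable at
#' the cumulant PSF scale anyway, the ratios can be estimated from locally
#' averaged cumulant images (`ratio_smooth_px` > 0, a Gaussian kernel with
#' normalized edge handling). Smoothing affects only the ratio estimation;
#' the density numerator keeps the unsmoothed g2. On a spatially uniform
#' field smoothing is the identity, so forward-model inversions are exact
#' either way.
#'
#' Pixels where the inversion is ill-posed are flagged invalid rather than
#' clipped: `g2` below `g2_tol_frac * max(g2)`, `g2` not significantly above
#' its own estimation noise (when the cumulant set carries a block-to-block
#' standard error, `g2 <= g2_snr * g2_se`), `3 K1^2 - 2 K2 <= 0`, or
#' `rho` outside `rho_limits`.
#'
#' @param cumulants a `sofi_cumulants` with g2, g3 and g4.
#' @param moments a [psf_moments()] object.
#' @param g2_tol_frac relative g2 floor below which a pixel is invalid.
#' @param rho_limits admissible open interval for the on-time ratio.
#' @param ratio_smooth_px Gaussian sigma (in grid pixels) for the local
#'   averaging of g2, g3, g4 before forming K1 and K2; 0 disables it.
#' @param g2_snr significance multiple for the g2 noise guard; only applied
#'   when `cumulants$g2_se` is available.
#' @return An object of class `sofi_blinking` with matrix fields `K1`, `K2`,
#'   `epsilon`, `rho_on` (NA on invalid pixels) and logical `valid`.
#' @export
estimate_blinking <- function(cumulants, moments, g2_tol_frac = 1e-12,
                              rho_limits = c(0.001, 0.999),
                              ratio_smooth_px = 0, g2_snr = 2) {
  stopifnot(inherits(cumulants, "sofi_cumulants"),
            inherits(moments, "sofi_psf_moments"), ratio_smooth_px >= 0)
  g2 <- cumulants$g2; g3 <- cumulants$g3; g4 <- cumulants$g4
  if (is.null(g2) || is.null(g3) || is.null(g4)) {
    stop("blinking estimation needs cumulant orders 2, 3 and 4")
  }
  ok <- g2 > g2_tol_frac * max(g2)
  if (!is.null(cumulants$g2_se) && g2_snr > 0) {
    ok <- ok & g2 > g2_snr * cumulants$g2_se
  }
  if (ratio_smooth_px > 0) {
    g2 <- gaussian_smooth(g2, ratio_smooth_px)
    g3 <- gaussian_smooth(g3, ratio_smooth_px)
    g4 <- gaussian_smooth(g4, ratio_smooth_px)
  }
  mu <- moments$mu
  ok <- ok & g2 > 0
  K1 <- K2 <- eps <- rho <- matrix(NA_real_, nrow(g2), ncol(g2))
  K1[ok] <- mu[["mu2"]] * g3[ok] / (mu[["mu3"]] * g2[ok])
  K2[ok] <- mu[["mu2"]] * g4[ok] / (mu[["mu4"]] * g2[ok])
  D <- 3 * K1^2 - 2 * K2
  ok <- ok & !is.na(D) & D > 0
  eps[ok] <- sqrt(D[ok])
  rho[ok] <- (3 * K1[ok]^2 - K1[ok] * eps[ok] - 2 * K2[ok]) / (2 * D[ok])
  ok <- ok & !is.na(rho) & rho > rho_limits[1L] & rho < rho_limits[2L]
  eps[!ok] <- NA_real_; rho[!ok] <- NA_real_
  if (!any(ok)) stop("blinking inversion is ill-posed on every pixel")
  structure(list(K1 = K1, K2 = K2, epsilon = eps, rho_on = rho, valid = ok),
            class = "sofi_blinking")
}

#' Gaussian smoothing with normalized edge handling
#'
#' Separable Gaussian convolution; near the border the kernel is
#' renormalized to the mass inside the image, so edges are neither darkened
#' nor reflected.
#'
#' @param m numeric matrix.
#' @param sigma_px kernel standard deviation in pixels.
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(m, sigma_px) {
  stopifnot(is.matrix(m), sigma_px > 0)
  band <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), `-`))
    k <- exp(-d^2 / (2 * sigma_px^2))
    k[d > 3 * sigma_px] <- 0
    k / rowSums(k)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' Regularize blinking parameters for a single fluorophore species
#'
#' The per-pixel blinking inversion is exact for ideal data but ill-
#' conditioned where the signal is weak: small errors in the 3rd/4th-order
#' cumulants produce order-of-magnitude excursions of the per-pixel
#' `epsilon^2 rho (1 - rho)` density denominator. When all emitters are one
#' fluorophore species, brightness and kinetics are global molecular
#' properties, so the robust choice for density mapping is to replace the
#' per-pixel fields by their medians over high-signal pixels and to keep as
#' valid every pixel whose g2 is significantly above its estimation noise.
#' Absolute densities are insensitive to this because the same denominator
#' scales the whole map; it is the spatial structure of g2 that carries the
#' density contrast.
#'
#' @param params a [estimate_blinking()] result.
#' @param cumulants the `sofi_cumulants` the parameters came from.
#' @param hi_fraction fraction of `max(g2)` above which pixels count as
#'   high-signal for the medians.
#' @param g2_snr significance multiple of the g2 standard error for the
#'   validity raster (ignored when no `g2_se` is available).
#' @return A `sofi_blinking` with constant `epsilon` and `rho_on` rasters
#'   and an SNR-based `valid` raster.
#' @export
regularize_blinking <- function(params, cumulants, hi_fraction = 0.25,
                                g2_snr = 2) {
  stopifnot(inherits(params, "sofi_blinking"),
            inherits(cumulants, "sofi_cumulants"))
  g2 <- cumulants$g2
  hi <- params$valid & g2 > hi_fraction * max(g2)
  if (!any(hi)) hi <- params$valid
  eps_ref <- median(params$epsilon[hi])
  rho_ref <- median(params$rho_on[hi])
  valid <- if (!is.null(cumulants$g2_se) && g2_snr > 0) {
    g2 > g2_snr * cumulants$g2_se
  } else {
    g2 > 0
  }
  params$epsilon[] <- eps_ref
  params$rho_on[] <- rho_ref
  params$valid <- valid
  params
}

#' Richardson-Lucy deconvolution of a cumulant image
#'
#' Sharpen a non-negative raster with the iterative Richardson-Lucy scheme
#' under a Gaussian kernel. The order-n cumulant image carries the n-th
#' power of the system PSF, i.e. an effective Gaussian of width
#' `sigma / sqrt(n)`; deconvolving the 2nd-order image before the density
#' inversion restores part of the resolution that the raw g2 numerator
#' lacks compared to the 4th-order sampling grid.
#'
#' @param m non-negative numeric matrix.
#' @param sigma_px Gaussian kernel sigma in grid pixels.
#' @param iterations Richardson-Lucy iterations.
#' @return The deconvolved matrix (non-negative, same size).
#' @export
deconvolve_cumulant <- function(m, sigma_px, iterations = 100) {
  stopifnot(is.matrix(m), sigma_px > 0, iterations >= 0)
  est <- pmax(m, 0)
  if (iterations == 0) return(est)
  est <- est + 1e-12
  obs <- pmax(m, 0)
  for (i in seq_len(iterations)) {
    conv <- gaussian_smooth(est, sigma_px)
    est <- est * gaussian_smooth(obs / pmax(conv, 1e-12), sigma_px)
  }
  est
}

#' Per-pixel molecular density map
#'
#' Inverts the 2nd-order cumulant into a molecular density (emitters per
#' grid-pixel area): since `g2 = N mu2 eps^2 rho (1 - rho)` for `N` emitters
#' per pixel area,
#' `N(r) = (g2 / mu2) / (eps^2 rho (1 - rho))`
#' with `eps`, `rho` from [estimate_blinking()]. This is the closed-form
#' density equation written in terms of the recovered blinking parameters,
#' with the `mu2` normalization of the 2nd-order PSF made explicit. Pixels
#' flagged invalid by the blinking inversion get density 0 and are excluded
#' from the ROI mean `delta_avg`.
#'
#' @param cumulants a `sofi_cumulants`.
#' @param params a `sofi_blinking` from [estimate_blinking()].
#' @param moments a [psf_moments()] object.
#' @param mask optional logical matrix (TRUE = analyze); defaults to the
#'   full field. See [background_mask()].
#' @return An object of class `sofi_density_map` with fields `N` (matrix),
#'   `delta_avg` (mean over valid, masked-in pixels), `mask`, `valid` and
#'   `grid_pitch_nm`.
#' @export
compute_density_map <- function(cumulants, params, moments, mask = NULL) {
  stopifnot(inherits(cumulants, "sofi_cumulants"),
            inherits(params, "sofi_blinking"),
            inherits(moments, "sofi_psf_moments"))
  g2 <- cumulants$g2
  if (is.null(mask)) mask <- matrix(TRUE, nrow(g2), ncol(g2))
  stopifnot(identical(dim(mask), dim(g2)))
  ok <- params$valid
  N <- matrix(0, nrow(g2), ncol(g2))
  N[ok] <- (g2[ok] / moments$mu[["mu2"]]) /
    (params$epsilon[ok]^2 * params$rho_on[ok] * (1 - params$rho_on[ok]))
  sel <- ok & mask
  if (!any(sel)) stop("no valid pixel inside the mask")
  structure(list(N = N, delta_avg = mean(N[sel]), mask = mask, valid = ok,
                 grid_pitch_nm = cumulants$grid_pitch_nm),
            class = "sofi_density_map")
}

#' @export
print.sofi_density_map <- function(x, ...) {
  cat(sprintf(
    "<sofi_density_map> %d x %d px (pitch %.4g nm), delta_avg %.4g /px (%.4g /um^2), %d%% masked-in\n",
    nrow(x$N), ncol(x$N), x$grid_pitch_nm, x$delta_avg,
    x$delta_avg / (x$grid_pitch_nm / 1000)^2,
    round(100 * mean(x$mask))))
  invisible(x)
}

#' Relative density values of a map
#'
#' @param map a `sofi_density_map`.
#' @return Matrix of densities in multiples of the ROI mean `delta_avg`.
#' @export
relative_density <- function(map) {
  stopifnot(inherits(map, "sofi_density_map"))
  map$N / map$delta_avg
}

#' Background mask from a bSOFI image
#'
#' Thresholds the linearized (brightness-linear) bSOFI image at a fixed
#' fraction of its maximum and keeps the largest 8-connected foreground
#' component, removing background areas and detached debris from the
#' density analysis.
#'
#' @param bsofi a [linearize_cumulant()] result.
#' @param fraction relative threshold in (0, 1).
#' @return Logical matrix (TRUE = analyze).
#' @export
background_mask <- function(bsofi, fraction = 0.05) {
  stopifnot(inherits(bsofi, "sofi_bsofi"),
            fraction > 0, fraction < 1)
  v <- bsofi$values
  if (max(v) <= 0) stop("background mask is empty: no foreground signal")
  fg <- v >= fraction * max(v)
  lab <- label_components(fg)
  sizes <- tabulate(lab[fg])
  lab == which.max(sizes)
}

#' Normalize density maps across samples and groups
#'
#' Two-step normalization that removes expression and acquisition scale
#' differences while preserving between-group density contrasts: every
#' sample map is first rescaled so that its masked mean density equals its
#' group mean; all maps are then divided by the maximum of the group means,
#' yielding relative densities comparable across groups.
#'
#' @param maps list of `sofi_density_map` objects.
#' @param groups character or factor of group labels, one per map.
#' @return List of normalized `sofi_density_map`s (same order), with an
#'   attribute `group_means` holding the post-normalization group means.
#' @export
normalize_density_groups <- function(maps, groups) {
  stopifnot(length(maps) >= 1L, length(groups) == length(maps),
            all(vapply(maps, inherits, TRUE, "sofi_density_map")))
  groups <- as.character(groups)
  sample_means <- vapply(maps, `[[`, 0, "delta_avg")
  if (any(sample_means <= 0)) stop("every sample must have a positive mean density")
  group_means <- tapply(sample_means, groups, mean)
  scale_max <- max(group_means)
  out <- lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    s <- (group_means[[groups[i]]] / sample_means[i]) / scale_max
    m$N <- m$N * s
    m$delta_avg <- m$delta_avg * s
    m
  })
  attr(out, "group_means") <- c(group_means / scale_max)
  out
}

#' Nyquist-limited minimum detectable feature diameter
#'
#' By the Shannon-Nyquist criterion the smallest detectable high-density
#' region on a density map of pitch `p` has a diameter of `2 p`.
#'
#' @param grid_pitch_nm density-map pixel pitch in nm.
#' @return Diameter in nm.
#' @export
nyquist_diameter_nm <- function(grid_pitch_nm) 2 * grid_pitch_nm
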