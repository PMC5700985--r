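# Shared fixtures, all built in code.

# camera config used by most I/O tests
test_config <- function(...) {
  acquisition_config(pixel_pitch_nm = 105, em_gain = 300, offset_counts = 100,
                     read_noise_counts = 10, psf_sigma_nm = 130,
                     frame_time_s = 0.032, ...)
}

# noiseless sequence of one or more static Gaussian spots (pixel-integrated),
# positions are (x, y) in 0-based pixel units
spot_sequence <- function(pos, H = 20, W = 24, n_frames = 20, sigma_px = 1,
                          amplitude = 1000, pitch = 105) {
  img <- matrix(0, H, W)
  for (k in seq_len(nrow(pos))) {
    fx <- pnorm((0:(W - 1) + 0.5 - pos[k, 1]) / sigma_px) -
      pnorm((0:(W - 1) - 0.5 - pos[k, 1]) / sigma_px)
    fy <- pnorm((0:(H - 1) + 0.5 - pos[k, 2]) / sigma_px) -
      pnorm((0:(H - 1) - 0.5 - pos[k, 2]) / sigma_px)
    img <- img + amplitude * outer(fy, fx)
  }
  sofi_sequence(array(rep(img, n_frames), c(H, W, n_frames)), pitch)
}

# sequence of a blinking point emitter with a point-sampled Gaussian PSF,
# for which the cross-cumulant distance factor is exact
blinking_emitter_sequence <- function(trace, center = c(8, 8), H = 15,
                                      sigma_px = 130 / 105, pitch = 105,
                                      amplitude = 1) {
  U <- amplitude * exp(-(outer((seq_len(H) - center[2])^2,
                               (seq_len(H) - center[1])^2, `+`)) /
                         (2 * sigma_px^2))
  sofi_sequence(array(as.vector(U) %o% trace, c(H, H, length(trace))), pitch)
}

# uniform-field cumulant set from the forward model g_n = N mu_n eps^n k_n(rho)
forward_cumulants <- function(N, eps, rho, mu = c(1, 1, 1, 1), dims = c(5, 5),
                              grid_pitch_nm = 26.25) {
  k <- bernoulli_cumulants(rho)
  mk <- function(v) matrix(v, dims[1], dims[2])
  structure(list(g2 = mk(N * mu[2] * eps^2 * k[["k2"]]),
                 g3 = mk(N * mu[3] * eps^3 * k[["k3"]]),
                 g4 = mk(N * mu[4] * eps^4 * k[["k4"]]),
                 g2_se = NULL, grid_pitch_nm = grid_pitch_nm,
                 camera_pitch_nm = grid_pitch_nm * 4, n_blocks = 1L),
            class = "sofi_cumulants")
}

# density map built directly from an N raster (delta_avg from the mask)
manual_density_map <- function(N, mask = NULL, grid_pitch_nm = 26.25,
                               delta_avg = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(N), ncol(N))
  if (is.null(delta_avg)) delta_avg <- mean(N[mask])
  structure(list(N = N, delta_avg = delta_avg, mask = mask,
                 valid = matrix(TRUE, nrow(N), ncol(N)),
                 grid_pitch_nm = grid_pitch_nm),
            class = "sofi_density_map")
}

# sweep object around an externally supplied count curve (for the threshold
# selection tests)
manual_sweep <- function(threshold, n_regions) {
  structure(list(table = tibble::tibble(
    threshold = threshold, n_regions = n_regions,
    mean_area_px2 = NA_real_, mean_equiv_diameter_nm = NA_real_,
    relative_area = NA_real_),
    regions = NULL, delta_avg = 1, grid_pitch_nm = 26.25,
    roi_area_px = 100L, step = diff(threshold[1:2])),
    class = "sofi_sweep")
}

# chunked standard error of a temporal cumulant estimator
chunk_se <- function(x, order, n_chunks = 25) {
  idx <- cut(seq_along(x), n_chunks, labels = FALSE)
  est <- vapply(split(x, idx), function(ch) {
    sample_cumulants(ch, orders = order)[[1]]
  }, 0)
  stats::sd(est) / sqrt(n_chunks)
}
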