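#' Run the full SOFI density and HDR analysis on a sequence
#'
#' Chains the analysis stages: optional fiducial-based drift correction,
#' block-wise 2nd–4th-order cross-cumulant imaging, bSOFI background
#' masking, blinking-parameter and density inversion, the threshold sweep
#' and automatic threshold selection.
#'
#' @param seq a [sofi_sequence()] (photoelectron counts).
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm.
#' @param block_len frames per cumulant block.
#' @param orders cumulant orders (must include 2, 3, 4 for the density
#'   inversion).
#' @param mask_fraction bSOFI mask threshold (fraction of the maximum).
#' @param ratio_smooth_nm Gaussian sigma (nm) for the local averaging of the
#'   cumulant images entering the blinking-ratio estimation (see
#'   [estimate_blinking()]); defaults to half the PSF sigma, the width of
#'   the 4th-order cumulant PSF. Set to 0 to invert single-pixel ratios.
#' @param blinking `"global"` (default) treats brightness and on-time ratio
#'   as species-wide constants estimated robustly from high-signal pixels
#'   ([regularize_blinking()]); `"pixel"` uses the raw per-pixel inversion.
#' @param deconvolve_iters Richardson-Lucy iterations applied to the g2
#'   density numerator ([deconvolve_cumulant()]); 0 disables deconvolution.
#' @param threshold_step threshold grid step, in multiples of `delta_avg`.
#' @param t_max top of the threshold range (NULL = full density range).
#' @param drift one of `"none"`, `"auto"` (correct if fiducials are found,
#'   else continue uncorrected) or `"require"`.
#' @param bead_brightness minimum fiducial brightness in photoelectron
#'   counts; default half the brightest pixel of the early-sequence mean.
#' @return An object of class `sofi_analysis`: a list with `cumulants`,
#'   `bsofi`, `mask`, `blinking`, `density`, `sweep`, `threshold`
#'   (selected relative threshold with fit attributes), `regions` (tibble
#'   at the selected threshold), `drift` (trace or NULL) and `params`.
#' @export
analyze_sequence <- function(seq, psf_sigma_nm, block_len = 500,
                             orders = 2:4, mask_fraction = 0.05,
                             ratio_smooth_nm = psf_sigma_nm / 2,
                             blinking = c("global", "pixel"),
                             deconvolve_iters = 100,
                             threshold_step = 0.1, t_max = NULL,
                             drift = c("none", "auto", "require"),
                             bead_brightness = NULL) {
  stopifnot(is_sofi_sequence(seq))
  drift <- match.arg(drift)
  if (!all(c(2, 3, 4) %in% orders)) {
    stop("the density inversion needs cumulant orders 2, 3 and 4")
  }
  trace <- NULL
  if (drift != "none") {
    if (is.null(bead_brightness)) {
      ref <- rowMeans(unclass(seq)[, , seq_len(min(50L, n_frames(seq))),
                                   drop = FALSE], dims = 2L)
      bead_brightness <- max(ref) / 2
    }
    tracked <- tryCatch(track_fiducials(seq, bead_brightness),
                        error = function(e) e)
    if (inherits(tracked, "error")) {
      if (drift == "require") stop(tracked)
      message("drift correction skipped: ", conditionMessage(tracked))
    } else {
      trace <- estimate_drift(tracked)
      seq <- apply_drift_correction(seq, trace)
    }
  }
  cum <- compute_cumulants(seq, psf_sigma_nm, block_len, orders)
  bsofi <- linearize_cumulant(cum$g2, 2L)
  mask <- background_mask(bsofi, mask_fraction)
  moments <- psf_moments(psf_sigma_nm, cum$grid_pitch_nm)
  blinking <- match.arg(blinking)
  blink <- estimate_blinking(cum, moments,
                             ratio_smooth_px = ratio_smooth_nm / cum$grid_pitch_nm)
  if (blinking == "global") blink <- regularize_blinking(blink, cum)
  cum_n <- cum                      # numerator for the density inversion
  if (deconvolve_iters > 0) {
    cum_n$g2 <- deconvolve_cumulant(
      cum_n$g2, psf_sigma_nm / sqrt(2) / cum_n$grid_pitch_nm, deconvolve_iters)
  }
  map <- compute_density_map(cum_n, blink, moments, mask)
  sweep <- sweep_thresholds(map, t_max = t_max, step = threshold_step)
  thr <- tryCatch(select_optimal_threshold(sweep), error = function(e) {
    message("automatic threshold selection failed: ", conditionMessage(e))
    structure(NA_real_, fit = c(A = NA_real_, m = NA_real_, s = NA_real_))
  })
  regions <- if (is.na(thr)) segment_hdrs(map, Inf) else
    segment_hdrs(map, as.numeric(thr))
  structure(list(
    cumulants = cum, bsofi = bsofi, mask = mask, blinking = blink,
    density = map, sweep = sweep, threshold = thr, regions = regions,
    drift = trace,
    params = list(psf_sigma_nm = psf_sigma_nm, block_len = block_len,
                  orders = orders, mask_fraction = mask_fraction,
                  ratio_smooth_nm = ratio_smooth_nm,
                  blinking = blinking, deconvolve_iters = deconvolve_iters,
                  threshold_step = threshold_step,
                  grid_pitch_nm = cum$grid_pitch_nm,
                  nyquist_diameter_nm = nyquist_diameter_nm(cum$grid_pitch_nm))),
    class = "sofi_analysis")
}

#' @export
print.sofi_analysis <- function(x, ...) {
  cat(sprintf(
    paste0("<sofi_analysis> grid pitch %.4g nm (Nyquist %.4g nm), ",
           "delta_avg %.4g /px\n  selected threshold %.3g x delta_avg: ",
           "%d HDR(s), relative area %.3g\n"),
    x$params$grid_pitch_nm, x$params$nyquist_diameter_nm,
    x$density$delta_avg, as.numeric(x$threshold), nrow(x$regions),
    sum(x$regions$area_px) / x$sweep$roi_area_px))
  invisible(x)
}

#' HDR recovery experiment with a matched random control
#'
#' Implements the simulation validation protocol: for every replicate a
#' clustered scenario and a random control with the same expected total
#' molecule density are simulated and analyzed; the density threshold is
#' selected automatically from the control's region-count curve (the
#' Gaussian of a random distribution falling below one region,
#' [select_optimal_threshold()]) and applied to the clustered sample, whose
#' segmented HDR count is compared to the ground truth. Because sample and
#' control share the same expected mean density, their relative density
#' scales coincide and the control threshold transfers directly.
#'
#' @param seeds integer vector, one seed per replicate.
#' @param diameter_nm,hdr_density_per_um2,contrast,n_hdrs scenario
#'   parameters (see [make_ground_truth()]).
#' @param n_frames_total frames per sequence.
#' @param field_um field side in micrometres.
#' @param model,optics simulation models.
#' @param ... further arguments passed to [analyze_sequence()].
#' @return A tibble with one row per replicate: `seed`, `threshold`
#'   (control-calibrated, in multiples of the sample mean density),
#'   `n_regions` (count at that threshold), `n_true` (ground-truth HDRs),
#'   `control_n_at_threshold` (control count at its own threshold).
#' @export
hdr_recovery_experiment <- function(seeds, diameter_nm = 180,
                                    hdr_density_per_um2 = 3000,
                                    contrast = 100, n_hdrs = 10,
                                    n_frames_total = 5000, field_um = 3,
                                    model = photokinetics_model(),
                                    optics = acquisition_config(), ...) {
  frac <- n_hdrs * pi * (diameter_nm / 2000)^2 / prod(rep(field_um, 2L))
  d_total <- hdr_density_per_um2 * frac +
    hdr_density_per_um2 / contrast * (1 - frac)
  rows <- lapply(seeds, function(sd) {
    cl <- simulate_scenario(diameter_nm, hdr_density_per_um2, contrast,
                            n_hdrs = n_hdrs, n_frames_total = n_frames_total,
                            field_um = field_um, model = model,
                            optics = optics, seed = sd)
    ct <- simulate_scenario(d_total, d_total, contrast = 1, n_hdrs = 0,
                            n_frames_total = n_frames_total,
                            field_um = field_um, model = model,
                            optics = optics, seed = sd + 500000L)
    a_cl <- analyze_sequence(cl$seq, psf_sigma_nm = optics$psf_sigma_nm, ...)
    a_ct <- analyze_sequence(ct$seq, psf_sigma_nm = optics$psf_sigma_nm, ...)
    thr <- as.numeric(a_ct$threshold)
    count_at <- function(sweep, t) {
      i <- which(sweep$table$threshold >= t - 1e-9)[1L]
      if (is.na(i)) 0L else sweep$table$n_regions[i]
    }
    tibble::tibble(seed = sd, threshold = thr,
                   n_regions = count_at(a_cl$sweep, thr),
                   n_true = nrow(cl$gt$hdrs),
                   control_n_at_threshold = count_at(a_ct$sweep, thr))
  })
  do.call(rbind, rows)
}

#' One-line numeric summary of an analysis
#'
#' @param analysis a [analyze_sequence()] result.
#' @return A single-row tibble: `selected_threshold`, `n_regions`,
#'   `mean_equiv_diameter_nm`, `relative_area`, `delta_avg`,
#'   `grid_pitch_nm`, `nyquist_diameter_nm`, `n_blocks`.
#' @export
analysis_summary <- function(analysis) {
  stopifnot(inherits(analysis, "sofi_analysis"))
  r <- analysis$regions
  tibble::tibble(
    selected_threshold = as.numeric(analysis$threshold),
    n_regions = nrow(r),
    mean_equiv_diameter_nm = if (nrow(r)) mean(r$equiv_diameter_nm) else NA_real_,
    relative_area = sum(r$area_px) / analysis$sweep$roi_area_px,
    delta_avg = analysis$density$delta_avg,
    grid_pitch_nm = analysis$params$grid_pitch_nm,
    nyquist_diameter_nm = analysis$params$nyquist_diameter_nm,
    n_blocks = analysis$cumulants$n_blocks)
}
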