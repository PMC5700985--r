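#' Photokinetics model of a photoswitching fluorophore
#'
#' Markov description of a PALM-type fluorescent protein: a molecule is
#' photo-activated after a geometric waiting time, then alternates between
#' an emitting (on) and a dark (off) state with geometric dwell times, and
#' irreversibly photobleaches from the on state. Defaults emulate sparse
#' mEos2-like traces at ~32 ms exposure: slow activation, short on-times,
#' long off-times and a low on-time ratio, which keeps higher-order
#' cumulants well conditioned.
#'
#' @param mean_on_frames mean on-dwell in frames (>= 1).
#' @param mean_off_frames mean off-dwell in frames (>= 1).
#' @param activation_rate_per_frame per-frame activation probability;
#'   1 means active from the first frame.
#' @param bleach_prob_per_on_frame per-on-frame bleaching probability;
#'   0 disables bleaching.
#' @param brightness_photons_per_frame mean emitted photons per on-frame.
#' @return A list of class `sofi_photokinetics`; field `rho_on` holds the
#'   implied stationary on-time ratio
#'   `mean_on / (mean_on + mean_off)`.
#' @export
photokinetics_model <- function(mean_on_frames = 2, mean_off_frames = 20,
                                activation_rate_per_frame = 5e-4,
                                bleach_prob_per_on_frame = 0.05,
                                brightness_photons_per_frame = 300) {
  stopifnot(mean_on_frames >= 1, mean_off_frames >= 1,
            activation_rate_per_frame > 0, activation_rate_per_frame <= 1,
            bleach_prob_per_on_frame >= 0, bleach_prob_per_on_frame <= 1,
            brightness_photons_per_frame >= 0)
  structure(list(mean_on_frames = mean_on_frames,
                 mean_off_frames = mean_off_frames,
                 rho_on = mean_on_frames / (mean_on_frames + mean_off_frames),
                 activation_rate_per_frame = activation_rate_per_frame,
                 bleach_prob_per_on_frame = bleach_prob_per_on_frame,
                 brightness_photons_per_frame = brightness_photons_per_frame),
            class = "sofi_photokinetics")
}

#' Ground-truth molecule layout with circular high-density regions
#'
#' Places `n_hdrs` non-overlapping circular HDRs fully inside a rectangular
#' field and populates them with Poisson molecule counts at the requested
#' density; a uniform background at `hdr density / contrast` covers the
#' whole field. `n_hdrs = 0` yields a purely random layout (control).
#'
#' @param n_hdrs number of high-density regions.
#' @param diameter_nm HDR diameter in nm: a single value, or a range
#'   `c(min, max)` sampled uniformly per HDR.
#' @param hdr_density_per_um2 molecular density inside HDRs in
#'   molecules/um^2 (single value or range).
#' @param contrast HDR-to-background density ratio (> 0).
#' @param field_um field side length(s) in micrometres (scalar or `c(w, h)`).
#' @param seed RNG seed (integer) or NULL to use the current RNG state.
#' @param max_tries placement retries before giving up.
#' @return A list of class `sofi_ground_truth`: `molecules` (tibble with
#'   `x_nm`, `y_nm`, `hdr_id`; 0 = background), `hdrs` (tibble with
#'   `hdr_id`, `x_nm`, `y_nm`, `diameter_nm`, `density_per_um2`,
#'   `n_molecules`), `background_density_per_um2`, `field_nm`, `seed`.
#' @export
make_ground_truth <- function(n_hdrs = 10, diameter_nm = c(60, 180),
                              hdr_density_per_um2 = c(500, 3000),
                              contrast = 100, field_um = 3, seed = NULL,
                              max_tries = 10000) {
  stopifnot(n_hdrs >= 0, all(diameter_nm > 0), all(hdr_density_per_um2 > 0),
            contrast > 0, all(field_um > 0))
  if (!is.null(seed)) set.seed(seed)
  field_nm <- rep(field_um, length.out = 2L) * 1000
  draw <- function(rng, k) if (length(rng) == 2L) runif(k, rng[1L], rng[2L]) else rep(rng, k)

  diam <- draw(diameter_nm, n_hdrs)
  dens <- draw(hdr_density_per_um2, n_hdrs)
  centers <- matrix(NA_real_, n_hdrs, 2L)
  if (n_hdrs > 0) {
    if (any(diam >= field_nm[1L]) || any(diam >= field_nm[2L])) {
      stop("HDR diameter exceeds the field")
    }
    placed <- 0L; tries <- 0L
    while (placed < n_hdrs) {
      if ((tries <- tries + 1L) > max_tries) {
        stop("could not place ", n_hdrs, " non-overlapping HDRs in ",
             max_tries, " tries")
      }
      k <- placed + 1L
      cand <- c(runif(1, diam[k] / 2, field_nm[1L] - diam[k] / 2),
                runif(1, diam[k] / 2, field_nm[2L] - diam[k] / 2))
      ok <- TRUE
      if (placed > 0L) {
        dd <- sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - cand)^2))
        ok <- all(dd >= (diam[seq_len(placed)] + diam[k]) / 2)
      }
      if (ok) { centers[k, ] <- cand; placed <- k }
    }
  }

  mols <- list()
  n_per_hdr <- integer(n_hdrs)
  for (k in seq_len(n_hdrs)) {
    r_um <- diam[k] / 2000
    n_k <- rpois(1L, dens[k] * pi * r_um^2)
    n_per_hdr[k] <- n_k
    if (n_k > 0L) {
      rr <- diam[k] / 2 * sqrt(runif(n_k)); th <- runif(n_k, 0, 2 * pi)
      mols[[length(mols) + 1L]] <- tibble::tibble(
        x_nm = centers[k, 1L] + rr * cos(th),
        y_nm = centers[k, 2L] + rr * sin(th),
        hdr_id = k)
    }
  }
  bg_density <- mean(dens %||% hdr_density_per_um2) / contrast
  n_bg <- rpois(1L, bg_density * prod(field_nm / 1000))
  if (n_bg > 0L) {
    mols[[length(mols) + 1L]] <- tibble::tibble(
      x_nm = runif(n_bg, 0, field_nm[1L]),
      y_nm = runif(n_bg, 0, field_nm[2L]),
      hdr_id = 0L)
  }
  molecules <- if (length(mols)) do.call(rbind, mols) else
    tibble::tibble(x_nm = numeric(), y_nm = numeric(), hdr_id = integer())
  structure(list(
    molecules = molecules,
    hdrs = tibble::tibble(hdr_id = seq_len(n_hdrs), x_nm = centers[, 1L],
                          y_nm = centers[, 2L], diameter_nm = diam,
                          density_per_um2 = dens, n_molecules = n_per_hdr),
    background_density_per_um2 = bg_density,
    field_nm = field_nm, seed = seed),
    class = "sofi_ground_truth")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' @export
print.sofi_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<sofi_ground_truth> %d molecules, %d HDRs on %.3g x %.3g um, background %.3g /um^2\n",
    nrow(x$molecules), nrow(x$hdrs), x$field_nm[1L] / 1000,
    x$field_nm[2L] / 1000, x$background_density_per_um2))
  invisible(x)
}

#' Simulate photon time traces of blinking molecules
#'
#' Each molecule is inactive until a geometric activation time, then follows
#' a two-state Markov chain with geometric on/off dwell times and bleaches
#' irreversibly with a fixed probability per on-frame; emitted photons per
#' on-frame are Poisson with the model brightness.
#'
#' @param n_molecules number of molecules.
#' @param n_frames_total number of frames to simulate.
#' @param model a [photokinetics_model()].
#' @param seed RNG seed or NULL.
#' @return A list of class `sofi_traces`: `events` (tibble with `molecule`,
#'   `frame`, `photons`; one row per on-frame), `n_molecules`, `n_frames`,
#'   `model`.
#' @export
simulate_traces <- function(n_molecules, n_frames_total, model, seed = NULL) {
  stopifnot(n_molecules >= 0, n_frames_total >= 1,
            inherits(model, "sofi_photokinetics"))
  if (!is.null(seed)) set.seed(seed)
  ev_mol <- ev_frame <- list()
  for (m in seq_len(n_molecules)) {
    t0 <- 1L + rgeom(1L, model$activation_rate_per_frame)
    if (t0 > n_frames_total) next
    budget <- if (model$bleach_prob_per_on_frame > 0) {
      1L + rgeom(1L, model$bleach_prob_per_on_frame)
    } else .Machine$integer.max
    on_frames <- integer(0)
    t <- t0
    while (t <= n_frames_total && budget > 0L) {
      dur <- min(1L + rgeom(1L, 1 / model$mean_on_frames), budget)
      fr <- t:min(t + dur - 1L, n_frames_total)
      on_frames <- c(on_frames, fr)
      budget <- budget - dur
      t <- t + dur + 1L + rgeom(1L, 1 / model$mean_off_frames)
    }
    if (length(on_frames)) {
      ev_mol[[length(ev_mol) + 1L]] <- rep.int(m, length(on_frames))
      ev_frame[[length(ev_frame) + 1L]] <- on_frames
    }
  }
  mol <- unlist(ev_mol) %||% integer(0)
  fr <- unlist(ev_frame) %||% integer(0)
  structure(list(
    events = tibble::tibble(
      molecule = mol, frame = fr,
      photons = rpois(length(fr), model$brightness_photons_per_frame)),
    n_molecules = n_molecules, n_frames = n_frames_total, model = model),
    class = "sofi_traces")
}

#' Render a camera image sequence from ground truth and traces
#'
#' Photon rates are splatted onto the camera grid through a pixel-integrated
#' Gaussian PSF; converted photoelectrons are Poisson with mean
#' `rate * detection_efficiency`; raw counts are
#' `em_gain * photoelectrons + offset + N(0, read_noise)`, rounded and
#' clipped to 16 bits, then converted back to photoelectron counts by the
#' linear camera model (as [read_stack()] would). The camera field extends
#' `margin_px` pixels beyond the ground-truth field on every side so that
#' border effects of the cumulant analysis do not clip HDRs near the field
#' edge; the ground-truth origin sits at pixel `(margin_px, margin_px)`
#' (attribute `origin_px`).
#'
#' @param gt a [make_ground_truth()] result.
#' @param traces a [simulate_traces()] result covering `nrow(gt$molecules)`
#'   molecules.
#' @param optics an [acquisition_config()].
#' @param seed RNG seed or NULL.
#' @param detection_efficiency photon-to-photoelectron conversion
#'   efficiency in (0, 1].
#' @param margin_px camera margin around the ground-truth field, in pixels.
#' @return A [sofi_sequence()] of photoelectron counts with attribute
#'   `origin_px`.
#' @export
render_sequence <- function(gt, traces, optics, seed = NULL,
                            detection_efficiency = 0.9, margin_px = 4L) {
  stopifnot(inherits(gt, "sofi_ground_truth"), inherits(traces, "sofi_traces"),
            inherits(optics, "sofi_config"),
            detection_efficiency > 0, detection_efficiency <= 1)
  if (traces$n_molecules < nrow(gt$molecules)) {
    stop("traces cover ", traces$n_molecules, " molecules but ground truth has ",
         nrow(gt$molecules))
  }
  if (!is.null(seed)) set.seed(seed)
  p <- optics$pixel_pitch_nm
  n_fx <- round(gt$field_nm[1L] / p); n_fy <- round(gt$field_nm[2L] / p)
  W <- n_fx + 2L * margin_px; H <- n_fy + 2L * margin_px
  T <- traces$n_frames
  sx <- optics$psf_sigma_nm / p

  mx <- gt$molecules$x_nm / p + margin_px   # 0-based pixel coordinates
  my <- gt$molecules$y_nm / p + margin_px
  R <- ceiling(4 * sx)
  patch <- lapply(seq_along(mx), function(m) {
    jc <- round(mx[m]); ic <- round(my[m])
    js <- max(jc - R, 0L):min(jc + R, W - 1L)
    is <- max(ic - R, 0L):min(ic + R, H - 1L)
    fx <- pnorm((js + 0.5 - mx[m]) / sx) - pnorm((js - 0.5 - mx[m]) / sx)
    fy <- pnorm((is + 0.5 - my[m]) / sx) - pnorm((is - 0.5 - my[m]) / sx)
    list(rows = is + 1L, cols = js + 1L, w = outer(fy, fx))
  })

  rate <- array(0, dim = c(H, W, T))
  ev <- traces$events
  keep <- ev$molecule <= length(patch) & ev$photons > 0
  for (i in which(keep)) {
    pt <- patch[[ev$molecule[i]]]
    rate[pt$rows, pt$cols, ev$frame[i]] <-
      rate[pt$rows, pt$cols, ev$frame[i]] + ev$photons[i] * pt$w
  }
  pe <- array(rpois(length(rate), rate * detection_efficiency), dim = dim(rate))
  raw <- round(optics$em_gain * pe + optics$offset_counts +
                 rnorm(length(pe), 0, optics$read_noise_counts))
  raw <- pmin(pmax(raw, 0), 65535)
  counts <- pmax((raw - optics$offset_counts) / optics$em_gain, 0)
  out <- sofi_sequence(array(counts, dim = c(H, W, T)),
                       pixel_pitch_nm = p, frame_time_s = optics$frame_time_s)
  attr(out, "origin_px") <- margin_px
  out
}

#' Simulate one complete scenario
#'
#' Ground truth, photon traces and camera rendering in one call, with
#' sub-seeds derived from `seed` for each stage.
#'
#' @inheritParams make_ground_truth
#' @inheritParams render_sequence
#' @param n_frames_total frames to simulate.
#' @param model a [photokinetics_model()].
#' @param optics an [acquisition_config()].
#' @return A list with `gt`, `traces`, `seq`.
#' @export
simulate_scenario <- function(diameter_nm, hdr_density_per_um2, contrast,
                              n_hdrs = 10, n_frames_total = 5000,
                              field_um = 3,
                              model = photokinetics_model(),
                              optics = acquisition_config(),
                              detection_efficiency = 0.9,
                              margin_px = 4L, seed = 1L) {
  gt <- make_ground_truth(n_hdrs = n_hdrs, diameter_nm = diameter_nm,
                          hdr_density_per_um2 = hdr_density_per_um2,
                          contrast = contrast, field_um = field_um,
                          seed = seed)
  traces <- simulate_traces(nrow(gt$molecules), n_frames_total, model,
                            seed = seed + 1L)
  seq <- render_sequence(gt, traces, optics, seed = seed + 2L,
                         detection_efficiency = detection_efficiency,
                         margin_px = margin_px)
  list(gt = gt, traces = traces, seq = seq)
}

#' Run a grid of simulation scenarios
#'
#' Generates the Cartesian product of HDR diameters, densities, contrasts
#' and layouts, each replicated with a deterministic per-run seed, and
#' optionally writes every sequence (TIFF), ground truth (CSV) and a
#' manifest CSV to disk.
#'
#' @param diameters_nm,densities_per_um2,contrasts scenario parameter values.
#' @param layouts subset of `c("hdr", "random")`; `"random"` uses
#'   `n_hdrs = 0` (control).
#' @param replicates replicates per scenario (0 gives an empty manifest).
#' @param n_frames_total frames per sequence.
#' @param model,optics simulation models.
#' @param seed base seed; run `i` uses `seed * 10000 + i`.
#' @param out_dir output directory, or NULL to keep results in memory.
#' @param n_hdrs HDRs per clustered scenario.
#' @return A tibble manifest (one row per sequence) with columns
#'   `run`, `layout`, `diameter_nm`, `density_per_um2`, `contrast`,
#'   `replicate`, `seed`, `n_molecules` and (if written) `stack`, `truth`.
#'   When `out_dir` is NULL the generated objects are attached as the
#'   attribute `results`.
#' @export
run_scenarios <- function(diameters_nm = c(60, 120, 180),
                          densities_per_um2 = c(500, 1750, 3000),
                          contrasts = c(20, 50, 100),
                          layouts = c("hdr", "random"),
                          replicates = 1, n_frames_total = 5000,
                          model = photokinetics_model(),
                          optics = acquisition_config(),
                          seed = 1L, out_dir = NULL, n_hdrs = 10) {
  stopifnot(all(layouts %in% c("hdr", "random")), replicates >= 0)
  grid <- expand.grid(replicate = seq_len(replicates), contrast = contrasts,
                      density_per_um2 = densities_per_um2,
                      diameter_nm = diameters_nm, layout = layouts,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(tibble::tibble(run = integer(), layout = character(),
                          diameter_nm = numeric(), density_per_um2 = numeric(),
                          contrast = numeric(), replicate = integer(),
                          seed = integer(), n_molecules = integer()))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    run_seed <- as.integer(seed) * 10000L + i
    sim <- simulate_scenario(
      diameter_nm = g$diameter_nm, hdr_density_per_um2 = g$density_per_um2,
      contrast = g$contrast,
      n_hdrs = if (g$layout == "hdr") n_hdrs else 0L,
      n_frames_total = n_frames_total, model = model, optics = optics,
      seed = run_seed)
    row <- tibble::tibble(run = i, layout = g$layout,
                          diameter_nm = g$diameter_nm,
                          density_per_um2 = g$density_per_um2,
                          contrast = g$contrast, replicate = g$replicate,
                          seed = run_seed,
                          n_molecules = nrow(sim$gt$molecules))
    if (!is.null(out_dir)) {
      stack <- file.path(out_dir, sprintf("run%03d_stack.tif", i))
      truth <- file.path(out_dir, sprintf("run%03d_truth.csv", i))
      write_stack(sim$seq, stack, optics)
      write.csv(sim$gt$molecules, truth, row.names = FALSE)
      row$stack <- stack; row$truth <- truth
    } else {
      results[[i]] <- sim
    }
    rows[[i]] <- row
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  } else {
    attr(manifest, "results") <- results
  }
  manifest
}
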