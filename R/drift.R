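#' Track fiducial beads through a sequence
#'
#' Fiducial markers (e.g. gold beads) are separated from blinking
#' fluorophores by temporal persistence, not brightness alone: a candidate
#' is a local maximum of the early-sequence average image that stays
#' brighter than `min_brightness` in at least `persistence` of all frames.
#' Each candidate is tracked frame by frame — the peak is re-located within
#' `search_px` of its previous position and refined to sub-pixel precision
#' by the intensity centroid of a 7x7 window (local baseline subtracted).
#'
#' @param seq a [sofi_sequence()].
#' @param min_brightness minimum peak brightness, in photoelectron counts.
#' @param persistence required fraction of frames above `min_brightness`.
#' @param search_px frame-to-frame search radius in pixels.
#' @return A list of `sofi_fiducial_track` objects, each with `positions`
#'   (a `T x 2` matrix of `(x, y)` 0-based pixel coordinates) and
#'   `intensity` (per-frame peak counts).
#' @export
track_fiducials <- function(seq, min_brightness, persistence = 0.95,
                            search_px = 3L) {
  stopifnot(is_sofi_sequence(seq), min_brightness > 0)
  d <- dim(seq); H <- d[1L]; W <- d[2L]; T <- d[3L]
  A <- unclass(seq)
  ref <- rowMeans(A[, , seq_len(min(50L, T)), drop = FALSE], dims = 2L)

  # local maxima of the reference image above threshold, best-first,
  # suppressing secondary maxima within 5 px
  cand <- which(ref >= min_brightness)
  cand <- cand[order(ref[cand], decreasing = TRUE)]
  peaks <- matrix(numeric(0), 0L, 2L)
  for (ix in cand) {
    r <- (ix - 1L) %% H + 1L; c <- (ix - 1L) %/% H + 1L
    win <- ref[max(r - 1L, 1L):min(r + 1L, H), max(c - 1L, 1L):min(c + 1L, W)]
    if (ref[r, c] < max(win)) next
    if (nrow(peaks) && any((peaks[, 1L] - r)^2 + (peaks[, 2L] - c)^2 < 25)) next
    peaks <- rbind(peaks, c(r, c))
  }
  if (nrow(peaks) == 0L) {
    stop("no fiducial candidate found; skip drift correction for this sequence")
  }

  centroid7 <- function(img, r, c) {
    rs <- max(r - 3L, 1L):min(r + 3L, nrow(img))
    cs <- max(c - 3L, 1L):min(c + 3L, ncol(img))
    w <- img[rs, cs, drop = FALSE]
    w <- w - min(w)
    s <- sum(w)
    if (s <= 0) return(c(x = c - 1, y = r - 1, peak = img[r, c]))
    c(x = sum(colSums(w) * (cs - 1L)) / s,
      y = sum(rowSums(w) * (rs - 1L)) / s,
      peak = max(img[rs, cs]))
  }

  tracks <- list()
  for (k in seq_len(nrow(peaks))) {
    pos <- matrix(NA_real_, T, 2L, dimnames = list(NULL, c("x", "y")))
    inten <- numeric(T)
    r <- peaks[k, 1L]; c <- peaks[k, 2L]
    for (t in seq_len(T)) {
      img <- A[, , t]
      rs <- max(r - search_px, 1L):min(r + search_px, H)
      cs <- max(c - search_px, 1L):min(c + search_px, W)
      w <- img[rs, cs, drop = FALSE]
      im <- arrayInd(which.max(w), dim(w))
      r <- rs[im[1L]]; c <- cs[im[2L]]
      cc <- centroid7(img, r, c)
      pos[t, ] <- cc[c("x", "y")]
      inten[t] <- cc[["peak"]]
      r <- round(cc[["y"]]) + 1L; c <- round(cc[["x"]]) + 1L
      r <- min(max(r, 1L), H); c <- min(max(c, 1L), W)
    }
    if (mean(inten >= min_brightness) >= persistence) {
      tracks[[length(tracks) + 1L]] <- structure(
        list(positions = pos, intensity = inten),
        class = "sofi_fiducial_track")
    }
  }
  if (length(tracks) == 0L) {
    stop("no persistent fiducial found (bright in >= ",
         round(100 * persistence),
         "% of frames); skip drift correction for this sequence")
  }
  tracks
}

# centered moving average whose window shrinks symmetrically near the
# boundaries; symmetric windows keep the average exact for linear trends,
# so slow drift is not distorted at the sequence ends
.smooth_moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  h <- pmin((window - 1L) %/% 2L, seq_len(n) - 1L, n - seq_len(n))
  cs <- cumsum(c(0, x))
  (cs[seq_len(n) + h + 1L] - cs[seq_len(n) - h]) / (2L * h + 1L)
}

#' Estimate the drift trace from fiducial tracks
#'
#' The per-frame displacement is the mean over tracks of each track's
#' position relative to its first frame, smoothed by a centered moving
#' average (window shrinking symmetrically at the boundaries) to suppress
#' localization jitter without distorting slow mechanical drift; frame 1 is
#' re-anchored at zero displacement.
#'
#' @param tracks list of tracks from [track_fiducials()].
#' @param smooth_window moving-average window in frames.
#' @return An object of class `sofi_drift`: a `T x 2` matrix of `(dx, dy)`
#'   displacements in pixels relative to frame 1.
#' @export
estimate_drift <- function(tracks, smooth_window = 51L) {
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, inherits, TRUE, "sofi_fiducial_track")))
  lens <- vapply(tracks, function(tr) nrow(tr$positions), 1L)
  if (length(unique(lens)) != 1L) {
    stop("fiducial tracks have unequal lengths: ",
         paste(lens, collapse = ", "))
  }
  rel <- lapply(tracks, function(tr) {
    sweep(tr$positions, 2L, tr$positions[1L, ])
  })
  disp <- Reduce(`+`, rel) / length(rel)
  disp[, 1L] <- .smooth_moving_average(disp[, 1L], smooth_window)
  disp[, 2L] <- .smooth_moving_average(disp[, 2L], smooth_window)
  disp <- sweep(disp, 2L, disp[1L, ])
  dimnames(disp) <- list(NULL, c("dx", "dy"))
  structure(disp, class = c("sofi_drift", "matrix"))
}

#' Register a sequence against its drift trace
#'
#' Translates every frame by the negative of its displacement using
#' bilinear interpolation (sub-pixel registration); pixels shifted in from
#' outside the field are set to 0.
#'
#' @param seq a [sofi_sequence()].
#' @param drift a [estimate_drift()] trace of the same length.
#' @return The registered [sofi_sequence()].
#' @export
apply_drift_correction <- function(seq, drift) {
  stopifnot(is_sofi_sequence(seq))
  if (nrow(drift) != n_frames(seq)) {
    stop("drift trace has ", nrow(drift), " frames but sequence has ",
         n_frames(seq))
  }
  A <- unclass(seq)
  out <- A
  for (t in seq_len(dim(A)[3L])) {
    if (drift[t, 1L] == 0 && drift[t, 2L] == 0) next
    out[, , t] <- EBImage::translate(
      A[, , t], c(-drift[t, "dy"], -drift[t, "dx"]),
      filter = "bilinear", bg.col = 0)
  }
  seq_like(seq, pmax(out, 0))
}
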