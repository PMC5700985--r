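#' Image sequence container
#'
#' An image sequence is a `H x W x T` numeric array of photoelectron counts
#' with the sample-plane pixel pitch and the frame time attached. The first
#' array dimension is the image row (y), the second the column (x); pixel
#' centers sit at integer coordinates starting at 0, so the physical position
#' of pixel `(i, j)` (0-based) is `(x, y) = (j, i) * pixel_pitch_nm` from the
#' top-left pixel center.
#'
#' @param frames a `H x W x T` numeric array, a single matrix, or a list of
#'   equally sized matrices (one per frame).
#' @param pixel_pitch_nm sample-plane pixel pitch in nm (> 0).
#' @param frame_time_s exposure time per frame in seconds (> 0).
#' @return An object of class `sofi_sequence`.
#' @export
sofi_sequence <- function(frames, pixel_pitch_nm, frame_time_s = 0.032) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) {
      stop("all frames must share the same height and width; got shapes: ",
           paste(vapply(dims, paste, "", collapse = "x"), collapse = ", "))
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1L]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3L] >= 1L)
  if (!is.numeric(pixel_pitch_nm) || pixel_pitch_nm <= 0) {
    stop("pixel_pitch_nm must be a positive number")
  }
  if (any(frames < 0)) stop("photoelectron counts must be non-negative")
  structure(frames,
            pixel_pitch_nm = as.numeric(pixel_pitch_nm),
            frame_time_s = as.numeric(frame_time_s),
            class = c("sofi_sequence", "array"))
}

#' @export
print.sofi_sequence <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<sofi_sequence> %d frames of %d x %d px (pitch %.4g nm, %.4g s/frame)\n",
    d[3L], d[1L], d[2L], attr(x, "pixel_pitch_nm"), attr(x, "frame_time_s")))
  invisible(x)
}

#' @rdname sofi_sequence
#' @param x object to test or query.
#' @export
is_sofi_sequence <- function(x) inherits(x, "sofi_sequence")

#' @rdname sofi_sequence
#' @export
n_frames <- function(x) dim(x)[3L]

#' @rdname sofi_sequence
#' @export
pixel_pitch <- function(x) attr(x, "pixel_pitch_nm")

# rebuild a sequence from a raw array, copying metadata from a template
seq_like <- function(template, frames) {
  sofi_sequence(frames,
                pixel_pitch_nm = attr(template, "pixel_pitch_nm"),
                frame_time_s = attr(template, "frame_time_s"))
}

#' Acquisition configuration
#'
#' Describes the camera and optics used to acquire (or simulate) a sequence:
#' pixel pitch, EM gain, camera offset, read noise and the Gaussian PSF width.
#'
#' @param pixel_pitch_nm sample-plane pixel pitch in nm.
#' @param em_gain electron-multiplying gain (counts per photoelectron).
#' @param offset_counts camera baseline offset in counts (>= 0).
#' @param read_noise_counts standard deviation of the additive Gaussian read
#'   noise, in counts.
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm.
#' @param frame_time_s exposure time per frame in seconds.
#' @return A list of class `sofi_config`.
#' @export
acquisition_config <- function(pixel_pitch_nm = 105, em_gain = 300,
                               offset_counts = 100, read_noise_counts = 10,
                               psf_sigma_nm = 130, frame_time_s = 0.032) {
  cfg <- list(pixel_pitch_nm = pixel_pitch_nm, em_gain = em_gain,
              offset_counts = offset_counts,
              read_noise_counts = read_noise_counts,
              psf_sigma_nm = psf_sigma_nm, frame_time_s = frame_time_s)
  for (f in names(cfg)) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a single finite number")
    }
  }
  if (cfg$offset_counts < 0) stop("offset_counts must be >= 0")
  pos <- setdiff(names(cfg), "offset_counts")
  bad <- pos[vapply(cfg[pos], function(v) v <= 0, TRUE)]
  if (length(bad)) stop("config fields must be positive: ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "sofi_config")
}

#' Read or write an acquisition config file
#'
#' Configs are stored as flat YAML key-value files whose keys mirror the
#' [acquisition_config()] argument names.
#'
#' @param path file path.
#' @return [read_acquisition_config()] returns a `sofi_config`;
#'   [write_acquisition_config()] returns `path` invisibly.
#' @export
read_acquisition_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(acquisition_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(acquisition_config, vals)
}

#' @rdname read_acquisition_config
#' @param config a `sofi_config`.
#' @export
write_acquisition_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a multi-frame TIFF stack as photoelectron counts
#'
#' Reads a grayscale multi-page TIFF of raw camera counts and converts it to
#' photoelectrons by the linear camera model
#' `(raw - offset_counts) / em_gain`, clipped at zero. EMCCD excess noise is
#' not inverted; the conversion is purely linear.
#'
#' @param path path to a multi-frame TIFF file.
#' @param config an [acquisition_config()].
#' @return A [sofi_sequence()] with one frame per TIFF page.
#' @export
read_stack <- function(path, config) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  stopifnot(inherits(config, "sofi_config"))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("no pages in TIFF: ", path)
  if (any(!vapply(pages, is.matrix, TRUE))) {
    stop("expected single-channel grayscale pages in ", path)
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) {
    stop("TIFF pages differ in shape (",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "),
         "): ", path)
  }
  counts <- lapply(pages, function(p) {
    pmax((p - config$offset_counts) / config$em_gain, 0)
  })
  sofi_sequence(counts, pixel_pitch_nm = config$pixel_pitch_nm,
                frame_time_s = config$frame_time_s)
}

#' Write a sequence to a 16-bit multi-frame TIFF
#'
#' Inverse of [read_stack()]: photoelectron counts are converted back to raw
#' camera counts (`counts * em_gain + offset_counts`), rounded and clipped to
#' the 16-bit range.
#'
#' @inheritParams read_stack
#' @param seq a [sofi_sequence()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(seq, path, config) {
  stopifnot(is_sofi_sequence(seq), inherits(config, "sofi_config"))
  pages <- lapply(seq_len(n_frames(seq)), function(t) {
    raw <- round(seq[, , t] * config$em_gain + config$offset_counts)
    pmin(pmax(raw, 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Crop a square region of interest from a sequence
#'
#' The ROI is specified in physical units (micrometres from the top-left
#' pixel center) and converted to whole pixels: the side length in pixels is
#' `round(side_um * 1000 / pixel_pitch_nm)`.
#'
#' @param seq a [sofi_sequence()].
#' @param center_um ROI center as `c(x, y)` in micrometres.
#' @param side_um ROI side length in micrometres.
#' @return The cropped [sofi_sequence()]; pixel pitch and frame time are
#'   preserved.
#' @export
select_roi <- function(seq, center_um, side_um) {
  stopifnot(is_sofi_sequence(seq), length(center_um) == 2L, side_um > 0)
  pitch <- pixel_pitch(seq)
  side_px <- round(side_um * 1000 / pitch)
  if (side_px < 1L) stop("ROI smaller than one pixel")
  center_px <- center_um * 1000 / pitch             # (x, y), 0-based
  x0 <- round(center_px[1L] - (side_px - 1) / 2)
  y0 <- round(center_px[2L] - (side_px - 1) / 2)
  d <- dim(seq)
  if (x0 < 0 || y0 < 0 || x0 + side_px > d[2L] || y0 + side_px > d[1L]) {
    stop(sprintf(
      "ROI of %d px at (%.4g, %.4g) um exceeds the %d x %d px field",
      side_px, center_um[1L], center_um[2L], d[2L], d[1L]))
  }
  seq_like(seq, unclass(seq)[y0 + seq_len(side_px), x0 + seq_len(side_px), ,
                             drop = FALSE])
}
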