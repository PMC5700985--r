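#' Split a sequence into consecutive blocks
#'
#' Long acquisitions are analyzed in consecutive, non-overlapping
#' sub-sequences (default 500 frames) so that slow photobleaching within a
#' block stays negligible; cumulant images are computed per block and
#' averaged afterwards ([aggregate_blocks()]). A trailing remainder shorter
#' than `block_len` is discarded.
#'
#' @param seq a [sofi_sequence()].
#' @param block_len frames per block.
#' @return A list of `floor(T / block_len)` sequences of `block_len` frames.
#' @export
split_blocks <- function(seq, block_len = 500) {
  stopifnot(is_sofi_sequence(seq), block_len >= 1)
  T <- n_frames(seq)
  if (T < block_len) {
    stop("sequence has ", T, " frames, fewer than block_len = ", block_len)
  }
  n_blocks <- T %/% block_len
  lapply(seq_len(n_blocks), function(b) {
    idx <- (b - 1L) * block_len + seq_len(block_len)
    seq_like(seq, unclass(seq)[, , idx, drop = FALSE])
  })
}

# ---------------------------------------------------------------------------
# Virtual-pixel combinations
#
# An order-n cross-cumulant image lives on a grid n-times finer than the
# camera grid. Each virtual node is assigned the joint cumulant of n camera
# pixels whose centroid coincides with the node. Per sub-pixel offset class
# (a/n, b/n) we pick one combination of n integer pixel offsets summing to
# (a, b): all-distinct combinations are preferred (temporal shot noise is
# uncorrelated across distinct pixels, so it cancels from cross-cumulants)
# and, within that preference, the combination with the smallest summed
# squared distance to the node. Candidates are restricted to a radius of
# 2*sigma around the node to bound the noise amplification of the distance
# factor; a floor of 1.6 px keeps every offset class feasible for small PSFs.

.combo_cache <- new.env(parent = emptyenv())

# non-decreasing index tuples of length n from 1..K (multisets)
.multiset_indices <- function(K, n) {
  g <- as.matrix(do.call(expand.grid, rep(list(seq_len(K)), n)))
  if (n > 1L) {
    keep <- rep(TRUE, nrow(g))
    for (k in seq_len(n - 1L)) keep <- keep & g[, k] <= g[, k + 1L]
    g <- g[keep, , drop = FALSE]
  }
  g
}

#' Pixel combinations for an order-n virtual grid
#'
#' Returns, for every sub-pixel offset class of the order-`order` virtual
#' grid, the chosen camera-pixel combination, its Gaussian distance factor
#' and whether it had to repeat a pixel.
#'
#' @param order cumulant order (2, 3 or 4).
#' @param sigma_px Gaussian PSF standard deviation in camera pixels.
#' @return A list with one element per offset class `(a, b)`,
#'   `a, b in 0..order-1`, each holding `offsets` (an `order x 2` integer
#'   matrix of `(dy, dx)` pixel offsets), `weight` (the distance factor),
#'   `distinct` (logical) and `class_offset`.
#' @keywords internal
#' @export
pixel_combinations <- function(order, sigma_px) {
  stopifnot(order %in% 2:4, sigma_px > 0)
  key <- sprintf("%d|%.8g", order, sigma_px)
  if (!is.null(.combo_cache[[key]])) return(.combo_cache[[key]])
  radius <- max(2 * sigma_px, 1.6)
  span <- ceiling(radius) + 1L
  cand_all <- as.matrix(expand.grid(dy = -span:span, dx = -span:span))
  out <- list()
  for (a in 0:(order - 1L)) {
    for (b in 0:(order - 1L)) {
      o <- c(a, b) / order
      d2 <- (cand_all[, 1L] - o[1L])^2 + (cand_all[, 2L] - o[2L])^2
      cand <- cand_all[d2 <= radius^2, , drop = FALSE]
      cd2 <- d2[d2 <= radius^2]
      idx <- .multiset_indices(nrow(cand), order)
      sy <- matrix(cand[idx, 1L], nrow(idx)); sx <- matrix(cand[idx, 2L], nrow(idx))
      feas <- rowSums(sy) == a & rowSums(sx) == b
      idx <- idx[feas, , drop = FALSE]
      if (nrow(idx) == 0L) {
        stop("no feasible pixel combination for order ", order,
             " offset (", a, ",", b, ") within radius ", signif(radius, 3))
      }
      distinct <- apply(idx, 1L, function(r) !anyDuplicated(r))
      if (any(distinct)) idx <- idx[distinct, , drop = FALSE]
      score <- rowSums(matrix(cd2[idx], nrow(idx)))
      best <- which(score == min(score))
      if (length(best) > 1L) {
        # deterministic tie-break: lexicographic on the flattened offsets
        keys <- apply(idx[best, , drop = FALSE], 1L, paste, collapse = ",")
        best <- best[order(keys)][1L]
      }
      offs <- cand[idx[best[1L], ], , drop = FALSE]
      out[[sprintf("%d_%d", a, b)]] <- list(
        class_offset = o,
        offsets = offs,
        weight = exp(-min(score) / (2 * sigma_px^2)),
        distinct = !anyDuplicated(offs %*% c(1000L, 1L)))
    }
  }
  .combo_cache[[key]] <- out
  out
}

# ---------------------------------------------------------------------------

#' Order-n spatio-temporal cross-cumulant image of one block
#'
#' Computes the zero-time-lag joint cumulant of the mean-subtracted pixel
#' traces for every node of the order-`order` virtual grid (pitch =
#' camera pitch / `order`) and divides it by the Gaussian distance factor
#' `exp(-sum_i |r_i - c|^2 / (2 sigma^2))` that accounts for the PSF
#' attenuation of pixels away from the node. Joint cumulants used:
#' order 2 `E[X1 X2]`, order 3 `E[X1 X2 X3]`, order 4
#' `E[X1 X2 X3 X4] - E[X1 X2]E[X3 X4] - E[X1 X3]E[X2 X4] - E[X1 X4]E[X2 X3]`.
#'
#' Nodes too close to the field border for their pixel combination are set
#' to 0.
#'
#' @param block a [sofi_sequence()] with at least two frames.
#' @param order cumulant order, one of 2, 3, 4.
#' @param psf_sigma_nm Gaussian PSF standard deviation in nm.
#' @return A numeric matrix of size `(order*(H-1)+1) x (order*(W-1)+1)` with
#'   attributes `grid_pitch_nm`, `order` and `repeats_used`.
#' @export
cross_cumulant_image <- function(block, order, psf_sigma_nm) {
  stopifnot(is_sofi_sequence(block))
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  if (psf_sigma_nm <= 0) stop("psf_sigma_nm must be positive")
  if (n_frames(block) < 2L) stop("block needs at least 2 frames")
  pitch <- pixel_pitch(block)
  sigma_px <- psf_sigma_nm / pitch
  combos <- pixel_combinations(order, sigma_px)

  d <- dim(block); H <- d[1L]; W <- d[2L]
  A <- unclass(block)
  A <- A - as.vector(rowMeans(A, dims = 2L))   # per-pixel temporal mean removal
  G <- matrix(0, order * (H - 1L) + 1L, order * (W - 1L) + 1L)

  shifted <- function(Q, k, ib, jb) {
    A[ib + Q[k, 1L], jb + Q[k, 2L], , drop = FALSE]
  }
  for (cl in combos) {
    Q <- cl$offsets
    ib <- (1L - min(Q[, 1L])):(H - max(Q[, 1L]))
    jb <- (1L - min(Q[, 2L])):(W - max(Q[, 2L]))
    if (length(ib) < 1L || length(jb) < 1L || ib[1L] > ib[length(ib)] ||
        jb[1L] > jb[length(jb)]) next
    S <- lapply(seq_len(order), function(k) shifted(Q, k, ib, jb))
    P <- S[[1L]]
    for (k in seq_len(order)[-1L]) P <- P * S[[k]]
    val <- rowMeans(P, dims = 2L)
    if (order == 4L) {
      e <- function(i, j) rowMeans(S[[i]] * S[[j]], dims = 2L)
      val <- val - e(1, 2) * e(3, 4) - e(1, 3) * e(2, 4) - e(1, 4) * e(2, 3)
    }
    a <- cl$class_offset[1L] * order; b <- cl$class_offset[2L] * order
    G[order * (ib - 1L) + a + 1L, order * (jb - 1L) + b + 1L] <-
      val / cl$weight
  }
  structure(G, grid_pitch_nm = pitch / order, order = order,
            repeats_used = any(!vapply(combos, `[[`, TRUE, "distinct")))
}

# bilinear resampling of an order-n virtual grid onto the 4x grid,
# both expressed in camera-pixel coordinates over the same extent
.resample_to_4x <- function(mat, src_factor, H_cam, W_cam) {
  if (src_factor == 4L) return(mat)
  interp1 <- function(n_cam, sf) {
    u <- (seq_len(4L * (n_cam - 1L) + 1L) - 1L) / 4L   # camera units
    s <- u * sf + 1                                    # fractional src index
    lo <- pmin(floor(s), sf * (n_cam - 1L))            # keep hi in range
    list(lo = as.integer(lo), w = s - lo)
  }
  ry <- interp1(H_cam, src_factor); rx <- interp1(W_cam, src_factor)
  My <- mat[ry$lo, , drop = FALSE] * (1 - ry$w) +
    mat[ry$lo + 1L, , drop = FALSE] * ry$w
  My[, rx$lo, drop = FALSE] * rep(1 - rx$w, each = nrow(My)) +
    My[, rx$lo + 1L, drop = FALSE] * rep(rx$w, each = nrow(My))
}

#' Average per-block cumulant images and assemble a cumulant set
#'
#' Cumulant images computed per block are averaged arithmetically across
#' blocks; 2nd- and 3rd-order images are then resampled from their native
#' 2x/3x virtual grids onto the common 4x grid by bilinear interpolation.
#' Negative values of the averaged 2nd-order image are estimation noise
#' (a second-order cumulant of a real signal is a variance) and are clamped
#' to 0; 3rd and 4th order keep their sign, which carries blinking
#' information.
#'
#' @param per_block a named list with elements `g2`, `g3`, `g4` (any subset),
#'   each a list of per-block rasters from [cross_cumulant_image()].
#' @return An object of class `sofi_cumulants` with fields `g2`, `g3`, `g4`
#'   (matrices on the 4x grid), `grid_pitch_nm`, `camera_pitch_nm`,
#'   `n_blocks` and `block_len`.
#' @export
aggregate_blocks <- function(per_block) {
  orders_present <- intersect(c("g2", "g3", "g4"), names(per_block))
  if (length(orders_present) == 0L) stop("per_block must contain g2/g3/g4")
  n_blocks <- unique(vapply(per_block[orders_present], length, 1L))
  if (length(n_blocks) != 1L || n_blocks < 1L) {
    stop("every order needs the same, positive number of blocks")
  }
  out <- list()
  g2_se <- NULL
  cam_pitch <- NULL; H_cam <- NULL
  for (gn in orders_present) {
    rasters <- per_block[[gn]]
    ord <- as.integer(sub("g", "", gn))
    dims <- unique(lapply(rasters, dim))
    if (length(dims) != 1L) stop("per-block rasters of ", gn, " differ in shape")
    gp <- attr(rasters[[1L]], "grid_pitch_nm")
    Hc <- (nrow(rasters[[1L]]) - 1L) %/% ord + 1L
    Wc <- (ncol(rasters[[1L]]) - 1L) %/% ord + 1L
    if (is.null(H_cam)) { H_cam <- Hc; W_cam <- Wc } else {
      if (Hc != H_cam || Wc != W_cam) stop("orders cover different camera areas")
    }
    if (!is.null(gp)) cam_pitch <- gp * ord
    res <- lapply(rasters, function(r) .resample_to_4x(unclass(r), ord, Hc, Wc))
    m <- Reduce(`+`, res) / n_blocks
    out[[gn]] <- m
    if (gn == "g2" && n_blocks > 1L) {
      # block-to-block scatter -> standard error of the averaged g2
      v <- Reduce(`+`, lapply(res, function(r) (r - m)^2)) / (n_blocks - 1L)
      g2_se <- sqrt(v / n_blocks)
    }
  }
  if (!is.null(out$g2)) out$g2 <- pmax(out$g2, 0)
  structure(list(g2 = out$g2, g3 = out$g3, g4 = out$g4, g2_se = g2_se,
                 grid_pitch_nm = if (!is.null(cam_pitch)) cam_pitch / 4,
                 camera_pitch_nm = cam_pitch,
                 n_blocks = n_blocks,
                 block_len = attr(per_block, "block_len")),
            class = "sofi_cumulants")
}

#' @export
print.sofi_cumulants <- function(x, ...) {
  present <- c("g2", "g3", "g4")[!vapply(x[c("g2", "g3", "g4")], is.null, TRUE)]
  cat(sprintf("<sofi_cumulants> %s on %d x %d grid (pitch %.4g nm), %d block(s)\n",
              paste(present, collapse = "/"),
              nrow(x[[present[1L]]]), ncol(x[[present[1L]]]),
              x$grid_pitch_nm, x$n_blocks))
  invisible(x)
}

#' Compute block-averaged cumulant images of a sequence
#'
#' Convenience wrapper: [split_blocks()], [cross_cumulant_image()] per block
#' and order, then [aggregate_blocks()].
#'
#' @inheritParams split_blocks
#' @inheritParams cross_cumulant_image
#' @param orders cumulant orders to compute (subset of 2:4).
#' @return A `sofi_cumulants` object (see [aggregate_blocks()]).
#' @export
compute_cumulants <- function(seq, psf_sigma_nm, block_len = 500,
                              orders = 2:4) {
  stopifnot(all(orders %in% 2:4))
  blocks <- split_blocks(seq, block_len)
  per_block <- lapply(orders, function(ord) {
    lapply(blocks, cross_cumulant_image, order = ord,
           psf_sigma_nm = psf_sigma_nm)
  })
  names(per_block) <- paste0("g", orders)
  attr(per_block, "block_len") <- block_len
  aggregate_blocks(per_block)
}

#' Linearize a cumulant image (bSOFI brightness image)
#'
#' An order-n cumulant scales with the n-th power of the molecular
#' brightness; taking the n-th root of its magnitude restores a linear
#' brightness response. The linearized 2nd-order image is used as the
#' background transparency mask of the density analysis.
#'
#' @param cumulant a cumulant raster (matrix).
#' @param order the cumulant order it was computed at.
#' @return An object of class `sofi_bsofi` with fields `values` (matrix,
#'   all values >= 0), `order_used` and `grid_pitch_nm`.
#' @export
linearize_cumulant <- function(cumulant, order) {
  if (!order %in% 2:4) stop("order must be 2, 3 or 4")
  structure(list(values = abs(unclass(cumulant))^(1 / order),
                 order_used = as.integer(order),
                 grid_pitch_nm = attr(cumulant, "grid_pitch_nm")),
            class = "sofi_bsofi")
}

#' Temporal sample cumulants of a trace
#'
#' Sample estimates of the 2nd- to 4th-order cumulants of a single time
#' trace at zero time lag, after subtraction of the sample mean:
#' `k2 = E[x^2]`, `k3 = E[x^3]`, `k4 = E[x^4] - 3 E[x^2]^2`.
#'
#' @param x numeric vector (the trace).
#' @param orders which cumulant orders to return (subset of 2:4).
#' @return Named numeric vector (`k2`, `k3`, `k4`).
#' @export
sample_cumulants <- function(x, orders = 2:4) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(orders %in% 2:4))
  x <- x - mean(x)
  m2 <- mean(x^2)
  vals <- c(k2 = m2, k3 = mean(x^3), k4 = mean(x^4) - 3 * m2^2)
  vals[paste0("k", orders)]
}

#' Theoretical cumulants of a Bernoulli blinking process
#'
#' Cumulants of a two-state emitter that is on with probability `rho`:
#' `k2 = rho(1-rho)`, `k3 = rho(1-rho)(1-2 rho)`,
#' `k4 = rho(1-rho)(1 - 6 rho + 6 rho^2)`. A molecule of brightness
#' `epsilon` contributes `epsilon^n * kn` to the order-n cumulant.
#'
#' @param rho on-time ratio in (0, 1).
#' @return Named numeric vector `c(k2, k3, k4)`.
#' @export
bernoulli_cumulants <- function(rho) {
  stopifnot(rho > 0, rho < 1)
  c(k2 = rho * (1 - rho),
    k3 = rho * (1 - rho) * (1 - 2 * rho),
    k4 = rho * (1 - rho) * (1 - 6 * rho + 6 * rho^2))
}
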