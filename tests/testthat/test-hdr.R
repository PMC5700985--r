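test_that("component labeling is 8-connected", {
  fg <- matrix(FALSE, 5, 5)
  fg[2, 2] <- fg[3, 3] <- TRUE        # diagonal touch: one component
  lab <- label_components(fg)
  expect_equal(max(lab), 1L)
  fg[5, 5] <- TRUE
  expect_equal(max(label_components(fg)), 2L)
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0L)
})

test_that("segmentation reports areas, equivalent diameters and centroids", {
  N <- matrix(1, 10, 10)
  N[2:3, 2:3] <- 5; N[7:8, 6:7] <- 5
  map <- manual_density_map(N, delta_avg = 1, grid_pitch_nm = 26.25)
  regs <- segment_hdrs(map, 4)
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$area_px, c(4L, 4L))
  expect_equal(regs$equiv_diameter_nm,
               rep(2 * sqrt(4 / pi) * 26.25, 2), tolerance = 1e-12)
  expect_equal(sort(regs$centroid_x_nm), c(1.5, 5.5) * 26.25)
  expect_equal(regs$mean_density, c(5, 5))

  # a threshold above the maximum yields no region; zero yields the mask
  expect_equal(nrow(segment_hdrs(map, 10)), 0L)
  all_mask <- segment_hdrs(map, 0)
  expect_equal(nrow(all_mask), 1L)
  expect_equal(all_mask$area_px, 100L)
})

test_that("the toy sweep matches direct enumeration", {
  N <- matrix(1, 8, 8)
  N[2:3, 2:3] <- 5; N[6:7, 5:6] <- 5
  map <- manual_density_map(N, grid_pitch_nm = 25)
  expect_equal(map$delta_avg, 1.5)
  sw <- sweep_thresholds(map, step = 0.1)
  tab <- sw$table
  at <- function(t) tab[which(abs(tab$threshold - t) < 1e-9), ]
  expect_equal(at(2)$n_regions, 2L)
  expect_equal(at(2)$relative_area, 8 / 64)
  expect_equal(nrow(segment_hdrs(map, 4)), 0L)
  # relative threshold 1 is absolute 1.5: everything below the blocks is gone
  expect_equal(at(1)$relative_area, 8 / 64)
})

test_that("a constant map keeps one region up to its own mean density", {
  map <- manual_density_map(matrix(2, 6, 6))
  sw <- sweep_thresholds(map, step = 0.25)
  expect_equal(max(sw$table$threshold), 1)
  expect_true(all(sw$table$n_regions == 1L))
  expect_equal(nrow(segment_hdrs(map, 1.01)), 0L)
})

test_that("sweep bookkeeping: area identity and monotone coverage", {
  set.seed(30)
  map <- manual_density_map(gaussian_smooth(matrix(rexp(900), 30, 30), 1.5))
  sw <- sweep_thresholds(map)
  tab <- sw$table
  expect_true(all(diff(tab$relative_area) <= 1e-12))
  for (i in seq_len(nrow(tab))) {
    expect_equal(sum(sw$regions[[i]]$area_px),
                 tab$relative_area[i] * sw$roi_area_px)
  }
})

test_that("threshold selection inverts an exact Gaussian count curve", {
  t <- seq(0, 5, by = 0.1)
  sw <- manual_sweep(t, 50 * exp(-(t - 1)^2 / (2 * 0.5^2)))
  thr <- select_optimal_threshold(sw)
  t_star <- 1 + 0.5 * sqrt(2 * log(50))
  expect_equal(attr(thr, "continuous"), t_star, tolerance = 1e-6)
  expect_lt(abs(as.numeric(thr) - t_star), 0.1 + 1e-9)  # one grid step
  fit <- attr(thr, "fit")
  expect_equal(unname(fit), c(50, 1, 0.5), tolerance = 1e-6)
})

test_that("curves that never exceed one region return the fitted center", {
  t <- seq(0, 5, by = 0.1)
  thr <- select_optimal_threshold(manual_sweep(t, 0.5 * exp(-(t - 1)^2 / 0.5)))
  expect_equal(attr(thr, "continuous"), 1, tolerance = 1e-4)
})

test_that("degenerate count curves are rejected with a diagnostic", {
  t <- seq(0, 3, by = 0.1)
  expect_error(select_optimal_threshold(manual_sweep(t, rep(0, length(t)))),
               "degenerate")
  expect_error(select_optimal_threshold(manual_sweep(t, seq_along(t))),
               "interior maximum")
  expect_error(select_optimal_threshold(data.frame(x = 1)), "sofi_sweep")
})

test_that("group summaries report box-plot statistics", {
  mk <- function(n) manual_sweep(seq(0, 3, by = 0.5), c(9, 8, 7, 6, n, 1, 0))
  sweeps <- lapply(c(1, 2, 3, 4, 5), mk)
  s <- summarize_hdr_groups(sweeps, rep("A", 5), at = 2)
  row <- s[s$metric == "n_regions", ]
  expect_equal(row$median, 3)
  expect_equal(c(row$iqr_low, row$iqr_high), c(2, 4))
  expect_equal(c(row$min, row$max), c(1, 5))
  expect_equal(row$n_samples, 5L)

  one <- summarize_hdr_groups(sweeps[3], "A", at = 2)
  r1 <- one[one$metric == "n_regions", ]
  expect_equal(c(r1$median, r1$iqr_high - r1$iqr_low), c(3, 0))

  two <- summarize_hdr_groups(c(lapply(1:2, mk), lapply(8:9, mk)),
                              c("lo", "lo", "hi", "hi"), at = 2)
  med <- tapply(two$median[two$metric == "n_regions"],
                two$group[two$metric == "n_regions"], identity)
  expect_gt(med[["hi"]], med[["lo"]])
})

test_that("regions nest and coverage shrinks over random maps", {
  set.seed(31)
  violations <- 0L
  for (rep in 1:100) {
    N <- gaussian_smooth(matrix(rexp(40 * 40), 40, 40), runif(1, 0.8, 2.5))
    mask <- matrix(TRUE, 40, 40)
    if (rep %% 3 == 0) mask[1:10, 1:40] <- FALSE
    map <- manual_density_map(N, mask = mask)
    sw <- sweep_thresholds(map, step = 0.4)
    tab <- sw$table
    if (any(diff(tab$relative_area) > 1e-12)) violations <- violations + 1L
    rel <- N / map$delta_avg
    for (i in seq_len(nrow(tab) - 1L)) {
      lab_lo <- label_components(mask & rel >= tab$threshold[i])
      lab_hi <- label_components(mask & rel >= tab$threshold[i + 1L])
      px <- which(lab_hi > 0L)
      if (length(px) == 0L) next
      # every fine region must sit inside exactly one coarse region
      parents <- tapply(lab_lo[px], lab_hi[px], function(p) length(unique(p)))
      if (any(parents != 1L) || any(lab_lo[px] == 0L)) {
        violations <- violations + 1L
      }
    }
  }
  expect_equal(violations, 0L)
})

test_that("equivalent diameters are quantized by the grid pitch", {
  set.seed(32)
  map <- manual_density_map(gaussian_smooth(matrix(rexp(625), 25, 25), 1.2))
  sw <- sweep_thresholds(map, step = 0.5)
  for (regs in sw$regions) {
    if (nrow(regs) == 0) next
    areas <- regs$equiv_diameter_nm^2 * pi / 4 / map$grid_pitch_nm^2
    expect_equal(areas, round(areas), tolerance = 1e-9)
    expect_true(all(regs$area_px >= 1))
  }
})
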