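test_that("Gaussian PSF moments scale as 1/n", {
  m <- psf_moments(130, 26.25)
  expect_lt(abs(m$mu[["mu2"]] / m$mu[["mu3"]] - 1.5), 1e-6)
  expect_lt(abs(m$mu[["mu2"]] / m$mu[["mu4"]] - 2.0), 1e-6)
  expect_true(all(diff(m$mu) < 0) && all(m$mu > 0) && all(is.finite(m$mu)))
  # analytic value: sum of U^n over the grid ~ 2 pi sigma^2 / (n pitch^2)
  expect_equal(m$mu[["mu2"]], 2 * pi * 130^2 / (2 * 26.25^2),
               tolerance = 1e-5)
  expect_error(psf_moments(-1, 26.25), "positive")
})

test_that("blinking inversion reproduces the worked K1/K2 example exactly", {
  cum <- forward_cumulants(N = 50, eps = 4, rho = 0.3)
  bl <- estimate_blinking(cum, psf_moments_manual(c(1, 1, 1, 1)))
  expect_equal(bl$K1[1, 1], 1.6, tolerance = 1e-12)
  expect_equal(bl$K2[1, 1], -4.16, tolerance = 1e-12)
  expect_equal(bl$epsilon[1, 1], 4, tolerance = 1e-12)
  expect_equal(bl$rho_on[1, 1], 0.3, tolerance = 1e-12)
  expect_true(all(bl$valid))
})

test_that("symmetric blinking (rho = 0.5) gives a vanishing K1", {
  cum <- forward_cumulants(N = 20, eps = 3, rho = 0.5)
  bl <- estimate_blinking(cum, psf_moments_manual(c(1, 1, 1, 1)))
  expect_equal(bl$K1[1, 1], 0, tolerance = 1e-12)
  expect_equal(bl$rho_on[1, 1], 0.5, tolerance = 1e-12)
})

test_that("pixels with degenerate g2 are flagged invalid, not NaN", {
  cum <- forward_cumulants(N = 50, eps = 4, rho = 0.3)
  cum$g2[2, 2] <- 0
  bl <- estimate_blinking(cum, psf_moments_manual(c(1, 1, 1, 1)))
  expect_false(bl$valid[2, 2])
  expect_true(is.na(bl$epsilon[2, 2]))
  expect_false(anyNA(bl$epsilon[bl$valid]))
  # all-degenerate map errors
  cum$g2[] <- 0
  expect_error(estimate_blinking(cum, psf_moments_manual(c(1, 1, 1, 1))),
               "ill-posed")
})

test_that("the density equation inverts the forward model exactly", {
  mu1 <- psf_moments_manual(c(1, 1, 1, 1))
  cum <- forward_cumulants(N = 50, eps = 4, rho = 0.3)
  expect_equal(cum$g2[1, 1], 168)  # 50 * 16 * 0.21
  bl <- estimate_blinking(cum, mu1)
  map <- compute_density_map(cum, bl, mu1)
  expect_equal(map$N[1, 1], 50, tolerance = 1e-12)
  expect_equal(map$delta_avg, 50, tolerance = 1e-12)

  # doubling the brightness at fixed N leaves the estimate unchanged
  cum2 <- forward_cumulants(N = 50, eps = 8, rho = 0.3)
  map2 <- compute_density_map(cum2, estimate_blinking(cum2, mu1), mu1)
  expect_equal(map2$N, map$N, tolerance = 1e-12)

  # degenerate pixels surface as zero density
  cum$g2[3, 3] <- 0
  bl3 <- estimate_blinking(cum, mu1)
  map3 <- compute_density_map(cum, bl3, mu1)
  expect_equal(map3$N[3, 3], 0)
})

test_that("forward-model inversion is exact over the parameter grid", {
  mu <- psf_moments(130, 26.25)$mu
  grid <- expand.grid(N = 10^seq(0, 3, length.out = 10),
                      eps = seq(0.5, 20, length.out = 10),
                      rho = seq(0.05, 0.95, length.out = 10))
  moments <- psf_moments(130, 26.25)
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cum <- forward_cumulants(g$N, g$eps, g$rho, mu = mu, dims = c(2, 2))
    map <- compute_density_map(cum, estimate_blinking(cum, moments), moments)
    worst <- max(worst, abs(map$N[1, 1] - g$N) / g$N)
  }
  expect_lt(worst, 1e-9)
})

test_that("background mask keeps the largest connected bright component", {
  v <- matrix(0, 20, 20)
  v[5:15, 5:15][outer((-5:5)^2, (-5:5)^2, `+`) <= 25] <- 10
  bs <- structure(list(values = v, order_used = 2L, grid_pitch_nm = 26.25),
                  class = "sofi_bsofi")
  m <- background_mask(bs)
  expect_equal(m, v > 0)

  expect_true(all(background_mask(structure(list(values = matrix(3, 5, 5)),
                                            class = "sofi_bsofi"))))

  v2 <- matrix(0, 20, 20); v2[2:11, 2:11] <- 5; v2[15:17, 15:17] <- 5
  bs2 <- structure(list(values = v2), class = "sofi_bsofi")
  m2 <- background_mask(bs2)
  expect_true(all(m2[2:11, 2:11]) && !any(m2[15:17, 15:17]))

  expect_error(background_mask(structure(list(values = matrix(0, 4, 4)),
                                         class = "sofi_bsofi")), "empty")
})

test_that("group normalization equalizes means within and across groups", {
  set.seed(20)
  mk <- function(mean_val) {
    N <- matrix(runif(16, 0.5, 1.5), 4, 4)
    manual_density_map(N * mean_val / mean(N))
  }
  maps <- lapply(c(2, 4, 1, 3), mk)
  out <- normalize_density_groups(maps, c("A", "A", "B", "B"))
  means <- vapply(out, function(m) mean(m$N), 0)
  # group means were A: 3, B: 2; maximum group mean 3
  expect_equal(means, c(1, 1, 2 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(attr(out, "group_means")), c(1, 2 / 3), tolerance = 1e-12)

  single <- normalize_density_groups(maps[1], "A")
  expect_equal(mean(single[[1]]$N), 1, tolerance = 1e-12)

  same <- normalize_density_groups(list(maps[[1]], maps[[1]]), c("A", "A"))
  expect_equal(same[[1]]$N, same[[2]]$N)
  expect_equal(mean(same[[1]]$N), 1, tolerance = 1e-12)
})

test_that("species-wide regularization keeps the forward-model parameters", {
  mu <- psf_moments_manual(c(1, 1, 1, 1))
  cum <- forward_cumulants(N = 30, eps = 5, rho = 0.2)
  reg <- regularize_blinking(estimate_blinking(cum, mu), cum)
  expect_equal(unique(as.vector(reg$epsilon)), 5, tolerance = 1e-12)
  expect_equal(unique(as.vector(reg$rho_on)), 0.2, tolerance = 1e-12)
  expect_true(all(reg$valid))
  map <- compute_density_map(cum, reg, mu)
  expect_equal(map$N[1, 1], 30, tolerance = 1e-12)
})

test_that("smoothing is the identity on uniform fields and conserves mass", {
  u <- matrix(3.7, 10, 12)
  expect_equal(gaussian_smooth(u, 2), u, tolerance = 1e-12)
  set.seed(21)
  m <- matrix(runif(400), 20, 20)
  expect_equal(mean(gaussian_smooth(m, 1.5)), mean(m), tolerance = 0.02)
})

test_that("deconvolution sharpens a blurred spot and conserves flux", {
  img <- matrix(0, 31, 31); img[16, 16] <- 100
  blurred <- gaussian_smooth(img, 3)
  sharp <- deconvolve_cumulant(blurred, 3, iterations = 50)
  expect_gt(max(sharp), 3 * max(blurred))
  expect_equal(sum(sharp), sum(blurred), tolerance = 0.05)
  expect_equal(which.max(sharp), which.max(blurred))
  expect_equal(deconvolve_cumulant(blurred, 3, 0), blurred)
})

test_that("scale invariance: rescaling all frames leaves densities unchanged", {
  set.seed(22)
  sim <- simulate_scenario(120, 1500, 50, n_hdrs = 2, n_frames_total = 400,
                          field_um = 1.2, seed = 31)
  run <- function(seq) {
    cum <- compute_cumulants(seq, 130, block_len = 200)
    mom <- psf_moments(130, cum$grid_pitch_nm)
    bl <- regularize_blinking(estimate_blinking(cum, mom), cum)
    compute_density_map(cum, bl, mom)
  }
  m1 <- run(sim$seq)
  m2 <- run(sofi_sequence(unclass(sim$seq) * 3, pixel_pitch(sim$seq)))
  expect_equal(m2$N / m2$delta_avg, m1$N / m1$delta_avg, tolerance = 1e-6)
})

test_that("nyquist limit is twice the map pitch", {
  expect_equal(nyquist_diameter_nm(26.25), 52.5)
})
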