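test_that("ground-truth HDRs fit the field, avoid overlap and hit densities", {
  counts <- c()
  for (sd in 1:3) {
    gt <- make_ground_truth(10, 180, 3000, 100, 3, seed = sd)
    h <- gt$hdrs
    expect_true(all(h$x_nm >= 90 & h$x_nm <= 2910 &
                      h$y_nm >= 90 & h$y_nm <= 2910))
    d <- as.matrix(dist(cbind(h$x_nm, h$y_nm))); diag(d) <- Inf
    expect_true(all(d >= 180))
    # molecules assigned to an HDR lie inside its disk
    for (k in 1:10) {
      m <- gt$molecules[gt$molecules$hdr_id == k, ]
      expect_true(all((m$x_nm - h$x_nm[k])^2 + (m$y_nm - h$y_nm[k])^2 <=
                        90.0001^2))
    }
    counts <- c(counts, h$n_molecules)
  }
  # Poisson(3000 * pi * 0.09^2) = Poisson(76.3) per HDR, 30 draws
  lambda <- 3000 * pi * 0.09^2
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(counts)))
})

test_that("the no-cluster control is a uniform layout at background density", {
  gt <- make_ground_truth(0, 180, 3000, contrast = 100, field_um = 3, seed = 7)
  expect_equal(nrow(gt$hdrs), 0L)
  expect_true(all(gt$molecules$hdr_id == 0L))
  expect_equal(gt$background_density_per_um2, 30)
  expect_lt(abs(nrow(gt$molecules) - 30 * 9), 3 * sqrt(30 * 9))
  expect_error(make_ground_truth(5, 3200, 1000, 10, field_um = 3, seed = 1),
               "exceeds")
})

test_that("trace statistics follow the Markov photokinetics", {
  # activation and bleaching disabled: stationary on-fraction 0.2
  model <- photokinetics_model(mean_on_frames = 2, mean_off_frames = 8,
                               activation_rate_per_frame = 1,
                               bleach_prob_per_on_frame = 0)
  tr <- simulate_traces(25, 2000, model, seed = 41)
  on_frac <- vapply(1:25, function(m) sum(tr$events$molecule == m) / 2000, 0)
  expect_lt(abs(mean(on_frac) - 0.2), 3 * stats::sd(on_frac) / sqrt(25))

  # zero brightness gives all-zero photon traces
  dark <- simulate_traces(5, 100, photokinetics_model(
    brightness_photons_per_frame = 0, activation_rate_per_frame = 1), seed = 42)
  expect_true(all(dark$events$photons == 0))

  # certain bleaching limits every molecule to a single on-frame
  flash <- simulate_traces(50, 500, photokinetics_model(
    bleach_prob_per_on_frame = 1, activation_rate_per_frame = 0.05), seed = 43)
  expect_true(all(table(flash$events$molecule) == 1L))
})

test_that("the photon budget matches brightness times on-frames", {
  model <- photokinetics_model(activation_rate_per_frame = 1,
                               brightness_photons_per_frame = 50)
  tr <- simulate_traces(40, 3000, model, seed = 44)
  expected <- 50 * nrow(tr$events)
  expect_lt(abs(sum(tr$events$photons) - expected), 3 * sqrt(expected))
})

test_that("rendering reproduces the camera noise model", {
  gt <- make_ground_truth(0, 100, 1e-9, 1, field_um = 1, seed = 45)
  expect_equal(nrow(gt$molecules), 0L)
  optics <- acquisition_config(em_gain = 1, offset_counts = 100,
                               read_noise_counts = 10)
  tr <- simulate_traces(0, 50, photokinetics_model(), seed = 46)
  seq <- render_sequence(gt, tr, optics, seed = 47)
  # photoelectron counts are round(N(0, 10)) clipped at 0 here
  x <- as.vector(unclass(seq))
  n <- length(x)
  expect_lt(abs(mean(x) - 10 / sqrt(2 * pi)), 3 * 10 / sqrt(n) + 0.1)
  raw_sd_sq <- mean(x^2) - mean(x)^2
  expect_lt(abs(raw_sd_sq - 100 * (0.5 - 1 / (2 * pi))), 15)
})

test_that("an always-on molecule conserves photon flux on the camera", {
  gt <- make_ground_truth(0, 100, 1e-9, 1, field_um = 1, seed = 48)
  gt$molecules <- tibble::tibble(x_nm = 500, y_nm = 500, hdr_id = 0L)
  model <- photokinetics_model(mean_on_frames = 1e9,
                               activation_rate_per_frame = 1,
                               bleach_prob_per_on_frame = 0,
                               brightness_photons_per_frame = 200)
  tr <- simulate_traces(1, 300, model, seed = 49)
  optics <- acquisition_config(em_gain = 1, offset_counts = 500,
                               read_noise_counts = 1e-6)
  seq <- render_sequence(gt, tr, optics, seed = 50, detection_efficiency = 1)
  total <- sum(unclass(seq))
  expected <- sum(tr$events$photons)
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("camera gain cancels in the photoelectron output", {
  # all molecules emitting so the signal dominates the clipped noise floor
  bright <- photokinetics_model(activation_rate_per_frame = 1,
                                bleach_prob_per_on_frame = 0)
  sim1 <- simulate_scenario(120, 1000, 20, n_hdrs = 2, n_frames_total = 50,
                            field_um = 1, seed = 51, model = bright,
                            optics = acquisition_config(em_gain = 150))
  sim2 <- simulate_scenario(120, 1000, 20, n_hdrs = 2, n_frames_total = 50,
                            field_um = 1, seed = 51, model = bright,
                            optics = acquisition_config(em_gain = 300))
  expect_lt(abs(mean(sim1$seq) / mean(sim2$seq) - 1), 0.02)
})

test_that("identical seeds give bit-identical stacks", {
  a <- simulate_scenario(120, 1500, 50, n_hdrs = 3, n_frames_total = 40,
                         field_um = 1.5, seed = 52)
  b <- simulate_scenario(120, 1500, 50, n_hdrs = 3, n_frames_total = 40,
                         field_um = 1.5, seed = 52)
  expect_identical(unclass(a$seq), unclass(b$seq))
  expect_identical(a$gt$molecules, b$gt$molecules)
})

test_that("the scenario grid enumerates the Cartesian product", {
  man <- run_scenarios(diameters_nm = c(60, 120, 180),
                       densities_per_um2 = c(500, 1750, 3000),
                       contrasts = c(20, 50, 100), layouts = "hdr",
                       replicates = 1, n_frames_total = 3, seed = 3)
  expect_equal(nrow(man), 27L)
  expect_equal(nrow(unique(man[c("diameter_nm", "density_per_um2", "contrast")])),
               27L)
  expect_length(attr(man, "results"), 27L)

  empty <- run_scenarios(replicates = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("scenario files round-trip through disk deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m1 <- run_scenarios(120, 1500, 50, layouts = "hdr", replicates = 1,
                      n_frames_total = 5, seed = 9, out_dir = dir1)
  m2 <- run_scenarios(120, 1500, 50, layouts = "hdr", replicates = 1,
                      n_frames_total = 5, seed = 9, out_dir = dir2)
  expect_true(file.exists(m1$stack[1]) && file.exists(m1$truth[1]))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  expect_identical(unname(tools::md5sum(m1$stack[1])),
                   unname(tools::md5sum(m2$stack[1])))
  truth <- utils::read.csv(m1$truth[1])
  expect_named(truth, c("x_nm", "y_nm", "hdr_id"))
})
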