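test_that("noise-free ATPase generator matches the Michaelis-Menten closed form", {
  # half-saturation point
  ds <- gen_atpase_dataset(mm_params(0, 1, 10), actin_concs = 10,
                           noise_sd = 0, n_replicates = 1)
  expect_equal(ds$rate_per_s, 0.5)
  # whole curve at the wild-type truth
  ds <- gen_atpase_dataset(wt_truth(), assay_concs(), noise_sd = 0,
                           n_replicates = 1)
  expect_equal(ds$rate_per_s, mm_rate(wt_truth(), assay_concs()),
               tolerance = 1e-12)
})

test_that("noisy ATPase replicate means satisfy the CLT bound", {
  ds <- gen_atpase_dataset(wt_truth(), assay_concs(), noise_sd = 0.02,
                           n_replicates = 4, seed = 7)
  means <- tapply(ds$rate_per_s, ds$actin_uM, mean)
  truth <- mm_rate(wt_truth(), as.numeric(names(means)))
  expect_true(all(abs(means - truth) < 3 * 0.02 / sqrt(4)))
})

test_that("ATPase generator validates inputs and truncates rates at zero", {
  expect_error(gen_atpase_dataset(wt_truth(), numeric(0)),
               class = "myotension_invalid_input")
  expect_error(gen_atpase_dataset(wt_truth(), -1),
               class = "myotension_invalid_input")
  ds <- gen_atpase_dataset(mm_params(0, 0.001, 10), c(0, 1), noise_sd = 1,
                           n_replicates = 200, seed = 1)
  expect_true(all(ds$rate_per_s >= 0))
})

test_that("displacement generator matches the Kelvin-Voigt closed form", {
  tr <- gen_displacement_trace(list(amplitude = 2, tau = 5), dt = 1,
                               duration = 60, noise_sd = 0)
  expect_equal(tr$displacement[tr$times == 0], 0)
  expect_equal(tr$displacement[tr$times == 1], 2 * (1 - exp(-0.2)),
               tolerance = 1e-12)
  expect_true(all(diff(tr$displacement) >= 0))
  # plateau at the amplitude for t >> tau
  expect_equal(tr$displacement[length(tr$times)], 2, tolerance = 1e-4)
  expect_error(gen_displacement_trace(list(amplitude = -1, tau = 5), 1, 10),
               class = "myotension_invalid_input")
})

test_that("noisy displacement stays within the Gaussian tail bound", {
  tr <- gen_displacement_trace(list(amplitude = 2, tau = 5), dt = 0.5,
                               duration = 30, noise_sd = 0.05, seed = 42)
  closed <- 2 * (1 - exp(-tr$times / 5))
  # truncation at zero can only pull samples toward the closed form near 0
  expect_true(all(abs(tr$displacement - closed) < 5 * 0.05))
})

test_that("kv_params derives amplitude, tau and v0 consistently", {
  p <- kv_params(tension = 4, zeta = 2, eta = 10)
  expect_equal(p$amplitude, 2)
  expect_equal(p$tau, 5)
  expect_equal(p$v0, 0.4)
  expect_error(kv_params(0, 1, 1), class = "myotension_invalid_input")
})

test_that("kymograph rendering follows wound geometry", {
  tr <- displacement_trace(c(0, 1, 2), c(0, 0.8, 0.4))
  k <- gen_kymograph(tr, pixel_size = 0.2, gap_center = 5, width = 10)
  wound_px <- rowSums(k$image == 0)
  expect_equal(wound_px, c(0, 8, 4))  # width = 2 * displacement / pixel
  # zero displacement: no wound pixels anywhere
  flat <- displacement_trace(c(0, 1), c(0, 0))
  k0 <- gen_kymograph(flat, pixel_size = 0.2, gap_center = 5, width = 10)
  expect_true(all(k0$image == 1))
  # displacement beyond the image half-width is rejected
  big <- displacement_trace(c(0, 1), c(0, 6))
  expect_error(gen_kymograph(big, 0.2, gap_center = 5, width = 10),
               class = "myotension_invalid_input")
})

test_that("generators are bit-reproducible given a seed", {
  a <- gen_atpase_dataset(wt_truth(), assay_concs(), 0.02, 4, seed = 9)
  b <- gen_atpase_dataset(wt_truth(), assay_concs(), 0.02, 4, seed = 9)
  expect_identical(a, b)
  e1 <- gen_embryo(synth_embryo_config(n_cells = 5, seed = 9))
  e2 <- gen_embryo(synth_embryo_config(n_cells = 5, seed = 9))
  expect_identical(e1, e2)
  t1 <- gen_motility_tracks(100, c(10, 0), n_tracks = 3, seed = 9,
                            noise_sd = 5)
  t2 <- gen_motility_tracks(100, c(10, 0), n_tracks = 3, seed = 9,
                            noise_sd = 5)
  expect_identical(t1, t2)
})

test_that("embryo generator respects the coupling rule and bounds", {
  # zero motor activity: mean area constant up to noise
  e0 <- gen_embryo(synth_embryo_config(n_cells = 30, motor_activity_factor = 0,
                                       seed = 3))
  ms <- mean_area_series(e0)
  # noise on the 30-cell mean is ~0.09 um^2; any real constriction loses
  # tens of um^2 over the movie
  expect_lt(max(abs(ms$area - 40)), 0.5)
  # area never below the floor, intensity never negative
  e1 <- gen_embryo(synth_embryo_config(n_cells = 20, seed = 4,
                                       area_floor = 4))
  expect_true(all(e1$cells$area_um2 >= 4))
  expect_true(all(e1$cells$myosin_au >= 0))
  # no pulses: no accumulation events downstream
  ctrl <- gen_embryo(synth_embryo_config(n_cells = 30, seed = 5))
  quiet <- gen_embryo(synth_embryo_config(n_cells = 30, seed = 5,
                                          myosin_pulse_rate = 0))
  stats <- control_rate_stats(ctrl)
  rates <- cell_rates(quiet)
  ev <- detect_accumulation_events(rates, stats)
  expect_equal(nrow(ev$instances), 0L)
})

test_that("matched-pulse genotypes reproduce the motor-activity ratio", {
  embryos <- allelic_series(c(1.0, 0.47), seed = 21, duration = 600,
                            n_cells = 100)
  means <- event_rate_means(embryos)
  expect_equal(means[2] / means[1], 0.47, tolerance = 0.10,
               ignore_attr = TRUE)
})

test_that("motility tracks carry drift and recover the true speed", {
  # stationary filaments under pure drift
  still <- gen_motility_tracks(0, drift_velocity = c(50, 0), n_tracks = 20,
                               duration = 30, seed = 2)
  raw <- track_speeds(still, drift_correct = FALSE)
  expect_equal(mean(raw), 50, tolerance = 1e-9)
  corrected <- track_speeds(still, drift_correct = TRUE)
  expect_lt(mean(corrected), 1)
  # noise-free gliding at the study speed, no drift
  glide <- gen_motility_tracks(247, c(0, 0), n_tracks = 10, duration = 30,
                               seed = 3)
  expect_equal(mean(track_speeds(glide, drift_correct = FALSE)), 247,
               tolerance = 1e-9)
  # drift-corrected recovery within 5%
  drifted <- gen_motility_tracks(100, c(30, -20), n_tracks = 50,
                                 duration = 30, seed = 5)
  expect_equal(mean(track_speeds(drifted, drift_correct = TRUE)), 100,
               tolerance = 0.05)
})
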