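test_that("Gaussian smoothing preserves constants, mass and impulse shape", {
  expect_equal(smooth_trace(rep(3, 20), sigma = 2), rep(3, 20))
  # unit impulse reproduces the normalized discrete kernel
  n <- 31
  impulse <- c(rep(0, 15), 1, rep(0, 15))
  sm <- smooth_trace(impulse, sigma = 1)
  kernel <- dnorm(-4:4, sd = 1); kernel <- kernel / sum(kernel)
  expect_equal(sm[12:20], kernel, tolerance = 1e-12)
  # sum preservation with reflective boundaries
  set.seed(1)
  for (sigma in c(0.5, 1, 3)) {
    x <- rnorm(40)
    expect_equal(sum(smooth_trace(x, sigma)), sum(x), tolerance = 1e-9)
  }
  # shift commutation: smoothing commutes with additive constants
  x <- rnorm(40)
  expect_equal(smooth_trace(x + 7, 2), smooth_trace(x, 2) + 7,
               tolerance = 1e-12)
})

test_that("instantaneous rates match analytic derivatives", {
  t <- seq(0, 10, by = 0.5)
  # linear area loss of 2 um^2/min: constriction rate is +2 everywhere
  tr <- data.frame(time_min = t, area_um2 = 50 - 2 * t, myosin_au = 5)
  r <- instantaneous_rates(tr)
  expect_equal(r$area_rate, rep(2, length(t)), tolerance = 1e-12)
  expect_equal(r$myosin_rate, rep(0, length(t)), tolerance = 1e-12)
  # quadratic series: central differences are exact at interior points
  tr2 <- data.frame(time_min = t, area_um2 = 100 - t^2, myosin_au = t^2)
  r2 <- instantaneous_rates(tr2)
  interior <- 2:(length(t) - 1)
  expect_equal(r2$area_rate[interior], 2 * t[interior], tolerance = 1e-10)
  expect_equal(r2$myosin_rate[interior], 2 * t[interior], tolerance = 1e-10)
  # rates are invariant to constant shifts of the series
  tr3 <- tr2; tr3$area_um2 <- tr3$area_um2 + 500
  expect_equal(instantaneous_rates(tr3)$area_rate, r2$area_rate)
})

test_that("control rate statistics pool all cells and embryos", {
  # two-point cell: rates [2, 2] from one-sided differences of a 2/min ramp
  cells <- data.frame(cell_id = 1, time_min = c(0, 1), area_um2 = c(10, 9),
                      myosin_au = c(0, 2))
  e <- embryo_dataset(cells, frame_interval = 60)
  s <- control_rate_stats(e, smooth_sigma = 0)
  expect_equal(s$mean_rate, 2)
  # pooling is order-invariant across embryos
  e1 <- gen_embryo(synth_embryo_config(n_cells = 5, seed = 1))
  e2 <- gen_embryo(synth_embryo_config(n_cells = 5, seed = 2))
  s12 <- control_rate_stats(list(e1, e2))
  s21 <- control_rate_stats(list(e2, e1))
  expect_equal(s12$mean_rate, s21$mean_rate)
  expect_equal(s12$sd_rate, s21$sd_rate)
})

test_that("event detection flags the closed 1-2 SD window", {
  stats <- fixed_rate_stats(mean_rate = 10, sd_rate = 2)
  rates <- c(10, 10 + 1.5 * 2, 10 + 2.5 * 2, 10 + 1 * 2, 10 + 2 * 2, 9)
  ev <- detect_accumulation_events(rates, stats)
  expect_equal(ev$instances$time_index, c(2L, 4L, 5L))  # boundaries included
  # all-mean rates: no events
  ev0 <- detect_accumulation_events(rep(10, 50), stats)
  expect_equal(nrow(ev0$instances), 0L)
  # run merging collapses consecutive flagged frames to their first frame
  run_rates <- c(10, 13, 13, 13, 10, 13, 13)
  evm <- detect_accumulation_events(run_rates, stats, merge_runs = TRUE)
  expect_equal(evm$instances$time_index, c(2L, 6L))
  expect_error(detect_accumulation_events(rates, fixed_rate_stats(10, 0)),
               class = "myotension_invalid_input")
})

test_that("flagged fraction on Gaussian rates matches the normal CDF", {
  set.seed(3)
  rates <- rnorm(1e5, mean = 4, sd = 1.5)
  ev <- detect_accumulation_events(rates, fixed_rate_stats(4, 1.5))
  frac <- nrow(ev$instances) / 1e5
  expect_equal(frac, pnorm(2) - pnorm(1), tolerance = 0.005 / 0.1359)
})

test_that("constriction rates are read off at event instances", {
  rates <- data.frame(cell_id = c(1, 1, 2), time_index = c(1, 2, 1),
                      time_min = c(0, 1, 0), area_rate = c(3, 1, 5),
                      myosin_rate = c(20, 5, 30))
  stats <- fixed_rate_stats(10, 8)  # window [18, 26]
  ev <- detect_accumulation_events(rates, stats)
  expect_equal(constriction_rates_at_events(rates, ev), 3)
  # dangling reference
  ev$instances$cell_id <- 99
  expect_error(constriction_rates_at_events(rates, ev),
               class = "myotension_invalid_input")
  # empty event set: empty result with warning
  ev0 <- detect_accumulation_events(rates, fixed_rate_stats(1000, 1))
  expect_warning(out <- constriction_rates_at_events(rates, ev0), "empty")
  expect_length(out, 0)
})

test_that("lower motor activity never increases event-conditioned rates", {
  embryos <- allelic_series(c(1.0, 0.74, 0.60, 0.47), seed = 31,
                            duration = 600, n_cells = 60)
  means <- event_rate_means(embryos)
  expect_true(all(diff(means) < 0))
})

test_that("embryo alignment finds onsets and flags flat embryos", {
  e <- gen_embryo(synth_embryo_config(n_cells = 60, seed = 6,
                                      duration = 600))
  al <- align_embryos(e)[[1]]
  expect_true(al$alignable)
  # pulses (hence constriction) start at the 120 s onset delay
  expect_lt(abs(al$alignment_offset - 2), 2 * 5 / 60 + 1e-9)
  # identical embryo shifted by 60 s: offsets differ by 1 min
  shifted <- e
  shifted$cells$time_min <- shifted$cells$time_min + 1
  both <- align_embryos(list(e, shifted))
  expect_equal(both[[2]]$alignment_offset - both[[1]]$alignment_offset, 1,
               tolerance = 1e-9)
  # flat-area embryo is unalignable
  flat <- gen_embryo(synth_embryo_config(n_cells = 30, seed = 7,
                                         motor_activity_factor = 0))
  expect_false(align_embryos(flat)[[1]]$alignable)
})

test_that("time to half area matches closed forms and is scale-invariant", {
  t <- seq(0, 10, by = 0.1)
  # linear decay losing 10% of A0 per minute
  lin <- time_to_half_area(100 * (1 - 0.1 * t), t)
  expect_equal(lin$t_half, 5, tolerance = 1e-9)
  expect_false(lin$censored)
  # exponential decay with 10 min time constant: t_half = 10 ln 2
  expo <- time_to_half_area(80 * exp(-t / 10), t)
  expect_equal(expo$t_half, 10 * log(2), tolerance = 1e-3)
  # uniform rescaling of the areas leaves the half time unchanged
  expect_equal(time_to_half_area(7 * 80 * exp(-t / 10), t)$t_half,
               expo$t_half, tolerance = 1e-12)
  # series that never halves is censored, not an error
  cens <- time_to_half_area(100 - t, t)
  expect_true(cens$censored)
  expect_true(is.na(cens$t_half))
})

test_that("slower motors lengthen the time to half area", {
  embryos <- allelic_series(c(1.0, 0.74, 0.60, 0.47), seed = 32,
                            duration = 1500, n_cells = 60)
  halves <- vapply(embryos, function(e) {
    al <- align_embryos(e)[[1]]
    ms <- mean_area_series(al)
    time_to_half_area(ms$area, ms$times, al$alignment_offset)$t_half
  }, numeric(1))
  expect_true(all(is.finite(halves)))
  expect_true(all(diff(halves) > 0))
})

test_that("stack preprocessing applies the top-two 2.5 SD rule", {
  # all voxels below threshold: all-zero projection
  arr <- array(1, dim = c(3, 4, 4))
  s <- myosin_stack(arr, cyto_mean = 2, cyto_sd = 1)
  out <- preprocess_myosin_stack(s)
  expect_true(all(attr(out, "unsmoothed") == 0))
  # one pixel with z-values [10, 3, 2] and threshold 5: projection 10
  arr[, 2, 2] <- c(10, 3, 2)
  s <- myosin_stack(arr, cyto_mean = 2.5, cyto_sd = 1)  # threshold 5
  out <- preprocess_myosin_stack(s)
  expect_equal(attr(out, "unsmoothed")[2, 2], 10)
  # enumeration oracle: nonzero exactly where one of the two largest
  # z-values exceeds the threshold
  set.seed(9)
  arr <- array(rnorm(4 * 6 * 5, mean = 5, sd = 3), dim = c(4, 6, 5))
  s <- myosin_stack(arr, cyto_mean = 5, cyto_sd = 1.2)  # threshold 8
  proj <- attr(preprocess_myosin_stack(s), "unsmoothed")
  oracle <- apply(arr, c(2, 3), function(z) {
    sort(z, decreasing = TRUE)[1] > 8  # max of top two == max overall
  })
  expect_equal(proj > 0, oracle)
  # missing stats and no background region
  expect_error(myosin_stack(arr), class = "myotension_invalid_input")
  # stats estimated from a designated background region
  s_bg <- myosin_stack(arr, background_region = list(y = 1:2, x = 1:2))
  expect_true(is.finite(s_bg$cyto_mean) && s_bg$cyto_sd > 0)
})

test_that("side-by-side intensity profiles compare calibrated images", {
  set.seed(10)
  frames <- lapply(1:3, function(i) {
    matrix(runif(30 * 40, 1, 2) * i, nrow = 30)  # intensity peaks at frame 3
  })
  pp <- intensity_profile_pair(frames, frames, pixel_size = 1)
  expect_equal(pp$profile_a, pp$profile_b)
  expect_equal(pp$peak_frame_a, 3L)
  # image B at half intensity: profile ratio 0.5 everywhere
  half <- lapply(frames, function(f) f * 0.5)
  pph <- intensity_profile_pair(frames, half, pixel_size = 1)
  expect_equal(pph$profile_b / pph$profile_a, rep(0.5, length(pph$profile_a)),
               tolerance = 1e-12)
  # 33 um window at 1 um/px spans 33 columns
  expect_length(pp$profile_a, 33)
  expect_error(intensity_profile_pair(frames, frames, pixel_size = 1,
                                      pixel_size_b = 0.5),
               class = "myotension_invalid_input")
})
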