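# analytic area trace straight from the generator's axis law, bypassing
# rasterization: area(t) = pi/4 * major(t) * minor(t)
analytic_trace <- function(cfg, noise_sd = 0, seed = 1) {
  n <- round(cfg$fps * cfg$duration_s)
  tt <- (seq_len(n) - 1) / cfg$fps
  ax <- axes_at(cfg, tt)
  a <- pi / 4 * ax$major * ax$minor
  if (noise_sd > 0) {
    set.seed(seed)
    a <- pmax(a + rnorm(n, sd = noise_sd), 0)
  }
  new_area_trace(tt, a, cfg$fps)
}

test_that("area_trace converts mask counts to a uniform time series", {
  cfg <- quick_config(fps = 200, duration_s = 0.25)
  sq <- generate_sequence(cfg)
  tr <- area_trace(sq)
  expect_length(tr$times, 50)
  expect_equal(tr$times[length(tr$times)], 49 / 200)
  expect_equal(tr$areas, vapply(sq$masks, function(m) sum(m > 0), numeric(1)))
  expect_error(area_trace(list(), 200), "empty")
})

test_that("mask area trace is periodic at the beat frequency", {
  cfg <- quick_config(fps = 200, duration_s = 1, beat_freq = 5)
  tr <- area_trace(generate_sequence(cfg))
  period_frames <- cfg$fps / cfg$beat_freq          # 40 frames
  shifted <- tr$areas[(period_frames + 1):length(tr$areas)]
  orig <- tr$areas[1:length(shifted)]
  # rasterization jitter bound: 2% of diastolic area
  expect_lt(max(abs(shifted - orig)), 0.02 * max(tr$areas))
})

test_that("diastole peaks are found at the beat period", {
  cfg <- quick_config(fps = 200, duration_s = 10, beat_freq = 7.5)
  tr <- analytic_trace(cfg)
  bs <- detect_diastole_peaks(tr)
  expect_gte(length(bs$peak_times), 74)
  expect_lte(length(bs$peak_times), 76)
  expect_true(all(diff(bs$peak_times) > 0))
  expect_length(bs$ibis, length(bs$peak_times) - 1)
  expect_equal(mean(bs$ibis), 1 / 7.5, tolerance = 0.01)
})

test_that("constant traces raise an insufficient-beats error", {
  tr <- new_area_trace((0:99) / 100, rep(500, 100), 100)
  expect_error(detect_diastole_peaks(tr), "constant|insufficient")
})

test_that("peak count is robust to small additive noise", {
  cfg <- quick_config(fps = 200, duration_s = 10, beat_freq = 6)
  clean <- analytic_trace(cfg)
  n0 <- length(detect_diastole_peaks(clean)$peak_times)
  amp <- diff(range(clean$areas))
  for (s in 1:5) {
    noisy <- analytic_trace(cfg, noise_sd = 0.01 * amp, seed = s)
    expect_equal(length(detect_diastole_peaks(noisy)$peak_times), n0)
  }
})

test_that("simple local maxima agree with pracma on a clean trace", {
  skip_if_not_installed("pracma")
  cfg <- quick_config(fps = 200, duration_s = 2, beat_freq = 4)
  tr <- analytic_trace(cfg)
  bs <- detect_diastole_peaks(tr, smooth_window = 1)
  pk <- pracma::findpeaks(tr$areas, minpeakdistance = 10)
  expect_equal(sort(bs$peak_indices), sort(pk[, 2]))
})

test_that("heart rate is 60 over the mean inter-beat interval", {
  expect_equal(heart_rate(c(0.5, 0.5, 0.5)), 120)
  expect_equal(heart_rate(c(0.4, 0.6)), 120)
  bs <- structure(list(peak_times = c(1, 1.5), ibis = 0.5,
                       peak_indices = c(1L, 2L)), class = "beat_series")
  expect_equal(heart_rate(bs), 120)
  expect_error(heart_rate(numeric(0)), "at least one")
  # invariance to uniform time shift of the peaks
  t0 <- c(0.1, 0.35, 0.61, 0.84)
  expect_equal(heart_rate(diff(t0)), heart_rate(diff(t0 + 3.7)))
})

test_that("poincare matches the rotated-coordinate oracle", {
  set.seed(31)
  for (i in 1:100) {
    x <- runif(sample(3:40, 1), 0.1, 0.4)
    p <- poincare(x)
    o <- oracle_poincare(x)
    expect_equal(p$sd1, o$sd1, tolerance = 1e-10)
    expect_equal(p$sd2, o$sd2, tolerance = 1e-10)
    # sd1 also equals the difference-variance closed form
    expect_equal(p$sd1, sqrt(var(diff(x)) / 2), tolerance = 1e-12)
  }
})

test_that("poincare degenerate and scaling behavior", {
  p <- poincare(rep(0.25, 10))
  expect_equal(p$sd1, 0)
  expect_equal(p$sd2, 0)
  x <- c(0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6, 0.4, 0.6)
  p1 <- poincare(x); p3 <- poincare(3 * x)
  expect_equal(p3$sd1, 3 * p1$sd1)
  expect_equal(p3$sd2, 3 * p1$sd2)
  expect_error(poincare(c(0.5, 0.5)), "at least 3")
  expect_equal(poincare(x, unit = "ms")$unit, "ms")
})

test_that("area change follows the EDV/ESV formula", {
  tr <- new_area_trace((0:3) / 10, c(100, 80, 100, 80), 10)
  expect_equal(area_change(tr), 20)
  flat <- new_area_trace((0:3) / 10, rep(70, 4), 10)
  expect_equal(area_change(flat), 0)
  # both axes contracting by c shrink the area by 1 - (1-c)^2
  cfg <- quick_config(fps = 200, duration_s = 2, contraction_fraction = 0.2)
  expect_equal(area_change(analytic_trace(cfg)), (1 - 0.8^2) * 100,
               tolerance = 0.1)
})

test_that("global area change dominates the per-beat mean on noisy traces", {
  cfg <- quick_config(fps = 200, duration_s = 5, beat_freq = 6)
  amp <- diff(range(analytic_trace(cfg)$areas))
  for (s in 1:20) {
    tr <- analytic_trace(cfg, noise_sd = 0.03 * amp, seed = s)
    beats <- detect_diastole_peaks(tr)
    expect_gte(area_change(tr, "global"),
               area_change(tr, "per_beat", beats = beats))
  }
})
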