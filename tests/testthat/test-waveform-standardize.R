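test_that("waveform construction enforces the envelope invariants", {
  tt <- seq(0, 1, by = 0.01)
  expect_s3_class(waveform(tt, 50 + sin(tt)), "waveform")
  expect_error(waveform(tt, rep(1, 3)), "equal length")
  expect_error(waveform(tt[1:5], rep(1, 5)), "at least 8")
  expect_error(waveform(rev(tt), 50 + sin(tt)), "increasing")
  expect_error(waveform(tt, sin(tt)), "positive")       # dips below 0
  expect_error(waveform(tt, c(NA, rep(50, length(tt) - 1))), "finite")
})

test_that("waveform files round-trip with labels from the filename", {
  w <- waveform(seq(0, 2, by = 0.005), 60 + 10 * sin(seq(0, 2, by = 0.005)),
                artery = "MCA_L", subject = "P001")
  d <- withr::local_tempdir()
  f <- file.path(d, "P001_MCA_L.csv")
  write_waveform(w, f)
  r <- read_waveform(f)
  expect_equal(r$t, w$t)
  expect_equal(r$v, w$v)
  expect_equal(r$artery, "MCA_L")
  expect_equal(r$subject, "P001")
})

test_that("nadir detection finds cycle boundaries of a pure cosine", {
  tt <- seq(0, 2.4, by = 1 / 200)
  w <- waveform(tt, 60 - 20 * cos(2 * pi * tt / 0.8))
  nad <- detect_nadirs(w)
  expect_length(nad, 4L)
  expect_lt(max(abs(nad - c(0, 0.8, 1.6, 2.4))), 1.01 / 200)
})

test_that("nadir detection rejects dicrotic notches and degenerate input", {
  sw <- synth_waveform(patient_params(95, 55, 80), cycles = 4L,
                       notch_depth = 0.1)
  nad <- detect_nadirs(sw$waveform)
  truth <- sw$truth$beat_times
  expect_length(nad, length(truth))
  expect_lt(max(abs(nad - truth)), 1.01 / 200)

  tt <- seq(0, 3, by = 0.01)
  expect_error(detect_nadirs(waveform(tt, rep(50, length(tt)))), "constant")
  short <- waveform(seq(0, 0.2, by = 0.01), 50 + seq(0, 0.2, by = 0.01))
  expect_error(detect_nadirs(short), "shorter")
})

test_that("nadir detection stays accurate on smoothed noisy envelopes", {
  sw <- synth_waveform(patient_params(95, 55, 80), cycles = 4L,
                       noise_sd = 1, notch_depth = 0.1, seed = 5)
  nad <- detect_nadirs(smooth_waveform(sw$waveform))
  truth <- sw$truth$beat_times
  expect_length(nad, length(truth))
  expect_lt(max(abs(nad - truth)), 0.05)
})

test_that("cycle extraction re-bases beats and preserves the samples", {
  sw <- synth_waveform(patient_params(88, 52, 70), cycles = 3L)
  w <- sw$waveform
  nad <- detect_nadirs(w)
  cyc <- extract_cycles(w, nad)
  expect_length(cyc, length(nad) - 1L)
  for (k in seq_along(cyc)) {
    expect_equal(cyc[[k]]$t[1], 0)
    expect_equal(cyc[[k]]$duration, nad[k + 1] - nad[k], tolerance = 1e-12)
  }
  # round-trip: concatenated cycles reproduce the source samples
  i0 <- which.min(abs(w$t - nad[1]))
  i1 <- which.min(abs(w$t - nad[length(nad)]))
  rebuilt <- c(cyc[[1]]$v,
               unlist(lapply(cyc[-1], function(c) c$v[-1])))
  expect_equal(rebuilt, w$v[i0:i1])
  expect_error(extract_cycles(w, nad[1]), "at least 2")
})

test_that("standardization maps any beat onto the 0.8 s / 50-80 frame", {
  tt <- seq(0, 1.2, length.out = 121)
  c1 <- cardiac_cycle(tt, 40 - 20 * cos(2 * pi * tt / 1.2))  # 1.2 s, 20-60
  s1 <- standardize_cycle(c1)
  expect_equal(s1$duration, 0.8)
  expect_equal(s1$vmin, 50)
  expect_equal(s1$vmax, 80)
  expect_false(s1$in_range)   # flag carried over from the 1.2 s duration

  # exact idempotence (standardized cycles are returned unchanged)
  expect_identical(standardize_cycle(s1), s1)

  # invariance to affine changes of the input scales
  a <- 3.7; b <- 12; g <- 1.9
  c2 <- cardiac_cycle(tt * g, a * c1$v + b)
  expect_equal(standardize_cycle(c2)$v, s1$v, tolerance = 1e-12)
  expect_equal(standardize_cycle(c2)$t, s1$t, tolerance = 1e-12)
})

test_that("a beat sampled from the standardized model is nearly fixed", {
  c0 <- v0_cycle()
  s0 <- standardize_cycle(c0)
  expect_lt(max(abs(s0$v - c0$v)), 0.2)
})

test_that("degenerate amplitude is rejected at the cycle boundary", {
  expect_error(cardiac_cycle(c(0, 0.4, 0.8), rep(55, 3)), "degenerate")
})

test_that("resampling and the median beat preserve the standardized frame", {
  c0 <- standardize_cycle(v0_cycle(1601))
  r <- resample_cycle(c0, 200L)
  expect_length(r$t, 200L)
  expect_equal(r$t[1], 0)
  expect_equal(r$duration, 0.8)
  expect_lt(max(abs(r$v - fs_evaluate(renormalized_template(), r$t))), 0.01)

  m <- median_cycle(list(c0, c0, c0), n = 200L)
  expect_equal(m$v, r$v)
})
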