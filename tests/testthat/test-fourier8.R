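test_that("built-in standardized model carries the printed constants", {
  s <- v0()
  expect_equal(s$a0, 64.5)
  expect_equal(s$w, 7.85)
  expect_equal(s$b[1], 10.962)
  expect_equal(s$a[1], -5.154)
  # direct summation of the coefficients at t = 0
  expect_equal(fs_evaluate(s, 0), 50.118744, tolerance = 1e-12)
})

test_that("evaluation is a plain harmonic superposition and is periodic", {
  const <- fourier8(w = 1, a0 = 5, a = rep(0, 8), b = rep(0, 8))
  expect_equal(fs_evaluate(const, c(-3, 0, 0.7, 100)), rep(5, 4))

  s <- v0()
  set.seed(1)
  tt <- runif(50, -2, 2)
  for (k in c(-2L, 1L, 3L))
    expect_equal(fs_evaluate(s, tt + k * fs_period(s)), fs_evaluate(s, tt),
                 tolerance = 1e-9)
  expect_error(fs_evaluate(s, c(0, NA)), "finite")
  expect_error(fs_evaluate(s, Inf), "finite")
})

test_that("period follows 2*pi/w and matches the 0.8 s standardized cycle", {
  expect_equal(fs_period(fourier8(2 * pi, 1, rep(0, 8), rep(0, 8))), 1.0)
  expect_lt(abs(fs_period(v0()) - 0.8) / 0.8, 0.001)
  # patient-specific cycle is 60/H to the same 0.1 % (w is a rounded 7.85)
  for (H in c(60, 72.5, 100)) {
    p <- patient_params(95, 60, H)
    expect_lt(abs(fs_period(vx_transform(p)) - 60 / H) / (60 / H), 0.001)
  }
})

test_that("time-average equals a0, confirmed by quadrature", {
  expect_equal(fs_mean(v0()), 64.5)
  expect_equal(fs_mean(fourier8(3, -2.5, rnorm(8), rnorm(8))), -2.5)
  # trapezoid oracle over one full period at 1e5 points
  s <- v0()
  tt <- seq(0, fs_period(s), length.out = 1e5 + 1)
  quad <- pracma::trapz(tt, fs_evaluate(s, tt)) / fs_period(s)
  expect_equal(quad, fs_mean(s), tolerance = 1e-9)
})

test_that("extrema search finds global extrema over one period", {
  ex <- fs_extrema(v0())
  expect_lt(abs(ex$vmin - 50), 0.5)
  expect_lt(abs(ex$vmax - 80), 0.5)
  P <- fs_period(v0())
  expect_true(ex$tmin >= 0 && ex$tmin < P)
  expect_true(ex$tmax >= 0 && ex$tmax < P)
  # stationary points of the analytic derivative
  ds <- fs_derivative(v0())
  expect_lt(abs(fs_evaluate(ds, ex$tmin)), 1e-8)
  expect_lt(abs(fs_evaluate(ds, ex$tmax)), 1e-8)

  # single-harmonic closed form: a0 +/- beta
  sh <- fourier8(w = 2 * pi, a0 = 10, a = rep(0, 8),
                 b = c(3.5, rep(0, 7)))
  exh <- fs_extrema(sh)
  expect_equal(exh$vmin, 10 - 3.5, tolerance = 1e-9)
  expect_equal(exh$vmax, 10 + 3.5, tolerance = 1e-9)
})

test_that("patient rescaling has the closed-form mean, extrema and identity", {
  # identity case: exact coefficient equality
  expect_identical(coef(vx_transform(patient_params(80, 50, 75))),
                   coef(v0()))

  expect_equal(fs_mean(vx_transform(patient_params(110, 80, 75))),
               (14.5 * 110 + 15.5 * 80) / 30)

  # pointwise composition oracle at random times
  set.seed(42)
  p <- patient_params(104, 63, 88)
  vx <- vx_transform(p)
  tt <- runif(1000, 0, 3)
  oracle <- p$N + ((p$M - p$N) / 30) *
    (fs_evaluate(v0(), 0.8 * p$H * tt / 60) - 50)
  expect_equal(fs_evaluate(vx, tt), oracle, tolerance = 1e-10)

  # extrema map affinely from the standardized model's extrema
  ex0 <- fs_extrema(v0())
  for (par in list(c(95, 40, 66), c(40, 22, 99))) {
    p <- patient_params(par[1], par[2], par[3])
    exx <- fs_extrema(vx_transform(p))
    sc <- (p$M - p$N) / 30
    expect_equal(exx$vmin, p$N + sc * (ex0$vmin - 50), tolerance = 1e-9)
    expect_equal(exx$vmax, p$N + sc * (ex0$vmax - 50), tolerance = 1e-9)
  }
})

test_that("patient parameters are validated, warning outside inclusion", {
  expect_error(patient_params(50, 60, 75), "exceed")
  expect_error(patient_params(50, -5, 75), "> 0")
  expect_error(patient_params(50, 30, 0), "> 0")
  expect_warning(patient_params(130, 60, 75), "inclusion")
  expect_warning(patient_params(80, 50, 120), "inclusion")
  expect_silent(patient_params(80, 50, 75))
  expect_silent(patient_params(130, 60, 120, warn = FALSE))
})

test_that("derivative matches finite differences and has zero mean", {
  zero <- fs_derivative(fourier8(2, 7, rep(0, 8), rep(0, 8)))
  expect_equal(fs_evaluate(zero, seq(0, 3, 0.1)), rep(0, 31))

  set.seed(7)
  s <- vx_transform(patient_params(100, 55, 68))
  ds <- fs_derivative(s)
  expect_equal(fs_mean(ds), 0)
  tt <- runif(100, 0, 2)
  h <- 1e-6
  fd <- (fs_evaluate(s, tt + h) - fs_evaluate(s, tt - h)) / (2 * h)
  expect_equal(fs_evaluate(ds, tt), fd, tolerance = 1e-4)
})

test_that("coefficient serialization round-trips through flat JSON", {
  s <- vx_transform(patient_params(92, 48, 81))
  f <- withr::local_tempfile(fileext = ".json")
  write_fourier8(s, f, metadata = list(note = "synthetic"))
  r <- read_fourier8(f)
  expect_equal(coef(r), coef(s), tolerance = 1e-12)
  expect_equal(attr(r, "metadata")$units_w, "rad/s")
  expect_equal(attr(r, "metadata")$note, "synthetic")
  # missing keys are rejected
  jsonlite::write_json(list(w = 1, a0 = 2), f, auto_unbox = TRUE)
  expect_error(read_fourier8(f), "missing keys")
})

test_that("series construction rejects malformed input", {
  expect_error(fourier8(0, 1, rep(0, 8), rep(0, 8)), "w")
  expect_error(fourier8(1, 1, rep(0, 7), rep(0, 8)), "exactly 8")
  expect_error(fourier8(1, 1, c(NA, rep(0, 7)), rep(0, 8)), "finite")
})
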