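#' @keywords internal
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a TCD envelope waveform with known ground truth
#'
#' The base shape is the patient-specific model `vx_transform(params,
#' shape)` evaluated on a uniform sampling grid, reproducing the canonical
#' morphology: fast systolic upstroke from the nadir, slower late-systolic
#' rise, rapid early-diastolic decline. Optionally a dicrotic notch is
#' carved into the descending limb as a subtracted raised-cosine dip
#' (centre 55 % of the cycle, width 10 % of the cycle, depth a stated
#' fraction of the pulse amplitude), and i.i.d. Gaussian measurement noise
#' is added. Deterministic for a fixed seed; with `noise_sd = 0` and
#' `notch_depth = 0` the samples equal the model evaluation exactly.
#'
#' @param params A [patient_params] object.
#' @param cycles Number of cardiac cycles to generate (>= 1).
#' @param rate_hz Sampling rate, Hz (>= 50).
#' @param noise_sd Gaussian noise SD, cm/s.
#' @param notch_depth Notch depth as a fraction of the pulse amplitude
#'   `M - N`; 0 disables the notch.
#' @param seed Optional integer seed (the global RNG state is restored).
#' @param shape Standardized base shape passed to [vx_transform()].
#' @param artery,subject Labels stored on the waveform.
#' @return List with `waveform` (a [waveform]) and `truth`: the generating
#'   `series`, exact `beat_times` (multiples of the series period), the
#'   series `extrema`, and the generation parameters.
#' @export
synth_waveform <- function(params, cycles = 4L, rate_hz = 200,
                           noise_sd = 0, notch_depth = 0, seed = NULL,
                           shape = v0(), artery = NA_character_,
                           subject = NA_character_) {
  stopifnot(inherits(params, "patient_params"),
            cycles >= 1L, rate_hz >= 50, noise_sd >= 0,
            notch_depth >= 0, notch_depth < 1)
  series <- vx_transform(params, base = shape)
  period <- fs_period(series)
  t <- seq(0, by = 1 / rate_hz,
           length.out = floor(cycles * period * rate_hz) + 1L)
  v <- fs_evaluate(series, t)
  if (notch_depth > 0) {
    amp <- params$M - params$N
    u <- ((t / period) %% 1 - 0.55) / 0.10
    v <- v - ifelse(abs(u) <= 0.5,
                    notch_depth * amp * 0.5 * (1 + cos(2 * pi * u)), 0)
  }
  if (noise_sd > 0)
    v <- with_local_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
  list(waveform = waveform(t, v, artery = artery, subject = subject),
       truth = list(series = series,
                    beat_times = (0:cycles) * period,
                    extrema = fs_extrema(series),
                    params = params, noise_sd = noise_sd,
                    notch_depth = notch_depth))
}

#' Configuration of a synthetic TCD cohort
#'
#' Defaults encode the study conditions the generator emulates: systolic /
#' end-diastolic velocities within 30--120 / 15--90 cm/s, heart rates
#' 60--100 beats/min, measurement noise of SD 1 cm/s (consistent with the
#' +/- 3 cm/s fitting bandwidth), a dicrotic notch in half the patients at
#' 10 % of the pulse amplitude, and a per-patient morphological jitter of
#' 5 % SD on each harmonic coefficient so the cohort is not a pure affine
#' image of the template.
#'
#' @param n_patients Number of patients.
#' @param M_range,N_range Sampling intervals for CBFV_max / CBFV_min, cm/s.
#' @param H_range Heart-rate interval, beats/min.
#' @param noise_sd Gaussian noise SD, cm/s.
#' @param notch_probability Fraction of patients with a dicrotic notch.
#' @param notch_depth Notch depth as a fraction of pulse amplitude.
#' @param jitter_sd Relative SD of the per-patient multiplicative jitter
#'   applied to each harmonic coefficient of the template (0 disables).
#' @param cycles,rate_hz Per-waveform sampling, as in [synth_waveform()].
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100L,
                          M_range = c(30, 120), N_range = c(15, 90),
                          H_range = c(60, 100),
                          noise_sd = 1, notch_probability = 0.5,
                          notch_depth = 0.1, jitter_sd = 0.05,
                          cycles = 4L, rate_hz = 200, seed = 1L) {
  stopifnot(n_patients >= 1L,
            length(M_range) == 2L, M_range[1] < M_range[2],
            length(N_range) == 2L, N_range[1] < N_range[2],
            length(H_range) == 2L, H_range[1] < H_range[2], H_range[1] > 0,
            noise_sd >= 0, notch_probability >= 0, notch_probability <= 1,
            notch_depth >= 0, notch_depth < 1, jitter_sd >= 0,
            cycles >= 1L, rate_hz >= 50)
  structure(list(n_patients = as.integer(n_patients),
                 M_range = M_range, N_range = N_range, H_range = H_range,
                 noise_sd = noise_sd, notch_probability = notch_probability,
                 notch_depth = notch_depth, jitter_sd = jitter_sd,
                 cycles = as.integer(cycles), rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic TCD cohort
#'
#' Each patient has one heart rate (one heart) shared by nine artery
#' waveforms whose (M, N) pairs are drawn independently within the
#' configured ranges -- with N capped at 0.75 M so pulsatility stays
#' physiological -- plus one per-patient jittered copy of the standardized
#' template shared by all nine arteries. A per-patient Bernoulli draw turns
#' the dicrotic notch on for all of that patient's arteries. Deterministic
#' per seed.
#'
#' @param cfg A [cohort_config].
#' @return List of `cfg$n_patients` patients; each is a list with
#'   `subject`, `H`, `waveforms` (named list over [tcd_arteries()]) and
#'   `truth` (per-artery ground truth from [synth_waveform()]). The
#'   configuration is attached as attribute `config`.
#' @export
synth_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  arteries <- tcd_arteries()
  with_local_seed(cfg$seed, {
    patients <- lapply(seq_len(cfg$n_patients), function(i) {
      subject <- sprintf("P%03d", i)
      H <- stats::runif(1, cfg$H_range[1], cfg$H_range[2])
      notch_on <- stats::runif(1) < cfg$notch_probability
      shape <- v0()
      if (cfg$jitter_sd > 0) {
        shape$a <- shape$a * (1 + stats::rnorm(8, 0, cfg$jitter_sd))
        shape$b <- shape$b * (1 + stats::rnorm(8, 0, cfg$jitter_sd))
      }
      waves <- list(); truth <- list()
      for (a in arteries) {
        M <- stats::runif(1, cfg$M_range[1], cfg$M_range[2])
        N <- stats::runif(1, cfg$N_range[1], min(cfg$N_range[2], 0.75 * M))
        sw <- synth_waveform(
          patient_params(M, N, H, warn = FALSE),
          cycles = cfg$cycles, rate_hz = cfg$rate_hz,
          noise_sd = cfg$noise_sd,
          notch_depth = if (notch_on) cfg$notch_depth else 0,
          shape = shape, artery = a, subject = subject)
        waves[[a]] <- sw$waveform
        truth[[a]] <- sw$truth
      }
      list(subject = subject, H = H, waveforms = waves, truth = truth)
    })
    attr(patients, "config") <- cfg
    patients
  })
}
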