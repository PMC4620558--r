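#' Lightly smoothed copy of a waveform
#'
#' Running-median smoothing over roughly `window` seconds, used when
#' estimating beat boundaries and per-cycle extrema from noisy envelopes
#' (the raw samples are always kept for residual and deviation
#' computations). The sample maximum of a noisy trace is biased upwards by
#' several noise SDs; the running median suppresses that bias.
#'
#' @param w A [waveform].
#' @param window Smoothing window, seconds (default 0.025 s).
#' @return A smoothed [waveform].
#' @export
smooth_waveform <- function(w, window = 0.025) {
  stopifnot(inherits(w, "waveform"), window > 0)
  rate <- 1 / stats::median(diff(w$t))
  k <- max(3L, as.integer(round(window * rate)))
  if (k %% 2L == 0L) k <- k + 1L
  waveform(w$t, stats::runmed(w$v, k, endrule = "median"),
           artery = w$artery, subject = w$subject)
}

#' Estimate (M, N, H) from a measured waveform
#'
#' Heart rate is the reciprocal mean nadir spacing; M and N are the medians
#' of the per-cycle maxima and minima of a lightly smoothed copy of the
#' trace.
#'
#' @param w A [waveform].
#' @param window Smoothing window passed to [smooth_waveform()].
#' @return A [patient_params] object (inclusion-range warnings suppressed).
#' @export
estimate_params <- function(w, window = 0.025) {
  sm <- smooth_waveform(w, window)
  nad <- detect_nadirs(sm)
  cyc <- extract_cycles(sm, nad)
  patient_params(M = stats::median(vapply(cyc, `[[`, numeric(1), "vmax")),
                 N = stats::median(vapply(cyc, `[[`, numeric(1), "vmin")),
                 H = 60 / mean(diff(nad)),
                 warn = FALSE)
}

#' Deviation integral between a model and a measured waveform
#'
#' The agreement statistic: the definite integral over one second of the
#' absolute pointwise difference between the model curve and the measured
#' trace,
#' \deqn{\int_0^1 |V_{model}(t) - V_{measured}(t)|\,dt \quad [cm/s],}
#' with both signals aligned so that t = 0 is a measured nadir. Computed by
#' the trapezoid rule on a uniform grid (default 2000 points), measured
#' values linearly interpolated. If the record does not span a full second
#' past the nadir it is extended periodically over its detected whole
#' cycles.
#'
#' @param model A [fourier8] series (its own nadir sits at t = 0 by the
#'   standardization phase convention).
#' @param measured A [waveform].
#' @param t0 Optional alignment time (a measured nadir). When `NULL`, the
#'   first nadir detected on a smoothed copy is used.
#' @param grid_n Quadrature grid size.
#' @return The deviation integral, cm/s.
#' @export
deviation_integral <- function(model, measured, t0 = NULL, grid_n = 2000L) {
  stopifnot(inherits(model, "fourier8"), inherits(measured, "waveform"),
            grid_n >= 100L)
  nad <- NULL
  if (is.null(t0)) {
    nad <- detect_nadirs(smooth_waveform(measured))
    t0 <- nad[1L]
  }
  tt <- seq(0, 1, length.out = grid_n)
  tmax <- measured$t[length(measured$t)]
  if (t0 + 1 <= tmax) {
    q <- t0 + tt
  } else {
    if (is.null(nad)) nad <- detect_nadirs(smooth_waveform(measured))
    nad <- nad[nad >= t0]
    span <- nad[length(nad)] - t0
    if (length(nad) < 2L || span <= 0)
      stop("measured record cannot cover [0, 1] s, even extended periodically",
           call. = FALSE)
    q <- t0 + tt %% span
  }
  mv <- stats::approx(measured$t, measured$v, xout = q)$y
  pracma::trapz(tt, abs(fs_evaluate(model, tt) - mv))
}

#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Classic one-sample KS test of the values against a normal distribution
#' with the sample's own mean and SD, with the asymptotic p-value (the
#' SPSS-style one-sample KS; no Lilliefors correction for the estimated
#' parameters). Used as a screen justifying the t-based confidence interval
#' of the mean deviation integral.
#'
#' @param values Numeric vector, length >= 5.
#' @return The p-value, with the KS statistic D attached as attribute
#'   `statistic`.
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  stopifnot(all(is.finite(values)))
  if (length(values) < 5L) stop("need at least 5 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate sample: zero variance", call. = FALSE)
  kt <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values),
                   exact = FALSE))
  structure(unname(kt$p.value), statistic = unname(kt$statistic))
}

#' Two-sided 95 % t confidence interval of the mean
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector `c(lo, hi)`.
#' @export
ci95 <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  half <- stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n)
  c(m - half, m + half)
}

#' Validate patient-specific models against measured waveforms
#'
#' For every patient and artery the patient-specific model is built from
#' that waveform's own estimated parameters ([estimate_params()]: per-artery
#' M and N from smoothed per-cycle extrema, H from beat spacing) and
#' compared to the raw measured trace by [deviation_integral()]. Per artery,
#' across patients, the report gives the KS normality p-value, mean, SD and
#' 95 % t interval of the deviation integrals; an artery passes when the CI
#' upper bound is below `threshold` (default 3 cm/s), the criterion for
#' declaring model and measurement the same curve. Waveforms that fail
#' segmentation are skipped with a message; more than 10 % skipped aborts.
#'
#' @param patients List of patients, each a list with `waveforms`: a named
#'   list of the nine artery [waveform]s.
#' @param threshold Agreement threshold on the CI upper bound, cm/s.
#' @param grid_n Quadrature grid for the deviation integral.
#' @return A `validation_report`: data frame with one row per artery and
#'   columns `artery`, `n`, `mean`, `sd`, `ks_p`, `ci_lo`, `ci_hi`, `pass`.
#' @export
validate_cohort <- function(patients, threshold = 3, grid_n = 2000L) {
  stopifnot(length(patients) >= 1L)
  arteries <- names(patients[[1L]]$waveforms)
  if (is.null(arteries) || length(arteries) == 0L)
    stop("patients must carry a named list of artery waveforms",
         call. = FALSE)
  vals <- stats::setNames(
    replicate(length(arteries), numeric(0), simplify = FALSE), arteries)
  total <- 0L; skipped <- 0L
  for (p in patients) {
    if (!setequal(names(p$waveforms), arteries))
      stop("all patients must share the same artery set", call. = FALSE)
    for (a in arteries) {
      total <- total + 1L
      d <- tryCatch({
        w <- p$waveforms[[a]]
        nad <- detect_nadirs(smooth_waveform(w))
        model <- vx_transform(estimate_params(w))
        deviation_integral(model, w, t0 = nad[1L], grid_n = grid_n)
      }, error = function(e) {
        message("skipping ", a, " (", conditionMessage(e), ")")
        NA_real_
      })
      if (is.na(d)) skipped <- skipped + 1L
      else vals[[a]] <- c(vals[[a]], d)
    }
  }
  if (skipped > 0.1 * total)
    stop("cohort error: more than 10 % of waveforms were skipped",
         call. = FALSE)
  rows <- lapply(arteries, function(a) {
    x <- vals[[a]]
    ci <- ci95(x)
    data.frame(artery = a, n = length(x), mean = mean(x),
               sd = stats::sd(x),
               ks_p = if (length(x) >= 5L) as.numeric(ks_normality(x))
                      else NA_real_,
               ci_lo = ci[1L], ci_hi = ci[2L],
               pass = ci[2L] < threshold)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "threshold") <- threshold
  attr(rep, "skipped") <- skipped
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation report: %d arteries, n = %d patients, threshold %.3g cm/s\n",
    nrow(x), max(x$n), attr(x, "threshold")))
  print.data.frame(cbind(x[, c("artery", "n")],
                         round(x[, c("mean", "sd", "ks_p",
                                     "ci_lo", "ci_hi")], 3),
                         pass = x$pass),
                   row.names = FALSE)
  invisible(x)
}

#' Write a validation report as delimited text
#'
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
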