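#' Truncated eighth-order Fourier series
#'
#' Container for the harmonic model used throughout the package:
#' \deqn{V(t) = a_0 + \sum_{n=1}^{8} a_n \cos(n w t) + b_n \sin(n w t)}
#' with angular frequency `w` (rad/s), offset `a0` (cm/s) and eight cosine /
#' sine coefficient pairs (cm/s). The order is fixed at eight; lower-order
#' content is expressed by zero coefficients.
#'
#' @param w Angular frequency in rad/s; must be a single positive number.
#' @param a0 Constant (offset) term, cm/s.
#' @param a Numeric vector of 8 cosine coefficients `a1..a8`, cm/s.
#' @param b Numeric vector of 8 sine coefficients `b1..b8`, cm/s.
#' @return An object of class `fourier8`.
#' @seealso [v0()], [fs_evaluate()], [vx_transform()]
#' @export
#' @examples
#' s <- fourier8(w = 2 * pi, a0 = 60, a = c(-5, rep(0, 7)), b = rep(0, 8))
#' fs_evaluate(s, c(0, 0.25, 0.5))
fourier8 <- function(w, a0, a, b) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w),
            is.numeric(a0), length(a0) == 1L, is.finite(a0))
  if (w <= 0) stop("angular frequency `w` must be > 0", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 8L || length(b) != 8L)
    stop("`a` and `b` must each hold exactly 8 harmonic coefficients",
         call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("harmonic coefficients must be finite", call. = FALSE)
  structure(list(w = w, a0 = a0, a = a, b = b), class = "fourier8")
}

#' The standardized CBFV waveform model V0(t)
#'
#' Returns the cohort-averaged eighth-order Fourier model of a standardized
#' transcranial Doppler velocity waveform: cardiac cycle standardized to
#' 0.8 s and velocity range to 50--80 cm/s, coefficients obtained by
#' averaging 900 per-artery least-squares fits. The constants are built in;
#' no data are needed.
#'
#' Note that because the coefficients are averages over many fits, the
#' extrema of V0 are approximately -- not exactly -- 50 and 80 cm/s
#' (dense search gives about 50.12 and 79.87), and its period 2*pi/7.85 is
#' 0.80041 s, within 0.1 % of the standardized 0.8 s cycle.
#'
#' @return A [fourier8] object with `w = 7.85` rad/s and `a0 = 64.5` cm/s.
#' @export
#' @examples
#' v0()$a0          # 64.5 cm/s
#' fs_period(v0())  # ~0.8 s
v0 <- function() {
  fourier8(
    w  = 7.85,
    a0 = 64.5,
    a  = c(-5.154, -5.4516, -1.731, -1.5684,
           -0.50328, -0.10014, -0.035316, 0.16248),
    b  = c(10.962, 1.7574, -0.846, -0.23976,
           -1.0524, -0.30504, -0.3963, -0.17118)
  )
}

#' Evaluate a Fourier series at given times
#'
#' @param series A [fourier8] object.
#' @param t Numeric vector of times in seconds (any real; the series is
#'   periodic). Non-finite values are an error.
#' @return Numeric vector of velocities, cm/s.
#' @export
fs_evaluate <- function(series, t) {
  stopifnot(inherits(series, "fourier8"))
  t <- as.numeric(t)
  if (length(t) == 0L) return(numeric(0))
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  ph <- outer(t, seq_len(8L)) * series$w      # length(t) x 8 phase matrix
  drop(series$a0 + cos(ph) %*% series$a + sin(ph) %*% series$b)
}

#' Period of a Fourier series
#'
#' @param series A [fourier8] object.
#' @return The fundamental period 2*pi/w, seconds.
#' @export
fs_period <- function(series) {
  stopifnot(inherits(series, "fourier8"))
  2 * pi / series$w
}

#' Time-average of a Fourier series over one period
#'
#' By harmonic orthogonality every harmonic integrates to zero over a full
#' period, so the time-average equals the constant term `a0`.
#'
#' @param series A [fourier8] object.
#' @return Mean velocity over one period, cm/s.
#' @export
fs_mean <- function(series) {
  stopifnot(inherits(series, "fourier8"))
  series$a0
}

#' Global extrema of a Fourier series over one period
#'
#' Locates the global minimum and maximum of the series on `[0, period)` by
#' a dense grid scan (default 4096 points) followed by local refinement: a
#' root of the analytic derivative is bracketed around the best grid point
#' (falling back to golden-section optimization if no sign change brackets).
#'
#' @param series A [fourier8] object.
#' @param n_grid Number of grid points for the initial scan (>= 4096 by
#'   default).
#' @return A list with `vmin`, `tmin`, `vmax`, `tmax`; times reported in
#'   `[0, period)`.
#' @export
#' @examples
#' fs_extrema(v0())[c("vmin", "vmax")]  # ~50 and ~80 cm/s
fs_extrema <- function(series, n_grid = 4096L) {
  stopifnot(inherits(series, "fourier8"), n_grid >= 64L)
  P <- fs_period(series)
  tg <- seq(0, P, length.out = n_grid + 1L)[-(n_grid + 1L)]
  vg <- fs_evaluate(series, tg)
  dt <- P / n_grid
  ds <- fs_derivative(series)

  refine <- function(t0, maximum) {
    lo <- t0 - dt; hi <- t0 + dt
    dlo <- fs_evaluate(ds, lo); dhi <- fs_evaluate(ds, hi)
    if (is.finite(dlo) && is.finite(dhi) && dlo * dhi < 0) {
      r <- stats::uniroot(function(tt) fs_evaluate(ds, tt), c(lo, hi),
                          tol = .Machine$double.eps^0.75)
      cand <- r$root
    } else {
      cand <- stats::optimize(function(tt) fs_evaluate(series, tt),
                              c(lo, hi), maximum = maximum,
                              tol = 1e-12)[[1L]]
    }
    # keep the refinement only if it actually improves on the grid point
    v_cand <- fs_evaluate(series, cand)
    v_grid <- fs_evaluate(series, t0)
    better <- if (maximum) v_cand >= v_grid else v_cand <= v_grid
    if (better) cand else t0
  }

  tmin <- refine(tg[which.min(vg)], maximum = FALSE) %% P
  tmax <- refine(tg[which.max(vg)], maximum = TRUE) %% P
  list(vmin = fs_evaluate(series, tmin), tmin = tmin,
       vmax = fs_evaluate(series, tmax), tmax = tmax)
}

#' Term-wise analytic derivative of a Fourier series
#'
#' Differentiating term by term: the offset vanishes, cosine terms become
#' sines and vice versa, each scaled by `n*w`. The result is again an
#' eighth-order series (units cm/s^2). The sign of the derivative at a time
#' point classifies the instant as rising or falling flow velocity -- the
#' model's proxy for the instantaneous balance between cerebral perfusion
#' pressure and cerebrovascular resistance.
#'
#' @param series A [fourier8] object.
#' @return A [fourier8] object holding the derivative series.
#' @export
fs_derivative <- function(series) {
  stopifnot(inherits(series, "fourier8"))
  n <- seq_len(8L)
  fourier8(w = series$w, a0 = 0,
           a = n * series$w * series$b,
           b = -n * series$w * series$a)
}

#' Patient waveform parameters (M, N, H)
#'
#' The three numbers that index a patient-specific model: systolic peak
#' velocity `M` (CBFV_max, cm/s), end-diastolic trough `N` (CBFV_min, cm/s)
#' and heart rate `H` (beats/min). Values outside the derivation cohort's
#' inclusion window (M 30--120, N 15--90, H 60--100) raise a warning, not an
#' error, so the model can still be exercised outside that window.
#'
#' @param M Systolic maximum velocity, cm/s. Must exceed `N`.
#' @param N End-diastolic minimum velocity, cm/s. Must be positive.
#' @param H Heart rate, beats/min. Must be positive.
#' @param warn Emit the out-of-inclusion-range warning? Default `TRUE`.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(M, N, H, warn = TRUE) {
  stopifnot(is.numeric(M), is.numeric(N), is.numeric(H),
            length(M) == 1L, length(N) == 1L, length(H) == 1L,
            is.finite(M), is.finite(N), is.finite(H))
  if (N <= 0) stop("CBFV_min `N` must be > 0", call. = FALSE)
  if (M <= N) stop("CBFV_max `M` must exceed CBFV_min `N`", call. = FALSE)
  if (H <= 0) stop("heart rate `H` must be > 0", call. = FALSE)
  if (warn && (M < 30 || M > 120 || N < 15 || N > 90 || H < 60 || H > 100))
    warning("parameters outside the inclusion ranges ",
            "(M 30-120, N 15-90 cm/s, H 60-100 beats/min)", call. = FALSE)
  structure(list(M = M, N = N, H = H), class = "patient_params")
}

#' Patient-specific waveform model Vx(t)
#'
#' Rescales the standardized model affinely in time and amplitude to a
#' patient's parameters:
#' \deqn{V_x(t) = N + \frac{M - N}{30}\,(V_0(\phi t) - 50), \qquad
#'       \phi = \frac{0.8\,H}{60}}
#' implemented in closed form on the coefficients: `w' = w * H/75`,
#' `a0' = N + ((M-N)/30) * (a0 - 50)`, harmonics scaled by `(M-N)/30`.
#' Consequences: time-average `(14.5 M + 15.5 N)/30` cm/s, velocity range
#' approximately `N` to `M` (to the same tolerance as V0's 50/80), period
#' `2*pi/w'` within 0.1 % of `60/H` s. At `(M, N, H) = (80, 50, 75)` the
#' transform is the exact identity on `base`.
#'
#' @param params A [patient_params] object (or a list with `M`, `N`, `H`).
#' @param base Standardized base series to rescale; defaults to [v0()].
#' @return A [fourier8] object.
#' @export
#' @examples
#' vx <- vx_transform(patient_params(110, 80, 75))
#' fs_mean(vx)  # (14.5*110 + 15.5*80)/30 = 94.5
vx_transform <- function(params, base = v0()) {
  if (!inherits(params, "patient_params"))
    params <- patient_params(params$M, params$N, params$H)
  stopifnot(inherits(base, "fourier8"))
  s   <- (params$M - params$N) / 30
  phi <- params$H / 75          # == 0.8 * H / 60, exact at H = 75
  fourier8(w  = base$w * phi,
           a0 = params$N + s * (base$a0 - 50),
           a  = s * base$a,
           b  = s * base$b)
}

#' @export
coef.fourier8 <- function(object, ...) {
  stats::setNames(c(object$w, object$a0, object$a, object$b),
                  c("w", "a0", paste0("a", 1:8), paste0("b", 1:8)))
}

#' @export
print.fourier8 <- function(x, ...) {
  cat("Eighth-order Fourier series\n")
  cat(sprintf("  w  = %.6g rad/s  (period %.5g s)\n", x$w, fs_period(x)))
  cat(sprintf("  a0 = %.6g cm/s\n", x$a0))
  cat("  a1..a8:", paste(signif(x$a, 6), collapse = ", "), "\n")
  cat("  b1..b8:", paste(signif(x$b, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.patient_params <- function(x, ...) {
  cat(sprintf("Patient parameters: M = %g cm/s, N = %g cm/s, H = %g bpm\n",
              x$M, x$N, x$H))
  invisible(x)
}

#' Write / read Fourier coefficients as flat JSON
#'
#' Serializes a [fourier8] object to a flat key-value JSON file with keys
#' `w`, `a0`, `a1..a8`, `b1..b8` plus a free-form `metadata` block. Units
#' are fixed: rad/s for `w`, cm/s for the remaining coefficients.
#'
#' @param series A [fourier8] object.
#' @param path File path to write to / read from.
#' @param metadata Optional named list stored verbatim under `metadata`.
#' @return `write_fourier8()` returns `path` invisibly; `read_fourier8()`
#'   returns a [fourier8] object with the metadata attached as an attribute.
#' @export
write_fourier8 <- function(series, path, metadata = list()) {
  stopifnot(inherits(series, "fourier8"))
  co <- as.list(coef(series))
  co$metadata <- c(list(units_w = "rad/s", units_coef = "cm/s"), metadata)
  jsonlite::write_json(co, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fourier8
#' @export
read_fourier8 <- function(path) {
  co <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("w", "a0", paste0("a", 1:8), paste0("b", 1:8))
  if (!all(need %in% names(co)))
    stop("coefficient file is missing keys: ",
         paste(setdiff(need, names(co)), collapse = ", "), call. = FALSE)
  s <- fourier8(w = co$w, a0 = co$a0,
                a = unlist(co[paste0("a", 1:8)], use.names = FALSE),
                b = unlist(co[paste0("b", 1:8)], use.names = FALSE))
  attr(s, "metadata") <- co$metadata
  s
}
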