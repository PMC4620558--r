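#' Least-squares eighth-order Fourier fit of a cardiac cycle
#'
#' Fits the 17 linear coefficients (a0, a1..a8, b1..b8) by ordinary least
#' squares on the cycle's samples. With `fix_w = TRUE` the angular frequency
#' is pinned to `2*pi/duration`; otherwise it is refined by bounded scalar
#' minimization of the residual norm over `w` in
#' `[1 - w_bracket, 1 + w_bracket] * 2*pi/duration` (default +/- 10 %), the
#' inner problem remaining linear. Deterministic for fixed input.
#'
#' @param c A [cardiac_cycle], or any list with numeric `t`, `v` (and
#'   optionally `duration`, defaulting to the time span).
#' @param fix_w Pin `w` to the cycle-implied value? Default `FALSE`.
#' @param w_bracket Half-width of the relative search bracket for free `w`.
#' @return A list of class `fourier8_fit`: `series` (a [fourier8]), `rmse`
#'   and `max_resid` (cm/s), `fix_w`.
#' @export
#' @examples
#' cyc <- resample_cycle(standardize_cycle(
#'   cardiac_cycle(seq(0, 0.8, length.out = 200),
#'                 fs_evaluate(v0(), seq(0, 0.8, length.out = 200)))))
#' fit_fourier8(cyc)$series$w  # ~7.854
fit_fourier8 <- function(c, fix_w = FALSE, w_bracket = 0.1) {
  t <- as.numeric(c$t); v <- as.numeric(c$v)
  stopifnot(length(t) == length(v), all(is.finite(t)), all(is.finite(v)))
  if (length(t) < 34L)
    stop("need at least 34 samples (2x the 17 linear unknowns)",
         call. = FALSE)
  dur <- if (!is.null(c$duration)) c$duration else diff(range(t))
  w0 <- 2 * pi / dur

  solve_lin <- function(w) {
    ph <- outer(t, 1:8) * w
    X <- cbind(1, cos(ph), sin(ph))
    qx <- qr(X)
    if (qx$rank < 17L)
      stop("fit error: rank-deficient design (too few distinct times)",
           call. = FALSE)
    beta <- qr.coef(qx, v)
    res <- v - drop(X %*% beta)
    list(beta = beta, rss = sum(res^2), res = res)
  }

  w <- if (fix_w) w0 else
    stats::optimize(function(ww) solve_lin(ww)$rss,
                    interval = w0 * c(1 - w_bracket, 1 + w_bracket),
                    tol = 1e-10)$minimum
  sol <- solve_lin(w)
  series <- fourier8(w = w, a0 = sol$beta[1L],
                     a = sol$beta[2:9], b = sol$beta[10:17])
  structure(list(series = series,
                 rmse = sqrt(mean(sol$res^2)),
                 max_resid = max(abs(sol$res)),
                 fix_w = fix_w),
            class = "fourier8_fit")
}

#' @export
print.fourier8_fit <- function(x, ...) {
  cat(sprintf("Fourier fit (%s w): rmse %.4g cm/s, max |resid| %.4g cm/s\n",
              if (x$fix_w) "fixed" else "free", x$rmse, x$max_resid))
  print(x$series)
  invisible(x)
}

#' Check the fitting-bandwidth criterion
#'
#' A fit is acceptable when every raw sample lies within a +/- `tol` cm/s
#' band (default 3 cm/s) around the fitted curve.
#'
#' @param c A [cardiac_cycle] (or list with `t`, `v`).
#' @param s A [fourier8] series.
#' @param tol Band half-width, cm/s.
#' @return List with `pass` (logical) and `max_resid` (cm/s).
#' @export
check_bandwidth <- function(c, s, tol = 3) {
  stopifnot(inherits(s, "fourier8"), tol >= 0)
  r <- as.numeric(c$v) - fs_evaluate(s, as.numeric(c$t))
  list(pass = max(abs(r)) <= tol, max_resid = max(abs(r)))
}

#' Average fitted coefficients into a standardized model
#'
#' Computes the arithmetic mean and standard deviation of each of the 18
#' coefficients (w, a0, a1..a8, b1..b8) across fits, yielding the cohort's
#' standardized model and a coefficient report. With a single fit the SDs
#' are zero.
#'
#' @param fits Non-empty list of [fourier8] objects or `fourier8_fit`
#'   results.
#' @return List with `series` (the mean [fourier8]), `sd` (named numeric,
#'   length 18) and `table` (data frame with columns `coefficient`, `mean`,
#'   `sd`).
#' @export
average_coefficients <- function(fits) {
  if (length(fits) == 0L) stop("no fits to average", call. = FALSE)
  series <- lapply(fits, function(f)
    if (inherits(f, "fourier8_fit")) f$series else f)
  stopifnot(all(vapply(series, inherits, logical(1), "fourier8")))
  cm <- vapply(series, coef, numeric(18L))          # 18 x k
  mu <- rowMeans(cm)
  sd <- if (ncol(cm) == 1L) stats::setNames(rep(0, 18L), rownames(cm))
        else apply(cm, 1L, stats::sd)
  list(series = fourier8(w = mu[["w"]], a0 = mu[["a0"]],
                         a = mu[paste0("a", 1:8)], b = mu[paste0("b", 1:8)]),
       sd = sd,
       table = data.frame(coefficient = names(mu), mean = unname(mu),
                          sd = unname(sd)))
}

#' Derive a standardized model from a set of waveforms
#'
#' The full derivation pipeline: each waveform is segmented into cardiac
#' cycles ([detect_nadirs()], [extract_cycles()]), its beats standardized
#' and condensed into one representative median beat ([median_cycle()]),
#' which is fitted by [fit_fourier8()]; the per-waveform fits are then
#' averaged coefficient-wise ([average_coefficients()]). Waveforms that fail
#' segmentation or fitting are skipped with a warning.
#'
#' @param waveforms List of [waveform] objects.
#' @param fix_w Passed to [fit_fourier8()].
#' @param n Resampling grid size per beat.
#' @return As [average_coefficients()], plus `n_waves` (fits used) and
#'   `skipped` (count).
#' @export
derive_model <- function(waveforms, fix_w = FALSE, n = 200L) {
  stopifnot(length(waveforms) >= 1L)
  fits <- list(); skipped <- 0L
  for (w in waveforms) {
    f <- tryCatch({
      cyc <- extract_cycles(w, detect_nadirs(w))
      fit_fourier8(median_cycle(cyc, n = n), fix_w = fix_w)
    }, error = function(e) {
      warning("skipping waveform (", conditionMessage(e), ")",
              call. = FALSE)
      NULL
    })
    if (is.null(f)) skipped <- skipped + 1L else fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    stop("no waveform could be fitted", call. = FALSE)
  out <- average_coefficients(fits)
  out$n_waves <- length(fits)
  out$skipped <- skipped
  out
}

#' Write a coefficient report table
#'
#' Tab-separated text with columns `coefficient`, `mean`, `sd`.
#'
#' @param avg Result of [average_coefficients()] or [derive_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficient_table <- function(avg, path) {
  utils::write.table(avg$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
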