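#' Standardize a cardiac cycle to the canonical 0.8 s / 50--80 cm/s frame
#'
#' Applies the four-step standardization: time is mapped affinely so the
#' first nadir sits at 0 s and the second at 0.8 s; velocity is mapped
#' affinely so the cycle's nadir becomes 50 cm/s and its zenith (per-cycle
#' global maximum) 80 cm/s:
#' \deqn{v' = 50 + 30\,(v - v_{min})/(v_{max} - v_{min})}
#' The returned cycle has duration 0.8 s and extrema exactly (50, 80) by
#' construction; an already standardized cycle is returned unchanged, making
#' the operation exactly idempotent. Standardization is invariant to affine
#' changes of the input's time and velocity scales.
#'
#' @param c A [cardiac_cycle].
#' @return A standardized [cardiac_cycle].
#' @export
standardize_cycle <- function(c) {
  stopifnot(inherits(c, "cardiac_cycle"))
  if (c$vmax <= c$vmin)
    stop("degenerate amplitude: vmax must exceed vmin", call. = FALSE)
  if (c$duration == 0.8 && c$vmin == 50 && c$vmax == 80) return(c)
  t2 <- c$t * (0.8 / c$duration)
  t2[length(t2)] <- 0.8
  v2 <- 50 + 30 * (c$v - c$vmin) / (c$vmax - c$vmin)
  cardiac_cycle(t2, v2, in_range = c$in_range)
}

#' Resample a cycle onto a uniform grid
#'
#' Piecewise-linear interpolation onto `n` uniformly spaced points spanning
#' `[0, duration]`. Standardized cycles are resampled to a common 200-point
#' grid on `[0, 0.8]` before fitting so all fits share one design matrix;
#' 200 points comfortably over-determine the 17 linear unknowns.
#'
#' @param c A [cardiac_cycle].
#' @param n Number of grid points (default 200).
#' @return A [cardiac_cycle] on the uniform grid.
#' @export
resample_cycle <- function(c, n = 200L) {
  stopifnot(inherits(c, "cardiac_cycle"), n >= 34L)
  tt <- seq(0, c$duration, length.out = n)
  vv <- stats::approx(c$t, c$v, xout = tt)$y
  cardiac_cycle(tt, vv, in_range = c$in_range)
}

#' Representative beat of a multi-cycle recording
#'
#' Each beat is standardized independently and resampled to the common
#' grid; the representative standardized cycle is the per-time-point median
#' across beats, which is robust to occasional outlier beats.
#'
#' @param cycles List of [cardiac_cycle] objects (raw, as from
#'   [extract_cycles()]).
#' @param n Grid size passed to [resample_cycle()].
#' @return A standardized [cardiac_cycle] on the uniform grid.
#' @export
median_cycle <- function(cycles, n = 200L) {
  stopifnot(length(cycles) >= 1L)
  std <- lapply(cycles, function(c) resample_cycle(standardize_cycle(c), n))
  vmat <- vapply(std, function(c) c$v, numeric(n))
  cardiac_cycle(std[[1L]]$t, apply(vmat, 1L, stats::median))
}
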