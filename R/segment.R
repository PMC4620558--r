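#' Detect cardiac-cycle boundary nadirs in a waveform
#'
#' Cycle boundaries are the end-diastolic minima. Candidate local minima
#' (including record boundaries) are screened by topographic prominence --
#' the drop from the lower of the two flanking peaks -- so that shallow
#' dicrotic-notch minima on the descending limb are rejected. Candidates
#' closer together than one cycle at `max_rate` are merged, keeping the
#' deeper minimum (earliest on ties).
#'
#' @param w A [waveform] object.
#' @param min_rate,max_rate Plausible heart-rate band, beats/min; admissible
#'   nadir spacing is `[60/max_rate, 60/min_rate]` s. Defaults bracket the
#'   60--100 beats/min inclusion window generously.
#' @param prominence_frac Minimum prominence as a fraction of the waveform's
#'   global peak-to-peak range; default 0.25.
#' @return Numeric vector (length >= 2) of nadir sample times, seconds.
#' @export
detect_nadirs <- function(w, min_rate = 40, max_rate = 150,
                          prominence_frac = 0.25) {
  stopifnot(inherits(w, "waveform"), min_rate > 0, max_rate > min_rate)
  v <- w$v; t <- w$t; n <- length(v)
  rng <- max(v) - min(v)
  if (rng <= 0)
    stop("segmentation error: constant signal has no cardiac cycles",
         call. = FALSE)
  if (t[n] - t[1] < 2 * 60 / max_rate)
    stop("segmentation error: record shorter than two cycles at max_rate",
         call. = FALSE)

  # candidate minima, boundaries included
  is_min <- logical(n)
  is_min[1] <- v[1] <= v[2]
  is_min[n] <- v[n] <= v[n - 1]
  if (n > 2L) {
    mid <- 2:(n - 1L)
    is_min[mid] <- v[mid] <= v[mid - 1L] & v[mid] < v[mid + 1L]
  }
  cand <- which(is_min)

  prominence <- function(i) {
    side_peak <- function(idx) {
      if (length(idx) == 0L) return(Inf)        # record boundary acts as wall
      pk <- -Inf
      for (j in idx) {
        if (v[j] < v[i]) break
        pk <- max(pk, v[j])
      }
      if (is.finite(pk)) pk else Inf
    }
    lp <- side_peak(rev(seq_len(i - 1L)))
    rp <- side_peak(seq.int(i + 1L, length.out = n - i))
    min(lp, rp) - v[i]
  }
  prom <- vapply(cand, prominence, numeric(1))
  cand <- cand[prom >= prominence_frac * rng]

  # enforce minimum spacing, keeping the deeper minimum
  min_gap <- 60 / max_rate
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && t[i] - t[keep[length(keep)]] < min_gap) {
      if (v[i] < v[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  if (length(keep) < 2L)
    stop("segmentation error: fewer than 2 cycle boundaries found",
         call. = FALSE)
  t[keep]
}

#' One nadir-to-nadir cardiac cycle
#'
#' @param t Times re-based so the first nadir is 0 s.
#' @param v Velocities, cm/s.
#' @param in_range Is the duration inside the 0.6--1.0 s window implied by
#'   heart rates of 60--100 beats/min?
#' @return An object of class `cardiac_cycle` with fields `t`, `v`,
#'   `duration`, `vmin`, `vmax`, `in_range`.
#' @export
cardiac_cycle <- function(t, v, in_range = NA) {
  t <- as.numeric(t); v <- as.numeric(v)
  stopifnot(length(t) == length(v), length(t) >= 3L,
            all(is.finite(t)), all(is.finite(v)))
  if (t[1] != 0) stop("cycle times must start at 0", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("cycle times must be strictly increasing", call. = FALSE)
  vmin <- min(v); vmax <- max(v)
  if (vmax <= vmin)
    stop("degenerate cycle: vmax must exceed vmin", call. = FALSE)
  dur <- t[length(t)]
  if (is.na(in_range)) in_range <- dur >= 0.6 && dur <= 1.0
  structure(list(t = t, v = v, duration = dur,
                 vmin = vmin, vmax = vmax, in_range = in_range),
            class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("Cardiac cycle: %.4g s, %.1f-%.1f cm/s, %d samples%s\n",
              x$duration, x$vmin, x$vmax, length(x$t),
              if (x$in_range) "" else " [duration outside 0.6-1.0 s]"))
  invisible(x)
}

#' Split a waveform into cardiac cycles at given nadir times
#'
#' One [cardiac_cycle] is produced per consecutive nadir pair, re-based so
#' its first sample is at 0 s. Cycles whose duration falls outside the
#' 0.6--1.0 s window (heart rate 60--100 beats/min) are flagged via
#' `in_range = FALSE` but retained.
#'
#' @param w A [waveform] object.
#' @param nadirs Nadir times as returned by [detect_nadirs()].
#' @return List of [cardiac_cycle] objects.
#' @export
extract_cycles <- function(w, nadirs) {
  stopifnot(inherits(w, "waveform"))
  if (length(nadirs) < 2L)
    stop("need at least 2 nadir times", call. = FALSE)
  idx <- vapply(nadirs, function(tn) which.min(abs(w$t - tn)), integer(1))
  lapply(seq_len(length(idx) - 1L), function(k) {
    seg <- idx[k]:idx[k + 1L]
    cardiac_cycle(w$t[seg] - w$t[idx[k]], w$v[seg])
  })
}
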