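#' Sampled TCD envelope waveform
#'
#' A sampled time--velocity trace of a transcranial Doppler envelope (raw or
#' synthetic). Times must be strictly increasing and velocities strictly
#' positive (a flow envelope); at least 8 samples are required.
#'
#' @param t Sample times, seconds.
#' @param v Velocities, cm/s.
#' @param artery Optional artery label (e.g. `"MCA_L"`). The nine standard
#'   sites are left/right anterior, middle and posterior cerebral, left/right
#'   vertebral, and basilar.
#' @param subject Optional subject identifier.
#' @return An object of class `waveform`.
#' @export
waveform <- function(t, v, artery = NA_character_, subject = NA_character_) {
  t <- as.numeric(t); v <- as.numeric(v)
  if (length(t) != length(v))
    stop("`t` and `v` must have equal length", call. = FALSE)
  if (length(t) < 8L)
    stop("waveform needs at least 8 samples", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(v)))
    stop("waveform samples must be finite", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("sample times must be strictly increasing", call. = FALSE)
  if (any(v <= 0))
    stop("velocities must be strictly positive (flow envelope)",
         call. = FALSE)
  structure(list(t = t, v = v,
                 artery = as.character(artery),
                 subject = as.character(subject)),
            class = "waveform")
}

#' The nine standard TCD recording sites
#'
#' Left/right anterior (ACA), middle (MCA) and posterior (PCA) cerebral
#' arteries, left/right vertebral arteries (VA) and the basilar artery (BA).
#'
#' @return Character vector of nine artery labels.
#' @export
tcd_arteries <- function() {
  c("ACA_L", "ACA_R", "MCA_L", "MCA_R", "PCA_L", "PCA_R",
    "VA_L", "VA_R", "BA")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("TCD waveform [%s / %s]: %d samples, %.3g-%.3g s, %.1f-%.1f cm/s\n",
              x$subject, x$artery, length(x$t),
              min(x$t), max(x$t), min(x$v), max(x$v)))
  invisible(x)
}

#' Read / write waveform files
#'
#' Waveforms are exchanged as two-column delimited text with the header
#' `time_s,velocity_cm_s`. Subject and artery labels default to the
#' `<subject>_<artery>.csv` filename pattern.
#'
#' @param path File path.
#' @param artery,subject Optional labels overriding the filename pattern.
#' @param w A [waveform] object.
#' @return `read_waveform()` returns a [waveform]; `write_waveform()` returns
#'   `path` invisibly.
#' @export
read_waveform <- function(path, artery = NULL, subject = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "velocity_cm_s") %in% names(d)))
    stop("expected columns `time_s` and `velocity_cm_s` in ", path,
         call. = FALSE)
  base <- sub("\\.[^.]*$", "", basename(path))
  parts <- regmatches(base, regexpr("_", base), invert = TRUE)[[1L]]
  if (is.null(subject)) subject <- if (length(parts) == 2L) parts[1L] else base
  if (is.null(artery))  artery  <- if (length(parts) == 2L) parts[2L] else NA
  waveform(d$time_s, d$velocity_cm_s, artery = artery, subject = subject)
}

#' @rdname read_waveform
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  utils::write.csv(data.frame(time_s = w$t, velocity_cm_s = w$v),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
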