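#' Uniformly sampled waveform
#'
#' A `waveform` is a numeric vector of finite samples carrying its sampling
#' rate (`fs_hz`) and units as attributes. It is the container every signal
#' stage of the package consumes and returns: PPG, ABP, derivatives, IMFs.
#'
#' @param samples Numeric vector of finite samples, length >= 2.
#' @param fs_hz Sampling rate in Hz, > 0.
#' @param units Unit string, e.g. `"a.u."` or `"mmHg"`.
#'
#' @return An object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 125)), fs_hz = 125)
#' duration_s(w)
#' @export
waveform <- function(samples, fs_hz, units = "a.u.") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    stop("waveform needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("waveform samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || !is.finite(fs_hz) || fs_hz <= 0) {
    stop("fs_hz must be a single positive number", call. = FALSE)
  }
  structure(samples, fs_hz = fs_hz, units = units, class = "waveform")
}

#' @rdname waveform
#' @param w A `waveform`.
#' @export
fs_hz <- function(w) attr(w, "fs_hz")

#' @rdname waveform
#' @export
duration_s <- function(w) length(w) / fs_hz(w)

#' @rdname waveform
#' @export
wave_units <- function(w) attr(w, "units")

# Rebuild a waveform from new samples, keeping metadata from a template.
rewave <- function(samples, template, units = NULL) {
  waveform(samples, fs_hz = fs_hz(template),
           units = if (is.null(units)) wave_units(template) else units)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3g s), units: %s\n",
              length(x), fs_hz(x), duration_s(x), wave_units(x)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

#' Waveform as a tidy table
#'
#' @param w A `waveform`.
#' @return A tibble with columns `time_s` and `value`.
#' @export
wave_tbl <- function(w) {
  tibble::tibble(time_s = (seq_along(w) - 1) / fs_hz(w), value = as.numeric(w))
}

#' @export
autoplot.waveform <- function(object, ...) {
  ggplot2::ggplot(wave_tbl(object), ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = wave_units(object))
}
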