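#' Analytic signal and instantaneous attributes
#'
#' Computes the discrete analytic signal in the frequency domain (negative
#' frequencies zeroed, positive doubled, DC and Nyquist kept) and derives
#' per-sample instantaneous amplitude (envelope, the modulus) and
#' instantaneous frequency (forward difference of the unwrapped phase times
#' `fs / 2*pi`, clamped at 0 and median-smoothed over 5 samples to tame
#' unwrap glitches).
#'
#' @param wave A [waveform()] (typically an IMF).
#' @return An `inst_attributes` list with numeric fields `amplitude`,
#'   `frequency_hz` (both the length of the input) and `fs_hz`.
#' @details
#' The discrete transform sees the segment as circular, so a non-periodic
#' oscillation has a wrap discontinuity whose leakage corrupts the envelope
#' and phase well into the segment. Before transforming, the signal is
#' therefore extended on both sides with its characteristic wave: the cubic
#' spline interpolant reflected about the sub-sample position of the first
#' and last interior extremum, which continues an oscillation smoothly
#' (exactly, for a pure tone). The extension is cropped off after the
#' transform. Signals with fewer than two extrema are transformed as-is.
#'
#' @examples
#' t <- seq(0, 5, by = 1 / 125)
#' ia <- analytic_signal(waveform(1.5 * sin(2 * pi * 2 * t), fs_hz = 125))
#' mean(ia$amplitude[100:500]) # ~1.5
#' @export
analytic_signal <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  x <- as.numeric(wave)
  fs <- fs_hz(wave)
  n <- length(x)

  ext <- extend_characteristic(x)
  ne <- length(ext$x)
  h <- numeric(ne)
  if (ne %% 2 == 0) {
    h[1] <- 1; h[ne / 2 + 1] <- 1
    h[2:(ne / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((ne + 1) / 2)] <- 2
  }
  z <- (fft(fft(ext$x) * h, inverse = TRUE) / ne)[(ext$offset + 1):(ext$offset + n)]
  amplitude <- Mod(z)

  phase <- unwrap_phase(Arg(z))
  freq <- c(diff(phase), 0) * fs / (2 * pi)
  freq[n] <- freq[n - 1]
  freq <- pmax(freq, 0)
  if (n >= 5) {
    freq <- as.numeric(stats::runmed(freq, k = 5, endrule = "median"))
  }
  structure(list(amplitude = amplitude, frequency_hz = freq, fs_hz = fs),
            class = "inst_attributes")
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Quadratic-fit sub-sample position of the extremum at sample i.
subsample_extremum <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(as.numeric(i))
  den <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (abs(den) < 1e-12) return(as.numeric(i))
  i + 0.5 * (x[i - 1] - x[i + 1]) / den
}

# Characteristic-wave extension: reflect the spline interpolant about the
# sub-sample first/last extremum so the oscillation continues smoothly past
# both ends; returns the extended signal and the left offset.
extend_characteristic <- function(x) {
  n <- length(x)
  ex <- find_extrema(x)
  all_ex <- sort(c(ex$max, ex$min))
  if (length(all_ex) < 2) return(list(x = x, offset = 0L))
  sf <- stats::splinefun(seq_len(n), x, method = "fmm")
  t_s <- subsample_extremum(x, all_ex[1])
  t_e <- subsample_extremum(x, all_ex[length(all_ex)])
  mL <- max(0L, min(floor(n - 2 * t_s + 1), n))
  mR <- max(0L, min(floor(2 * t_e - n - 1), n))
  lv <- if (mL > 0) sf(2 * t_s - ((1 - mL):0)) else numeric(0)
  rv <- if (mR > 0) sf(2 * t_e - ((n + 1):(n + mR))) else numeric(0)
  list(x = c(lv, x, rv), offset = as.integer(mL))
}

#' Binned Hilbert (time–frequency–energy) spectrum
#'
#' Accumulates, for every IMF and sample, the instantaneous amplitude into
#' the (time, frequency) cell given by the sample index and the binned
#' instantaneous frequency. Samples whose frequency falls outside
#' `[0, freq_max_hz]` are discarded. The default grid is 130 frequency bins
#' of 0.1 Hz over 0–13 Hz by one time bin per sample — finer than the
#' rendered image, so rendering only ever aggregates.
#'
#' @param imfs A list of [waveform()]s sharing sampling rate and length, or
#'   an `emd_result` (its IMFs are used).
#' @param freq_max_hz Upper frequency edge (default 13 Hz).
#' @param freq_bin_hz Frequency bin width (default 0.1 Hz).
#' @return A `hilbert_spectrum`: list with `matrix` (freq bins x time bins,
#'   row 1 = lowest frequency), `freq_max_hz`, `freq_bin_hz`, `duration_s`,
#'   `fs_hz`.
#' @export
hilbert_spectrum <- function(imfs, freq_max_hz = 13, freq_bin_hz = 0.1) {
  if (inherits(imfs, "emd_result")) imfs <- imfs$imfs
  if (!is.list(imfs) || length(imfs) == 0) {
    stop("need a non-empty list of IMFs", call. = FALSE)
  }
  fs <- fs_hz(imfs[[1]])
  n_t <- length(imfs[[1]])
  ok <- purrr::every(imfs, ~ inherits(.x, "waveform") &&
                       fs_hz(.x) == fs && length(.x) == n_t)
  if (!ok) stop("all IMFs must share sampling rate and length", call. = FALSE)

  n_f <- round(freq_max_hz / freq_bin_hz)
  mat <- matrix(0, nrow = n_f, ncol = n_t)
  for (imf in imfs) {
    ia <- analytic_signal(imf)
    fbin <- floor(ia$frequency_hz / freq_bin_hz) + 1L
    fbin[ia$frequency_hz == freq_max_hz] <- n_f  # closed upper edge
    keep <- which(fbin >= 1L & fbin <= n_f)
    if (length(keep)) {
      idx <- cbind(fbin[keep], keep)
      vals <- ia$amplitude[keep]
      # accumulate duplicates (same cell hit by several IMFs/samples)
      mat[idx] <- mat[idx] + vals
    }
  }
  structure(list(matrix = mat, freq_max_hz = freq_max_hz,
                 freq_bin_hz = freq_bin_hz,
                 duration_s = n_t / fs, fs_hz = fs),
            class = "hilbert_spectrum")
}

#' @export
print.hilbert_spectrum <- function(x, ...) {
  cat(sprintf("<hilbert_spectrum> %d freq bins x %d time bins, 0-%g Hz, %g s\n",
              nrow(x$matrix), ncol(x$matrix), x$freq_max_hz, x$duration_s))
  invisible(x)
}

#' Render a spectrum as an 8-bit grayscale channel
#'
#' Nearest-neighbour resamples the spectrum onto a `height x width` pixel
#' grid (frequency increasing upward, time rightward) and scales linearly so
#' the maximum amplitude maps to 255 and zero to 0. An all-zero spectrum
#' renders as an all-zero image.
#'
#' @param spec A [hilbert_spectrum()].
#' @param width,height Output pixel dimensions (defaults 1247 x 770).
#' @return An integer matrix `height x width` with values in 0..255; row 1
#'   is the top of the image (highest frequency).
#' @export
render_channel <- function(spec, width = 1247, height = 770) {
  stopifnot(inherits(spec, "hilbert_spectrum"))
  m <- spec$matrix
  n_f <- nrow(m); n_t <- ncol(m)
  # pixel-centre nearest-neighbour source indices; row 1 = top = freq_max
  src_f <- pmin(pmax(ceiling((1 - (seq_len(height) - 0.5) / height) * n_f), 1L), n_f)
  src_t <- pmin(pmax(ceiling((seq_len(width) - 0.5) / width * n_t), 1L), n_t)
  img <- m[src_f, src_t, drop = FALSE]
  mx <- max(img)
  if (mx > 0) img <- img / mx * 255
  matrix(as.integer(round(img)), nrow = height, ncol = width)
}

#' Write a grayscale channel image to PNG
#'
#' @param channel Integer matrix in 0..255 from [render_channel()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_channel_png <- function(channel, path) {
  png::writePNG(channel / 255, path)
  invisible(path)
}

#' @export
autoplot.hilbert_spectrum <- function(object, ...) {
  m <- object$matrix
  df <- tibble::tibble(
    time_s = rep((seq_len(ncol(m)) - 0.5) / ncol(m) * object$duration_s,
                 each = nrow(m)),
    freq_hz = rep((seq_len(nrow(m)) - 0.5) * object$freq_bin_hz,
                  times = ncol(m)),
    amplitude = as.numeric(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "amplitude")
}
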