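#' @name emd
#' @title Empirical mode decomposition by envelope sifting
#'
#' @description
#' Decomposes a waveform into intrinsic mode functions (IMFs) and a residue
#' by iterative sifting: at each step the mean of the cubic-spline upper
#' (through local maxima) and lower (through local minima) envelopes is
#' subtracted until the candidate satisfies the IMF conditions — extrema and
#' zero-crossing counts differing by at most one, and a locally
#' near-zero envelope mean. Sifting stops on a Cauchy criterion
#' (`sd_threshold`, normalised energy of the last correction) or after
#' `max_sift_iters`; extraction stops when the residue has too few extrema
#' to sift or `max_imfs` is reached.
#'
#' IMFs are ordered high to low frequency; `sum(imfs) + residue`
#' reconstructs the input to numerical precision by construction.
NULL

# Interior local maxima/minima indices, tolerant of short plateaus
# (the last sample of a plateau before the sign change is taken).
find_extrema <- function(x) {
  s <- sign(diff(x))
  idx <- which(s != 0)
  if (length(idx) < 2) return(list(max = integer(0), min = integer(0)))
  s2 <- s[idx]
  ch <- which(diff(s2) != 0)
  pos <- idx[ch] + 1L
  typ <- s2[ch]
  list(max = pos[typ > 0], min = pos[typ < 0])
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

# Spline envelope through the given extrema with the two edge extrema
# mirrored beyond each end, evaluated on 1..n.
spline_envelope <- function(x, idx, n) {
  k <- min(2, length(idx))
  left_idx <- idx[seq_len(k)]
  right_idx <- rev(idx)[seq_len(k)]
  px <- c(2 - left_idx, idx, 2 * n - right_idx)
  py <- c(x[left_idx], x[idx], x[right_idx])
  o <- order(px)
  px <- px[o]; py <- py[o]
  keep <- !duplicated(px)
  spline(px[keep], py[keep], xout = seq_len(n))$y
}

envelope_mean_num <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
  n <- length(x)
  (spline_envelope(x, ex$max, n) + spline_envelope(x, ex$min, n)) / 2
}

#' Mean of the upper and lower spline envelopes
#'
#' @param wave A [waveform()] with at least 2 maxima and 2 minima.
#' @return A [waveform()] holding the envelope mean.
#' @export
envelope_mean <- function(wave) {
  stopifnot(inherits(wave, "waveform"))
  m <- envelope_mean_num(as.numeric(wave))
  if (is.null(m)) {
    stop("signal has too few extrema to form envelopes (not siftable)",
         call. = FALSE)
  }
  rewave(m, wave)
}

#' Test the intrinsic-mode-function conditions
#'
#' TRUE iff the numbers of extrema and zero crossings differ by at most one
#' and the envelope mean is small everywhere (at most `rel_tol` times the
#' signal's peak magnitude — the sifting loop drives it toward zero, never
#' exactly to zero on real data).
#'
#' @param wave A [waveform()].
#' @param rel_tol Envelope-mean tolerance relative to `max(abs(wave))`.
#' @return Logical scalar.
#' @export
is_imf <- function(wave, rel_tol = 0.1) {
  x <- as.numeric(wave)
  ex <- find_extrema(x)
  n_ex <- length(ex$max) + length(ex$min)
  if (abs(n_ex - count_zero_crossings(x)) > 1) return(FALSE)
  m <- envelope_mean_num(x)
  if (is.null(m)) return(FALSE)
  max(abs(m)) <= rel_tol * max(abs(x))
}

#' @rdname emd
#' @param wave A [waveform()] (finite, length >= 16).
#' @param sd_threshold Cauchy stopping ratio for sifting (default 0.2).
#' @param max_sift_iters Sifting iteration cap per IMF (default 50).
#' @param max_imfs Maximum number of IMFs to extract (default 10).
#' @return An `emd_result`: list with `imfs` (list of [waveform()]s, high to
#'   low frequency) and `residue` (a [waveform()]).
#' @examples
#' t <- seq(0, 10, by = 1 / 125)
#' w <- waveform(sin(2 * pi * 5 * t) + sin(2 * pi * 0.5 * t), fs_hz = 125)
#' dec <- emd(w)
#' length(dec$imfs)
#' @export
emd <- function(wave, sd_threshold = 0.2, max_sift_iters = 50, max_imfs = 10) {
  stopifnot(inherits(wave, "waveform"))
  x <- as.numeric(wave)
  if (length(x) < 16) stop("signal too short for EMD (need >= 16 samples)", call. = FALSE)
  if (!all(is.finite(x))) stop("signal must be finite", call. = FALSE)
  if (sd_threshold <= 0) stop("sd_threshold must be positive", call. = FALSE)

  r <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    h <- r
    m <- envelope_mean_num(h)
    if (is.null(m)) break  # residue no longer siftable
    for (it in seq_len(max_sift_iters)) {
      h_new <- h - m
      sd_ratio <- sum(m^2) / (sum(h^2) + .Machine$double.eps)
      h <- h_new
      if (sd_ratio < sd_threshold) break
      m <- envelope_mean_num(h)
      if (is.null(m)) break
    }
    imfs[[length(imfs) + 1]] <- h
    r <- r - h
  }
  new_emd_result(imfs, r, wave)
}

new_emd_result <- function(imfs_num, residue_num, template) {
  structure(list(
    imfs = purrr::map(imfs_num, rewave, template = template),
    residue = rewave(residue_num, template)
  ), class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMFs + residue, %d samples @ %g Hz\n",
              length(x$imfs), length(x$residue), fs_hz(x$residue)))
  invisible(x)
}

#' Reconstruct the input of a decomposition
#'
#' @param result An `emd_result`.
#' @return The [waveform()] `sum(imfs) + residue`.
#' @export
reconstruct <- function(result) {
  stopifnot(inherits(result, "emd_result"))
  acc <- as.numeric(result$residue)
  for (imf in result$imfs) acc <- acc + as.numeric(imf)
  rewave(acc, result$residue)
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the signal, each perturbed with
#' fresh seeded white Gaussian noise of standard deviation
#' `noise_std * sd(wave)`, and averages IMF k across members (shorter
#' decompositions padded with zero IMFs). The added noise populates the
#' whole time–frequency plane so intermittent components stop hopping
#' between IMFs (mode mixing); averaging cancels the noise itself. The
#' residue is defined as `wave - sum(averaged IMFs)`, preserving the exact
#' reconstruction identity.
#'
#' @inheritParams emd
#' @param ensemble_size Number of noise realisations (default 100).
#' @param noise_std Noise level as a fraction of the signal's standard
#'   deviation (default 0.2). With `noise_std = 0` and `ensemble_size = 1`
#'   the result equals [emd()].
#' @param seed Integer seed; member seeds are derived deterministically.
#' @return An `emd_result`.
#' @export
eemd <- function(wave, ensemble_size = 100, noise_std = 0.2, seed = 1L,
                 sd_threshold = 0.2, max_sift_iters = 50, max_imfs = 10) {
  stopifnot(inherits(wave, "waveform"))
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  x <- as.numeric(wave)
  n <- length(x)
  amp <- noise_std * sd(x)

  decomps <- purrr::map(seq_len(ensemble_size), function(i) {
    xi <- if (amp > 0) {
      x + with_seed(derive_seed(seed, i), function() rnorm(n, 0, amp))
    } else x
    emd(rewave(xi, wave), sd_threshold = sd_threshold,
        max_sift_iters = max_sift_iters, max_imfs = max_imfs)
  })

  n_imfs <- max(purrr::map_int(decomps, ~ length(.x$imfs)))
  if (n_imfs == 0) return(new_emd_result(list(), x, wave))
  avg <- purrr::map(seq_len(n_imfs), function(k) {
    acc <- numeric(n)
    for (d in decomps) if (k <= length(d$imfs)) acc <- acc + as.numeric(d$imfs[[k]])
    acc / ensemble_size
  })
  residue <- x - Reduce(`+`, avg)
  new_emd_result(avg, residue, wave)
}

#' Band-selective reconstruction (denoising / de-drifting)
#'
#' Reconstructs a signal from the IMFs whose amplitude-weighted mean
#' instantaneous frequency lies inside `band_hz` (default 0.4–13 Hz, the
#' filter band and spectrogram ceiling). Faster IMFs carry broadband noise
#' and motion artifact; slower IMFs and the residue carry baseline drift —
#' both are dropped.
#'
#' @param result An `emd_result`.
#' @param band_hz Length-2 frequency band in Hz.
#' @return A [waveform()].
#' @export
denoise <- function(result, band_hz = c(0.4, 13)) {
  stopifnot(inherits(result, "emd_result"))
  if (length(result$imfs) == 0) {
    stop("decomposition has no IMFs to reconstruct from", call. = FALSE)
  }
  keep <- purrr::map_lgl(result$imfs, function(imf) {
    f <- mean_inst_freq(imf)
    f >= band_hz[1] && f <= band_hz[2]
  })
  if (!any(keep)) {
    stop("all IMFs fall outside the reconstruction band (empty reconstruction)",
         call. = FALSE)
  }
  acc <- Reduce(`+`, purrr::map(result$imfs[keep], as.numeric))
  rewave(acc, result$residue)
}

#' Amplitude-weighted mean instantaneous frequency of a waveform
#'
#' @param wave A [waveform()] (typically an IMF).
#' @return Frequency in Hz (0 for an all-zero input).
#' @export
mean_inst_freq <- function(wave) {
  ia <- analytic_signal(wave)
  wsum <- sum(ia$amplitude)
  if (wsum <= 0) return(0)
  sum(ia$amplitude * ia$frequency_hz) / wsum
}

#' Dump a decomposition to a delimited text file
#'
#' One column per IMF plus the residue, whitespace-delimited with a header.
#'
#' @param result An `emd_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_imfs <- function(result, path) {
  stopifnot(inherits(result, "emd_result"))
  cols <- c(purrr::map(result$imfs, as.numeric), list(as.numeric(result$residue)))
  df <- as.data.frame(cols, col.names = c(
    sprintf("imf%d", seq_along(result$imfs)), "residue"))
  write.table(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
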