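# Shared fixtures: tones and composite signals at the pipeline's 125 Hz.

FS <- 125

tone <- function(f_hz, duration_s = 5, amp = 1, fs = FS, phase = 0) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  waveform(amp * sin(2 * pi * f_hz * t + phase), fs_hz = fs)
}

time_of <- function(w) (seq_along(w) - 1) / fs_hz(w)

# interior index range discarding `edge_s` seconds on both sides
interior <- function(w, edge_s = 1) {
  n <- length(w)
  k <- round(edge_s * fs_hz(w))
  (k + 1):(n - k)
}

# tiny manifest for fold tests: n records x 2 segments each
toy_manifest <- function(n_records, classes) {
  rid <- sprintf("r%03d", seq_len(n_records))
  tibble::tibble(
    segment_id = c(paste0(rid, "_s1"), paste0(rid, "_s2")),
    record_id = rep(rid, 2),
    class = rep(classes, 2)
  )
}
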