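test_that("envelope mean tracks offsets and slow trends", {
  s <- tone(3, duration_s = 5)
  int <- interior(s, 0.5)
  m0 <- envelope_mean(s)
  expect_lt(max(abs(m0[int])), 0.05)

  mc <- envelope_mean(waveform(as.numeric(s) + 2.5, fs_hz = 125))
  expect_lt(max(abs(mc[int] - 2.5)), 0.05)

  ramp <- 0.5 * time_of(s)
  mr <- envelope_mean(waveform(as.numeric(s) + ramp, fs_hz = 125))
  expect_lt(max(abs(mr[int] - ramp[int])) / max(ramp), 0.05)

  expect_error(envelope_mean(waveform(seq_len(100), fs_hz = 125)),
               "not siftable")
})

test_that("emd separates a fast and a slow tone and reconstructs exactly", {
  t <- time_of(tone(1, 10))
  fast <- sin(2 * pi * 5 * t); slow <- sin(2 * pi * 0.5 * t)
  w <- waveform(fast + slow, fs_hz = 125)
  dec <- emd(w)

  rec <- reconstruct(dec)
  expect_lt(max(abs(as.numeric(rec) - as.numeric(w))) / max(abs(w)), 1e-8)

  expect_gte(abs(cor(as.numeric(dec$imfs[[1]]), fast)), 0.9)
  later <- purrr::map_dbl(dec$imfs[-1], ~ abs(cor(as.numeric(.x), slow)))
  expect_gte(max(later), 0.9)

  # every returned IMF satisfies the IMF conditions
  expect_true(all(purrr::map_lgl(dec$imfs, is_imf)))

  # a pure ramp has no oscillation: zero IMFs, residue == input
  r <- waveform(seq(0, 1, length.out = 625), fs_hz = 125)
  dr <- emd(r)
  expect_length(dr$imfs, 0)
  expect_equal(as.numeric(dr$residue), as.numeric(r))

  expect_error(emd(waveform(c(1, 2, 3, 4), fs_hz = 125)), "16")
})

test_that("is_imf accepts oscillatory modes and rejects offset signals", {
  expect_true(is_imf(tone(3, duration_s = 5)))
  # large offset: extrema but no zero crossings
  shifted <- waveform(as.numeric(tone(3, 5)) + 10, fs_hz = 125)
  expect_false(is_imf(shifted))
})

test_that("emd reconstruction identity holds across random signals", {
  set.seed(404)
  for (i in 1:10) {
    x <- waveform(cumsum(rnorm(400)) + rnorm(400), fs_hz = 125)
    dec <- emd(x)
    err <- max(abs(as.numeric(reconstruct(dec)) - as.numeric(x)))
    expect_lt(err / max(abs(x)), 1e-8)
    dec2 <- eemd(x, ensemble_size = 3, noise_std = 0.1, seed = i)
    err2 <- max(abs(as.numeric(reconstruct(dec2)) - as.numeric(x)))
    expect_lt(err2 / max(abs(x)), 1e-8)
  }
})

test_that("IMF ordering decreases in mean instantaneous frequency", {
  set.seed(11)
  n_pairs <- 0; ordered_pairs <- 0
  for (i in 1:5) {
    t <- time_of(tone(1, 8))
    f1 <- runif(1, 4, 8); f2 <- runif(1, 0.8, 1.6); f3 <- runif(1, 0.1, 0.3)
    w <- waveform(sin(2 * pi * f1 * t) + sin(2 * pi * f2 * t) +
                    0.8 * sin(2 * pi * f3 * t), fs_hz = 125)
    mif <- purrr::map_dbl(emd(w)$imfs, mean_inst_freq)
    if (length(mif) >= 2) {
      d <- diff(mif)
      n_pairs <- n_pairs + length(d)
      ordered_pairs <- ordered_pairs + sum(d <= 0)
    }
  }
  expect_gte(ordered_pairs / n_pairs, 0.9)
})

test_that("eemd reduces to emd at zero noise and is seed-deterministic", {
  w <- waveform(sin(2 * pi * 1.3 * time_of(tone(1, 6))) +
                  0.3 * sin(2 * pi * 6 * time_of(tone(1, 6))), fs_hz = 125)
  base <- emd(w)
  e0 <- eemd(w, ensemble_size = 1, noise_std = 0, seed = 5)
  expect_equal(purrr::map(e0$imfs, as.numeric), purrr::map(base$imfs, as.numeric))
  expect_equal(as.numeric(e0$residue), as.numeric(base$residue))

  a <- eemd(w, ensemble_size = 5, noise_std = 0.2, seed = 7)
  b <- eemd(w, ensemble_size = 5, noise_std = 0.2, seed = 7)
  expect_identical(a, b)

  # convergence to emd as noise_std -> 0 at fixed seed
  small <- eemd(w, ensemble_size = 5, noise_std = 1e-6, seed = 7)
  k <- min(length(small$imfs), length(base$imfs))
  for (j in seq_len(k)) {
    expect_lt(max(abs(as.numeric(small$imfs[[j]]) - as.numeric(base$imfs[[j]]))),
              1e-3)
  }
})

test_that("eemd suppresses mode mixing on an intermittent burst", {
  # intermittent high-frequency bursts superposed on a tone: classic
  # mode-mixing construction. Under plain EMD the tone-carrying IMF also
  # captures burst segments, so its within-IMF instantaneous-frequency
  # variance is inflated; the ensemble decomposition isolates the tone in a
  # clean IMF with strictly smaller variance (amplitude-weighted, so the
  # statistic reflects the carried oscillation rather than near-zero wiggle).
  t <- time_of(tone(1, 6))
  burst <- ifelse((t %% 1.5) < 0.25, sin(2 * pi * 20 * t), 0) * 0.3
  w <- waveform(sin(2 * pi * 1 * t) + burst, fs_hz = 125)

  tone_imf_stats <- function(dec) {
    cors <- purrr::map_dbl(dec$imfs, ~ abs(cor(as.numeric(.x), sin(2 * pi * t))))
    imf <- dec$imfs[[which.max(cors)]]
    ia <- analytic_signal(imf)
    int <- interior(imf, 0.5)
    a <- ia$amplitude[int]; f <- ia$frequency_hz[int]
    mu <- sum(a * f) / sum(a)
    list(cor = max(cors), wvar = sum(a * (f - mu)^2) / sum(a))
  }
  s_emd <- tone_imf_stats(emd(w))
  s_eemd <- tone_imf_stats(eemd(w, ensemble_size = 100, noise_std = 0.2,
                                seed = 1))
  expect_lt(s_eemd$wvar, s_emd$wvar)
  expect_gt(s_eemd$cor, s_emd$cor)
})

test_that("denoise keeps the physiological band and rejects drift and noise", {
  t <- time_of(tone(1, 10))
  tone12 <- sin(2 * pi * 1.2 * t)

  dn <- denoise(emd(waveform(tone12, fs_hz = 125)))
  expect_gte(cor(as.numeric(dn), tone12), 0.99)

  drift <- 0.8 * sin(2 * pi * 0.1 * t)
  dn2 <- denoise(emd(waveform(tone12 + drift, fs_hz = 125)))
  expect_lt(abs(cor(as.numeric(dn2), drift)), 0.1)

  set.seed(8)
  hi <- 0.4 * sin(2 * pi * 30 * t + runif(1))
  x3 <- waveform(tone12 + hi, fs_hz = 125)
  dn3 <- denoise(eemd(x3, ensemble_size = 10, noise_std = 0.1, seed = 2))
  pow_above <- function(x) {
    sp <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * 125 / length(x)
    sum(sp[freqs > 13 & freqs < 62.5])
  }
  drop_db <- 10 * log10(pow_above(as.numeric(x3)) / pow_above(as.numeric(dn3)))
  expect_gte(drop_db, 10)

  # all IMFs outside the band -> empty-reconstruction error
  slow <- emd(waveform(sin(2 * pi * 0.3 * t), fs_hz = 125))
  expect_error(denoise(slow, band_hz = c(5, 13)), "empty reconstruction")
})

test_that("IMF dumps round-trip through the text writer", {
  dec <- emd(waveform(sin(2 * pi * 2 * time_of(tone(1, 5))) +
                        0.5 * sin(2 * pi * 0.5 * time_of(tone(1, 5))),
                      fs_hz = 125))
  path <- withr::local_tempfile(fileext = ".txt")
  write_imfs(dec, path)
  tab <- read.table(path, header = TRUE)
  expect_equal(ncol(tab), length(dec$imfs) + 1)
  expect_equal(tab[[1]], as.numeric(dec$imfs[[1]]), tolerance = 1e-6)
})
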