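test_that("make_beat places and scales its components as specified", {
  # single bump: argmax at systolic_pos within one sample, peak amp within 1%
  m <- beat_morphology(tidal_amp = 0, dicrotic_amp = 0)
  b <- make_beat(m, period_s = 0.8, fs_hz = 125)
  n <- length(b)
  expect_equal(n, round(0.8 * 125))
  expect_lte(abs(which.max(b) - (m$systolic_pos * n + 1)), 1)
  expect_lt(abs(max(b) - m$systolic_amp) / m$systolic_amp, 0.01)

  # determinism
  expect_identical(as.numeric(make_beat(m, 0.8, 125)),
                   as.numeric(make_beat(m, 0.8, 125)))

  # invalid parameters rejected
  expect_error(beat_morphology(systolic_amp = -1), "non-negative")
  expect_error(beat_morphology(tidal_pos = 1.2), "inside")
  expect_error(make_beat(m, period_s = -1, fs_hz = 125), "period_s")
})

test_that("hypertensive template merges the tidal wave into a single maximum", {
  ht <- morphology_template("HT")
  b <- make_beat(ht, period_s = 0.9, fs_hz = 125)
  ex <- ppgplus:::find_extrema(as.numeric(b))
  big <- sum(as.numeric(b)[ex$max] > 0.1 * max(b))
  expect_identical(big, 1L)

  # normotensive template keeps separated tidal/dicrotic waves
  nt <- make_beat(morphology_template("NT"), period_s = 0.9, fs_hz = 125)
  ex_nt <- ppgplus:::find_extrema(as.numeric(nt))
  expect_gte(sum(as.numeric(nt)[ex_nt$max] > 0.1 * max(nt)), 2)
})

test_that("make_abp pins the waveform extrema to the requested pressures", {
  abp <- make_abp(150, 95, heart_rate_hz = 1.2, record_s = 10, fs_hz = 125)
  expect_equal(length(abp), 1250)
  expect_equal(max(abp), 150)
  expect_equal(min(abp), 95)
  expect_identical(wave_units(abp), "mmHg")
  expect_error(make_abp(90, 95, 1, 10, 125), "sbp")

  # pressures in the NT and PHT boxes classify accordingly
  nt_seg <- make_abp(115, 75, 1.2, 5, 125)
  pht_seg <- make_abp(125, 70, 1.2, 5, 125)
  bp1 <- extract_bp(nt_seg)
  bp2 <- extract_bp(pht_seg)
  expect_identical(as.character(jnc7_classify(bp1$sbp_mmHg, bp1$dbp_mmHg)), "NT")
  expect_identical(as.character(jnc7_classify(bp2$sbp_mmHg, bp2$dbp_mmHg)), "PHT")
})

test_that("generate_cohort is seeded, class-consistent and noise-controllable", {
  cfg <- cohort_config(n_records = 12, class_probs = c(0.5, 0, 0.5), seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(as.character(a$true_class) %in% c("NT", "HT")))

  # stored pressures always classify to the stored class
  expect_identical(as.character(jnc7_classify(a$sbp_mmHg, a$dbp_mmHg)),
                   as.character(a$true_class))

  # clean config: ppg equals the noiseless beat train (drift 0, noise 0)
  clean <- generate_cohort(cohort_config(n_records = 3, noise_std = 0,
                                         drift_amp = 0, seed = 3))
  for (i in 1:3) {
    w <- clean$ppg[[i]]
    # a pure beat train is non-negative and bounded by template amplitudes
    expect_gte(min(w), 0)
    expect_lt(max(w), 2)
  }
})

test_that("cohort class counts follow the configured multinomial", {
  co <- generate_cohort(cohort_config(n_records = 1000,
                                      class_probs = c(1, 1, 1) / 3,
                                      noise_std = 0.01, seed = 1))
  counts <- table(co$true_class)
  sd_bin <- sqrt(1000 * (1 / 3) * (2 / 3))
  for (cl in c("NT", "PHT", "HT")) {
    expect_lt(abs(counts[[cl]] - 1000 / 3), 4 * sd_bin)
  }
})

test_that("clean PPG spectral content stays below 13 Hz and drift stays below 0.4 Hz", {
  co <- generate_cohort(cohort_config(n_records = 4, noise_std = 0,
                                      drift_amp = 0, heart_rate_hz = c(0.8, 2),
                                      seed = 5))
  for (i in seq_len(4)) {
    x <- as.numeric(co$ppg[[i]])
    sp <- Mod(fft(x - mean(x)))[1:625]
    freqs <- (0:624) * 125 / 1250
    peak <- max(sp)
    above <- max(sp[freqs > 13])
    expect_lt(20 * log10(above / peak), -40)
  }

  # adding drift changes only the sub-0.4 Hz band (Hann window against the
  # rectangular-window leakage of a 1.5-cycle sinusoid in a 10-s record)
  cfg0 <- cohort_config(n_records = 1, noise_std = 0, drift_amp = 0, seed = 9)
  cfg1 <- cohort_config(n_records = 1, noise_std = 0, drift_amp = 0.5, seed = 9)
  x0 <- as.numeric(generate_cohort(cfg0)$ppg[[1]])
  x1 <- as.numeric(generate_cohort(cfg1)$ppg[[1]])
  d <- (x1 - x0)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_along(d) - 1) / (length(d) - 1)))
  dspec <- Mod(fft((d - mean(d)) * hann))[1:625]
  freqs <- (0:624) * 125 / 1250
  expect_lt(max(dspec[freqs >= 0.4]) / max(dspec), 0.05)
})

test_that("cohort round-trips through the delimited-text writer", {
  co <- generate_cohort(cohort_config(n_records = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir, seed = 2)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_identical(as.character(back$true_class), as.character(co$true_class))
  expect_equal(as.numeric(back$ppg[[2]]), as.numeric(co$ppg[[2]]), tolerance = 1e-6)
  expect_equal(fs_hz(back$abp[[1]]), 125)
})
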