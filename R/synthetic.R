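#' Beat morphology for synthetic PPG
#'
#' Parametrises one PPG beat as a sum of three Gaussian bumps — systolic
#' (main) wave, tidal wave and dicrotic wave — on a unit beat period. In
#' hypertension the tidal wave migrates toward the main wave until the two
#' merge and the descending branch steepens; the class templates encode that
#' contrast. `descending_steepness` > 1 narrows the right flank of the
#' systolic Gaussian.
#'
#' Positions are fractions of the beat period, widths are Gaussian standard
#' deviations as period fractions, amplitudes are dimensionless.
#'
#' @param systolic_amp,systolic_pos,systolic_width Main wave parameters.
#' @param tidal_amp,tidal_pos Tidal wave parameters.
#' @param dicrotic_amp,dicrotic_pos Dicrotic wave parameters.
#' @param descending_steepness Right-flank narrowing factor of the main wave
#'   (1 = symmetric).
#'
#' @return A `beat_morphology` list.
#' @seealso [morphology_template()] for per-class defaults, [make_beat()].
#' @export
beat_morphology <- function(systolic_amp = 1, systolic_pos = 0.18,
                            systolic_width = 0.05,
                            tidal_amp = 0.35, tidal_pos = 0.45,
                            dicrotic_amp = 0.18, dicrotic_pos = 0.70,
                            descending_steepness = 1) {
  m <- list(systolic_amp = systolic_amp, systolic_pos = systolic_pos,
            systolic_width = systolic_width,
            tidal_amp = tidal_amp, tidal_pos = tidal_pos,
            dicrotic_amp = dicrotic_amp, dicrotic_pos = dicrotic_pos,
            descending_steepness = descending_steepness)
  vals <- unlist(m)
  if (!all(is.finite(vals))) {
    stop("beat morphology parameters must be finite", call. = FALSE)
  }
  if (any(c(m$systolic_amp, m$tidal_amp, m$dicrotic_amp) < 0)) {
    stop("beat amplitudes must be non-negative", call. = FALSE)
  }
  pos <- c(m$systolic_pos, m$tidal_pos, m$dicrotic_pos)
  if (any(pos <= 0 | pos >= 1)) {
    stop("beat component positions must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (m$systolic_width <= 0 || m$descending_steepness <= 0) {
    stop("systolic_width and descending_steepness must be positive", call. = FALSE)
  }
  structure(m, class = "beat_morphology")
}

#' Class morphology templates
#'
#' Returns the beat morphology used for each JNC7 class. The normotensive
#' template has a well separated tidal wave and dicrotic notch; the
#' hypertensive template has the tidal wave migrated into the main wave
#' (single merged maximum, rounder peak) and a steeper descending branch;
#' prehypertension is intermediate.
#'
#' @param class One of `"NT"`, `"PHT"`, `"HT"`.
#' @return A [beat_morphology()].
#' @export
morphology_template <- function(class = c("NT", "PHT", "HT")) {
  class <- match.arg(class)
  switch(class,
    NT = beat_morphology(systolic_amp = 1, systolic_pos = 0.18,
                         systolic_width = 0.09,
                         tidal_amp = 0.40, tidal_pos = 0.48,
                         dicrotic_amp = 0.22, dicrotic_pos = 0.75,
                         descending_steepness = 1),
    PHT = beat_morphology(systolic_amp = 1, systolic_pos = 0.18,
                          systolic_width = 0.10,
                          tidal_amp = 0.55, tidal_pos = 0.40,
                          dicrotic_amp = 0.12, dicrotic_pos = 0.70,
                          descending_steepness = 1.15),
    HT = beat_morphology(systolic_amp = 1, systolic_pos = 0.18,
                         systolic_width = 0.13,
                         tidal_amp = 0.80, tidal_pos = 0.28,
                         dicrotic_amp = 0.08, dicrotic_pos = 0.64,
                         descending_steepness = 1.25)
  )
}

# Asymmetric Gaussian bump on the circular beat phase: distances are wrapped
# to [-0.5, 0.5) so consecutive beats join continuously (no boundary step,
# hence no spurious broadband content in the beat train).
asym_gauss <- function(u, pos, width, right_steepness = 1) {
  d <- u - pos
  d <- d - round(d)
  w <- ifelse(d <= 0, width, width / right_steepness)
  exp(-0.5 * (d / w)^2)
}

#' Synthesise one PPG beat
#'
#' @param m A [beat_morphology()].
#' @param period_s Beat period in seconds (> 0).
#' @param fs_hz Sampling rate in Hz (>= 50).
#' @return A [waveform()] of `round(period_s * fs_hz)` samples.
#' @examples
#' b <- make_beat(morphology_template("NT"), period_s = 0.8, fs_hz = 125)
#' @export
make_beat <- function(m, period_s, fs_hz) {
  if (!inherits(m, "beat_morphology")) m <- do.call(beat_morphology, m)
  if (!is.finite(period_s) || period_s <= 0) {
    stop("period_s must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(fs_hz) || fs_hz < 50) {
    stop("fs_hz must be >= 50", call. = FALSE)
  }
  n <- round(period_s * fs_hz)
  u <- (seq_len(n) - 1) / n
  y <- m$systolic_amp *
    asym_gauss(u, m$systolic_pos, m$systolic_width, m$descending_steepness) +
    m$tidal_amp * asym_gauss(u, m$tidal_pos, m$systolic_width * 1.6) +
    m$dicrotic_amp * asym_gauss(u, m$dicrotic_pos, m$systolic_width * 1.2)
  waveform(y, fs_hz = fs_hz, units = "a.u.")
}

# Beat train of total length n_samples with per-beat period jitter.
# jitter_frac = 0 gives a strictly periodic train.
beat_train <- function(m, heart_rate_hz, n_samples, fs_hz, jitter_frac = 0.05) {
  out <- numeric(0)
  base_period <- 1 / heart_rate_hz
  while (length(out) < n_samples) {
    p <- base_period * (1 + if (jitter_frac > 0) runif(1, -jitter_frac, jitter_frac) else 0)
    out <- c(out, as.numeric(make_beat(m, p, fs_hz)))
  }
  waveform(out[seq_len(n_samples)], fs_hz = fs_hz, units = "a.u.")
}

#' Synthesise an arterial blood-pressure waveform
#'
#' Builds a periodic pressure-like pulse train and rescales it so that its
#' global maximum is exactly `sbp_mmHg` and its global minimum exactly
#' `dbp_mmHg` — the quantities downstream labelling extracts from each
#' segment.
#'
#' @param sbp_mmHg Systolic (peak) pressure, mmHg.
#' @param dbp_mmHg Diastolic (trough) pressure, mmHg; must be < `sbp_mmHg`.
#' @param heart_rate_hz Heart rate in Hz.
#' @param record_s Record duration in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @param jitter_frac Beat-to-beat period jitter fraction.
#' @return A [waveform()] in mmHg of length `round(record_s * fs_hz)`.
#' @examples
#' abp <- make_abp(150, 95, heart_rate_hz = 1.2, record_s = 10, fs_hz = 125)
#' range(abp) # 95 150
#' @export
make_abp <- function(sbp_mmHg, dbp_mmHg, heart_rate_hz, record_s, fs_hz,
                     jitter_frac = 0.05) {
  if (!is.finite(sbp_mmHg) || !is.finite(dbp_mmHg) ||
      dbp_mmHg <= 0 || sbp_mmHg <= dbp_mmHg) {
    stop("need sbp_mmHg > dbp_mmHg > 0", call. = FALSE)
  }
  n <- round(record_s * fs_hz)
  shape <- beat_morphology(systolic_amp = 1, systolic_pos = 0.25,
                           systolic_width = 0.09,
                           tidal_amp = 0.25, tidal_pos = 0.5,
                           dicrotic_amp = 0.12, dicrotic_pos = 0.68,
                           descending_steepness = 1)
  y <- as.numeric(beat_train(shape, heart_rate_hz, n, fs_hz, jitter_frac))
  y <- (y - min(y)) / (max(y) - min(y)) * (sbp_mmHg - dbp_mmHg) + dbp_mmHg
  waveform(y, fs_hz = fs_hz, units = "mmHg")
}

#' Cohort generator configuration
#'
#' @param n_records Number of 10-s records to generate.
#' @param class_probs Probability triple over (NT, PHT, HT); must sum to 1.
#' @param heart_rate_hz Length-2 heart-rate range in Hz (within 0.8–2 Hz the
#'   clean-signal spectrum stays below the 13 Hz spectrogram ceiling).
#' @param noise_std Additive white-noise standard deviation (signal units).
#' @param drift_amp Amplitude of the sinusoidal baseline drift.
#' @param drift_freq_hz Drift frequency; must stay below the 0.4 Hz filter edge.
#' @param fs_hz Sampling rate (default 125 Hz).
#' @param record_s Record duration (default 10 s).
#' @param seed Integer seed controlling all randomness of the cohort.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_records = 100,
                          class_probs = c(NT = 1 / 3, PHT = 1 / 3, HT = 1 / 3),
                          heart_rate_hz = c(0.8, 2.0),
                          noise_std = 0.02, drift_amp = 0.3,
                          drift_freq_hz = 0.15,
                          fs_hz = 125, record_s = 10, seed = 1L) {
  cfg <- list(n_records = as.integer(n_records),
              class_probs = unname(as.numeric(class_probs)),
              heart_rate_hz = as.numeric(heart_rate_hz),
              noise_std = noise_std, drift_amp = drift_amp,
              drift_freq_hz = drift_freq_hz,
              fs_hz = fs_hz, record_s = record_s, seed = as.integer(seed))
  if (cfg$n_records < 1) stop("n_records must be >= 1", call. = FALSE)
  if (length(cfg$class_probs) != 3 || any(cfg$class_probs < 0) ||
      abs(sum(cfg$class_probs) - 1) > 1e-8) {
    stop("class_probs must be 3 non-negative numbers summing to 1", call. = FALSE)
  }
  if (length(cfg$heart_rate_hz) != 2 || cfg$heart_rate_hz[1] <= 0 ||
      diff(cfg$heart_rate_hz) < 0) {
    stop("heart_rate_hz must be an increasing positive range", call. = FALSE)
  }
  if (cfg$drift_freq_hz >= 0.4) {
    stop("drift_freq_hz must lie below the 0.4 Hz filter edge", call. = FALSE)
  }
  if (cfg$fs_hz <= 2 * 13) {
    stop("fs_hz must exceed twice the 13 Hz spectrum ceiling", call. = FALSE)
  }
  if (cfg$noise_std < 0 || cfg$drift_amp < 0) {
    stop("noise_std and drift_amp must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

# Per-class SBP/DBP sampling boxes (mmHg): disjoint and JNC7-consistent, so
# every draw classifies unambiguously to its intended class.
bp_boxes <- list(
  NT  = list(sbp = c(100, 119), dbp = c(60, 79)),
  PHT = list(sbp = c(120, 139), dbp = c(80, 89)),
  HT  = list(sbp = c(140, 180), dbp = c(90, 110))
)

#' Generate a synthetic PPG/ABP cohort
#'
#' Draws a JNC7 class per record, samples SBP/DBP from the class box, builds
#' the PPG from the class morphology template (with ±5% beat-to-beat period
#' jitter), contaminates it with white noise and low-frequency sinusoidal
#' baseline drift, and builds a paired ABP waveform whose extrema equal the
#' drawn pressures. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A tibble with one row per record: `record_id`, `true_class`
#'   (factor NT < PHT < HT), `sbp_mmHg`, `dbp_mmHg`, `heart_rate_hz`, and
#'   list-columns `ppg` and `abp` of [waveform()]s.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_records = 4, seed = 7))
#' cohort$true_class
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  classes <- c("NT", "PHT", "HT")
  with_seed(cfg$seed, function() {
    n <- cfg$n_records
    cls <- sample(classes, n, replace = TRUE, prob = cfg$class_probs)
    rows <- purrr::map(seq_len(n), function(i) {
      box <- bp_boxes[[cls[i]]]
      sbp <- runif(1, box$sbp[1], box$sbp[2])
      dbp <- runif(1, box$dbp[1], box$dbp[2])
      hr <- runif(1, cfg$heart_rate_hz[1], cfg$heart_rate_hz[2])
      ns <- round(cfg$record_s * cfg$fs_hz)
      ppg <- beat_train(morphology_template(cls[i]), hr, ns, cfg$fs_hz)
      tt <- (seq_len(ns) - 1) / cfg$fs_hz
      contaminated <- as.numeric(ppg) +
        cfg$drift_amp * sin(2 * pi * cfg$drift_freq_hz * tt + runif(1, 0, 2 * pi)) +
        (if (cfg$noise_std > 0) rnorm(ns, 0, cfg$noise_std) else 0)
      abp <- make_abp(sbp, dbp, hr, cfg$record_s, cfg$fs_hz)
      tibble::tibble(
        record_id = sprintf("rec%04d", i),
        true_class = cls[i],
        sbp_mmHg = sbp, dbp_mmHg = dbp, heart_rate_hz = hr,
        ppg = list(rewave(contaminated, ppg)),
        abp = list(abp)
      )
    })
    out <- dplyr::bind_rows(rows)
    out$true_class <- factor(out$true_class, levels = classes, ordered = TRUE)
    out
  })
}

#' Write / read a cohort as delimited text
#'
#' One two-column (`ppg`, `abp`) whitespace-delimited file per record with a
#' `#`-prefixed header carrying fs, class and pressures, plus a
#' `manifest.csv` (record_id, class, sbp, dbp, seed).
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @return `dir`, invisibly (writer); a cohort tibble (reader).
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    path <- file.path(dir, paste0(cohort$record_id[i], ".txt"))
    ppg <- cohort$ppg[[i]]
    con <- file(path, "w")
    writeLines(c(
      sprintf("# fs_hz %g", fs_hz(ppg)),
      sprintf("# class %s", as.character(cohort$true_class[i])),
      sprintf("# sbp_mmHg %.6f", cohort$sbp_mmHg[i]),
      sprintf("# dbp_mmHg %.6f", cohort$dbp_mmHg[i]),
      "ppg abp"
    ), con)
    write.table(data.frame(ppg = as.numeric(ppg),
                           abp = as.numeric(cohort$abp[[i]])),
                con, row.names = FALSE, col.names = FALSE)
    close(con)
  }
  manifest <- data.frame(record_id = cohort$record_id,
                         class = as.character(cohort$true_class),
                         sbp = cohort$sbp_mmHg, dbp = cohort$dbp_mmHg,
                         seed = seed)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    path <- file.path(dir, paste0(manifest$record_id[i], ".txt"))
    hdr <- readLines(path, n = 4)
    fs <- as.numeric(sub("^# fs_hz ", "", hdr[1]))
    dat <- read.table(path, skip = 5, col.names = c("ppg", "abp"))
    tibble::tibble(
      record_id = manifest$record_id[i],
      true_class = manifest$class[i],
      sbp_mmHg = manifest$sbp[i], dbp_mmHg = manifest$dbp[i],
      heart_rate_hz = NA_real_,
      ppg = list(waveform(dat$ppg, fs_hz = fs)),
      abp = list(waveform(dat$abp, fs_hz = fs, units = "mmHg"))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$true_class <- factor(out$true_class, levels = c("NT", "PHT", "HT"),
                           ordered = TRUE)
  out
}
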