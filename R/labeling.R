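#' Extract systolic and diastolic pressure from an ABP segment
#'
#' By default SBP is the global maximum of the segment and DBP the global
#' minimum ("extrema" method). The "beat_mean" method detects beats as
#' local maxima separated by at least 0.4 s and averages per-beat maxima and
#' minima instead.
#'
#' @param abp_segment A [waveform()] in mmHg.
#' @param method `"extrema"` (default) or `"beat_mean"`.
#' @param min_pulse_mmHg Minimum plausible pulse pressure; a flatter segment
#'   is rejected as an implausible waveform.
#' @return A tibble with columns `sbp_mmHg`, `dbp_mmHg`.
#' @export
extract_bp <- function(abp_segment, method = c("extrema", "beat_mean"),
                       min_pulse_mmHg = 5) {
  stopifnot(inherits(abp_segment, "waveform"))
  method <- match.arg(method)
  x <- as.numeric(abp_segment)
  if (max(x) - min(x) < min_pulse_mmHg) {
    stop(sprintf("implausible ABP segment: pulse pressure < %g mmHg",
                 min_pulse_mmHg), call. = FALSE)
  }
  if (method == "extrema") {
    return(tibble::tibble(sbp_mmHg = max(x), dbp_mmHg = min(x)))
  }
  fs <- fs_hz(abp_segment)
  ex <- find_extrema(x)
  peaks <- ex$max[x[ex$max] > min(x) + 0.5 * (max(x) - min(x))]
  # enforce >= 0.4 s separation between accepted beats
  if (length(peaks) > 1) {
    sel <- peaks[1]
    for (p in peaks[-1]) if (p - tail(sel, 1) >= 0.4 * fs) sel <- c(sel, p)
    peaks <- sel
  }
  if (length(peaks) < 2) {
    return(tibble::tibble(sbp_mmHg = max(x), dbp_mmHg = min(x)))
  }
  troughs <- purrr::map_dbl(seq_len(length(peaks) - 1), function(i) {
    min(x[peaks[i]:peaks[i + 1]])
  })
  tibble::tibble(sbp_mmHg = mean(x[peaks]), dbp_mmHg = mean(troughs))
}

#' JNC7 blood-pressure classification
#'
#' Vectorised staging into normotension (NT), prehypertension (PHT) and
#' hypertension (HT). The default boundary rule assigns HT when
#' `sbp >= 140` or `dbp >= 90` and PHT when `sbp >= 120` or `dbp >= 80`,
#' following the JNC7 guideline, so every reading gets exactly one class.
#' `strict_table = TRUE` instead applies the table bands as printed
#' (hypertension only above 140/90).
#'
#' @param sbp_mmHg,dbp_mmHg Numeric vectors of equal length, `sbp > dbp`,
#'   both within (20, 300).
#' @param strict_table Use the literal printed bands (see Details).
#' @return An ordered factor with levels `NT < PHT < HT`.
#' @examples
#' jnc7_classify(c(115, 118, 150), c(75, 85, 70)) # NT PHT HT
#' @export
jnc7_classify <- function(sbp_mmHg, dbp_mmHg, strict_table = FALSE) {
  if (length(sbp_mmHg) != length(dbp_mmHg)) {
    stop("sbp and dbp must have equal length", call. = FALSE)
  }
  bad <- !is.finite(sbp_mmHg) | !is.finite(dbp_mmHg) |
    sbp_mmHg <= dbp_mmHg | sbp_mmHg <= 20 | sbp_mmHg >= 300 |
    dbp_mmHg <= 20 | dbp_mmHg >= 300
  if (any(bad)) {
    stop("invalid reading: need 20 < dbp < sbp < 300 mmHg", call. = FALSE)
  }
  ht <- if (strict_table) sbp_mmHg > 140 | dbp_mmHg > 90
        else sbp_mmHg >= 140 | dbp_mmHg >= 90
  pht <- !ht & (sbp_mmHg >= 120 | dbp_mmHg >= 80)
  cls <- ifelse(ht, "HT", ifelse(pht, "PHT", "NT"))
  factor(cls, levels = c("NT", "PHT", "HT"), ordered = TRUE)
}

#' Label PPG segments from paired ABP segments
#'
#' Index-aligned pairing: segment i of the PPG record is labelled with the
#' JNC7 class of segment i of the ABP record. Pairs whose ABP segment is
#' implausible (near-flat) are dropped from the output; the number of drops
#' is attached as attribute `n_dropped` and reported via a message.
#'
#' @param ppg_segments,abp_segments Lists (or `wave` list-columns) of
#'   [waveform()]s, equal length and index-aligned.
#' @param method Passed to [extract_bp()].
#' @return A tibble with columns `segment` (original index), `ppg`
#'   (list-column), `sbp_mmHg`, `dbp_mmHg`, `class`; attribute `n_dropped`.
#' @export
label_record <- function(ppg_segments, abp_segments,
                         method = c("extrema", "beat_mean")) {
  method <- match.arg(method)
  if (length(ppg_segments) != length(abp_segments)) {
    stop("PPG and ABP segment lists are not aligned (length mismatch)",
         call. = FALSE)
  }
  n <- length(ppg_segments)
  rows <- vector("list", n)
  dropped <- 0L
  for (i in seq_len(n)) {
    bp <- tryCatch(extract_bp(abp_segments[[i]], method = method),
                   error = function(e) NULL)
    if (is.null(bp)) {
      dropped <- dropped + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      segment = i, ppg = list(ppg_segments[[i]]),
      sbp_mmHg = bp$sbp_mmHg, dbp_mmHg = bp$dbp_mmHg,
      class = jnc7_classify(bp$sbp_mmHg, bp$dbp_mmHg)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(segment = integer(), ppg = list(),
                          sbp_mmHg = numeric(), dbp_mmHg = numeric(),
                          class = factor(character(),
                                         levels = c("NT", "PHT", "HT"),
                                         ordered = TRUE))
  }
  if (dropped > 0) {
    message(sprintf("label_record: dropped %d segment pair(s) with implausible ABP",
                    dropped))
  }
  attr(out, "n_dropped") <- dropped
  out
}
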