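#' Pipeline run configuration
#'
#' Bundles the configuration of every stage of the end-to-end flow:
#' synthetic cohort (or a cohort directory), preprocessing, EEMD, Hilbert
#' spectra, PPG+ composition, labelling, splitting and training.
#'
#' @param cohort A [cohort_config()], or a directory path containing records
#'   written by [write_cohort()].
#' @param mode `"ppgplus"` (PPG, PPG', PPG'' as R/G/B) or `"ppg"` (control
#'   experiment: only the red channel carries signal).
#' @param trial A [trial_spec()] (or its name).
#' @param model A [model_spec()].
#' @param train A [train_config()].
#' @param ensemble_size,noise_std EEMD settings used by the pipeline run.
#' @param seg_s Segment length in seconds (default 5).
#' @param out_dir Output directory for images/manifest/report, or `NULL` to
#'   keep everything in memory.
#' @param write_images Write the composed PPG+ PNGs under `out_dir`.
#' @param image_width,image_height Rendered PPG+ resolution.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       mode = c("ppgplus", "ppg"),
                       trial = trial_spec("nt_vs_ht"),
                       model = model_spec("small_cnn"),
                       train = train_config(),
                       ensemble_size = 4, noise_std = 0.2,
                       seg_s = 5, out_dir = NULL, write_images = !is.null(out_dir),
                       image_width = 1247, image_height = 770,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(trial)) trial <- trial_spec(trial)
  stopifnot(inherits(trial, "trial_spec"), inherits(model, "model_spec"),
            inherits(train, "train_config"))
  if (!is.character(cohort) && !inherits(cohort, "cohort_config")) {
    stop("cohort must be a cohort_config or a directory path", call. = FALSE)
  }
  structure(list(cohort = cohort, mode = mode, trial = trial, model = model,
                 train = train, ensemble_size = ensemble_size,
                 noise_std = noise_std, seg_s = seg_s, out_dir = out_dir,
                 write_images = isTRUE(write_images),
                 image_width = image_width, image_height = image_height,
                 seed = as.integer(seed)),
            class = "run_config")
}

# One segment -> network input tensor: EEMD denoise, derivatives, per-signal
# EEMD + Hilbert spectra, PPG+ composition (zero G/B in "ppg" mode).
process_segment <- function(seg_wave, cfg, seg_id, label) {
  dec <- eemd(seg_wave, ensemble_size = cfg$ensemble_size,
              noise_std = cfg$noise_std, seed = derive_seed(cfg$seed, 31L))
  clean <- tryCatch(denoise(dec), error = function(e) seg_wave)
  clean <- normalize(clean)
  ds <- derivatives(clean)
  specs <- purrr::map(list(ds$ppg, ds$d1, ds$d2), function(w) {
    d <- eemd(w, ensemble_size = cfg$ensemble_size, noise_std = cfg$noise_std,
              seed = derive_seed(cfg$seed, 37L))
    if (length(d$imfs) == 0) d$imfs <- list(w)
    hilbert_spectrum(d$imfs)
  })
  if (cfg$mode == "ppg") {
    zero <- specs[[1]]
    zero$matrix <- zero$matrix * 0
    specs[[2]] <- zero
    specs[[3]] <- zero
  }
  img <- compose_ppgplus(specs[[1]], specs[[2]], specs[[3]], label = label,
                         segment_id = seg_id,
                         width = cfg$image_width, height = cfg$image_height)
  img
}

#' Run the full classification pipeline
#'
#' Executes simulate/ingest, preprocessing (band-pass, segmentation),
#' JNC7 labelling from the paired ABP segments, EEMD denoising, Hilbert
#' spectra of PPG and its derivatives, PPG+ composition, the stratified
#' grouped 7:3 split with k folds, and cross-validated training — and
#' returns a machine-readable report with counts at every stage and the
#' per-fold metrics.
#'
#' @param cfg A [run_config()].
#' @return A `run_report` list: `counts` (records_in, segments_made,
#'   segments_labeled, segments_dropped, images_written, trial segments),
#'   `manifest` (tibble), `cv` (the `cv_fit`), `timings_s`, and `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- tic() - t0
    message(sprintf("[pipeline] %-10s %6.1fs", name, timings[[name]]))
    res
  }

  cohort <- stage("ingest", {
    if (is.character(cfg$cohort)) read_cohort(cfg$cohort)
    else generate_cohort(cfg$cohort)
  })

  segments <- stage("prep", {
    purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      ppg_f <- bandpass(cohort$ppg[[i]])
      segs_p <- segment_record(ppg_f, seg_s = cfg$seg_s)
      segs_a <- segment_record(cohort$abp[[i]], seg_s = cfg$seg_s)
      k <- min(nrow(segs_p), nrow(segs_a))
      tibble::tibble(
        record_id = cohort$record_id[i],
        segment = segs_p$segment[seq_len(k)],
        ppg = segs_p$wave[seq_len(k)],
        abp = segs_a$wave[seq_len(k)]
      )
    })
  })

  labeled <- stage("label", {
    lab <- label_record(segments$ppg, segments$abp)
    lab$record_id <- segments$record_id[lab$segment]
    lab$segment_id <- sprintf("%s_s%d", lab$record_id,
                              segments$segment[lab$segment])
    lab
  })

  images <- stage("hht", {
    purrr::map(seq_len(nrow(labeled)), function(i) {
      process_segment(labeled$ppg[[i]], cfg, labeled$segment_id[i],
                      as.character(labeled$class[i]))
    })
  })

  images_written <- 0L
  if (!is.null(cfg$out_dir)) {
    dir.create(file.path(cfg$out_dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
  }
  img_paths <- rep(NA_character_, length(images))
  if (cfg$write_images && !is.null(cfg$out_dir)) {
    stage("write", {
      for (i in seq_along(images)) {
        img_paths[i] <- file.path(cfg$out_dir, "images",
                                  paste0(labeled$segment_id[i], ".png"))
        write_ppgplus_png(images[[i]], img_paths[i])
        images_written <- images_written + 1L
      }
    })
  }

  tensors <- stage("tensor", purrr::map(images, to_network_input))

  manifest <- stage("split", {
    m <- tibble::tibble(segment_id = labeled$segment_id,
                        record_id = labeled$record_id,
                        class = as.character(labeled$class),
                        sbp = labeled$sbp_mmHg, dbp = labeled$dbp_mmHg,
                        image_path = img_paths)
    make_folds(m, k = cfg$train$k_folds, train_frac = 0.7,
               seed = derive_seed(cfg$seed, 41L))
  })

  cv <- stage("train", {
    tr_rows <- which(manifest$split == "train")
    train_cv(tensors[tr_rows], manifest$class[tr_rows],
             manifest$fold[tr_rows], cfg$trial, cfg$model, cfg$train)
  })

  report <- structure(list(
    counts = list(
      records_in = nrow(cohort),
      segments_made = nrow(segments),
      segments_labeled = nrow(labeled),
      segments_dropped = attr(labeled, "n_dropped"),
      images_written = images_written,
      train_segments = sum(manifest$split == "train"),
      test_segments = sum(manifest$split == "test")
    ),
    manifest = manifest,
    cv = cv,
    tensors = tensors,
    timings_s = timings,
    config = cfg
  ), class = "run_report")

  if (!is.null(cfg$out_dir)) {
    write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(counts = report$counts,
           mean_metrics = as.list(cv$mean_metrics),
           per_fold = cv$per_fold,
           timings_s = as.list(timings)),
      file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-18s %s\n", nm, x$counts[[nm]]))
  print(x$cv)
  invisible(x)
}
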