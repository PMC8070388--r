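#' Compose a three-channel PPG+ image
#'
#' Renders the Hilbert spectra of a segment's PPG, first derivative (PPG')
#' and second derivative (PPG'') via [render_channel()] and assigns them to
#' the red, green and blue channels in that order. The derivative channels
#' raise the information dimension of the image: PPG' relates to aortic
#' flow velocity and PPG'' to vascular elasticity.
#'
#' @param spec_ppg,spec_d1,spec_d2 [hilbert_spectrum()]s of PPG, PPG', PPG''
#'   from the same segment (equal duration).
#' @param label Optional JNC7 class for the segment.
#' @param segment_id Optional identifier.
#' @param width,height Rendered resolution (defaults 1247 x 770).
#' @return A `ppgplus_image`: integer array `height x width x 3` in 0..255
#'   with attributes `label` and `segment_id`.
#' @export
compose_ppgplus <- function(spec_ppg, spec_d1, spec_d2, label = NA,
                            segment_id = NA_character_,
                            width = 1247, height = 770) {
  specs <- list(spec_ppg, spec_d1, spec_d2)
  ok <- purrr::every(specs, inherits, "hilbert_spectrum")
  if (!ok) stop("all three inputs must be hilbert_spectrum objects", call. = FALSE)
  durs <- purrr::map_dbl(specs, "duration_s")
  if (max(durs) - min(durs) > 1e-9) {
    stop("channel spectra have mismatched time extents", call. = FALSE)
  }
  arr <- array(0L, dim = c(height, width, 3))
  for (ch in 1:3) arr[, , ch] <- render_channel(specs[[ch]], width, height)
  structure(arr, label = label, segment_id = segment_id,
            class = "ppgplus_image")
}

#' @export
print.ppgplus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ppgplus_image> %d x %d x %d, label: %s, segment: %s\n",
              d[1], d[2], d[3], as.character(attr(x, "label")),
              attr(x, "segment_id")))
  invisible(x)
}

#' Seeded training-time augmentation
#'
#' Random aspect-ratio crop (area scale 0.7–1.0 of the image, aspect ratio
#' 3/4–4/3), horizontal flip with probability `flip_p`, then a centre crop
#' to a square. Fully reproducible from `seed`. Intended for the training
#' split only; the evaluation path is the deterministic centre crop inside
#' [to_network_input()].
#'
#' @param img A `ppgplus_image`.
#' @param seed Integer seed.
#' @param scale Length-2 area-fraction range of the random crop.
#' @param ratio Length-2 aspect-ratio (width/height) range.
#' @param flip_p Probability of a horizontal flip.
#' @param force_flip `NA` (random), `TRUE` or `FALSE`; overrides `flip_p`.
#' @return A `ppgplus_image` (square, side = min of crop dims).
#' @export
augment <- function(img, seed = 1L, scale = c(0.7, 1), ratio = c(3 / 4, 4 / 3),
                    flip_p = 0.5, force_flip = NA) {
  stopifnot(inherits(img, "ppgplus_image"))
  h <- dim(img)[1]; w <- dim(img)[2]
  crop <- with_seed(seed, function() {
    area <- runif(1, scale[1], scale[2]) * h * w
    ar <- exp(runif(1, log(ratio[1]), log(ratio[2])))
    cw <- min(w, round(sqrt(area * ar)))
    ch <- min(h, round(sqrt(area / ar)))
    top <- sample.int(h - ch + 1L, 1)
    left <- sample.int(w - cw + 1L, 1)
    flip <- if (is.na(force_flip)) runif(1) < flip_p else isTRUE(force_flip)
    list(top = top, left = left, ch = ch, cw = cw, flip = flip)
  })
  out <- img[crop$top:(crop$top + crop$ch - 1L),
             crop$left:(crop$left + crop$cw - 1L), , drop = FALSE]
  if (crop$flip) out <- out[, rev(seq_len(dim(out)[2])), , drop = FALSE]
  side <- min(dim(out)[1:2])
  r0 <- (dim(out)[1] - side) %/% 2
  c0 <- (dim(out)[2] - side) %/% 2
  out <- out[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), , drop = FALSE]
  structure(out, label = attr(img, "label"),
            segment_id = attr(img, "segment_id"), class = "ppgplus_image")
}

# Vectorised bilinear resampling of a matrix to out_h x out_w.
bilinear_resize <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  ry <- (seq_len(out_h) - 0.5) / out_h * in_h + 0.5
  rx <- (seq_len(out_w) - 0.5) / out_w * in_w + 0.5
  y0 <- pmin(pmax(floor(ry), 1), in_h); y1 <- pmin(y0 + 1, in_h)
  x0 <- pmin(pmax(floor(rx), 1), in_w); x1 <- pmin(x0 + 1, in_w)
  wy <- pmin(pmax(ry - y0, 0), 1); wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  top <- a + sweep(b - a, 2, wx, `*`)
  bot <- c_ + sweep(d - c_, 2, wx, `*`)
  top + sweep(bot - top, 1, wy, `*`)
}

# Per-channel standardisation constants: the widely used pretrained-backbone
# (ImageNet) channel statistics.
.norm_mean <- c(0.485, 0.456, 0.406)
.norm_sd <- c(0.229, 0.224, 0.225)

#' Convert a PPG+ image to a standardized network input tensor
#'
#' Deterministic evaluation path: centre crop to a square, bilinear resize
#' to `side x side`, scale intensities to [0, 1], then per-channel
#' standardisation with fixed pretrained-backbone channel statistics
#' (means 0.485/0.456/0.406, sds 0.229/0.224/0.225).
#'
#' @param img A `ppgplus_image` (augmented or not).
#' @param side Output spatial size (default 224).
#' @return A `network_input`: numeric array `3 x side x side`.
#' @export
to_network_input <- function(img, side = 224) {
  stopifnot(inherits(img, "ppgplus_image"))
  h <- dim(img)[1]; w <- dim(img)[2]
  sq <- min(h, w)
  r0 <- (h - sq) %/% 2; c0 <- (w - sq) %/% 2
  out <- array(0, dim = c(3, side, side))
  for (ch in 1:3) {
    m <- bilinear_resize(img[(r0 + 1):(r0 + sq), (c0 + 1):(c0 + sq), ch],
                         side, side)
    out[ch, , ] <- (m / 255 - .norm_mean[ch]) / .norm_sd[ch]
  }
  structure(out, label = attr(img, "label"),
            segment_id = attr(img, "segment_id"), class = "network_input")
}

#' Write / read a PPG+ image as PNG
#'
#' @param img A `ppgplus_image`.
#' @param path PNG path.
#' @return `path` invisibly (writer); a `ppgplus_image` (reader).
#' @export
write_ppgplus_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_ppgplus_png
#' @export
read_ppgplus_png <- function(path) {
  arr <- png::readPNG(path)
  structure(array(as.integer(round(arr * 255)), dim = dim(arr)),
            label = NA, segment_id = NA_character_, class = "ppgplus_image")
}

#' Stratified grouped train/test split and cross-validation folds
#'
#' Splits segments into train and test at `train_frac` (default 7:3),
#' stratified by class, then assigns the training rows to `k` folds, also
#' class-stratified. Both operations group by `record_id`: the two 5-s
#' segments of one record always land on the same side of the split and in
#' the same fold, so no record straddles train and test.
#'
#' @param manifest A tibble with columns `segment_id`, `record_id`, `class`.
#' @param k Number of folds (default 5).
#' @param train_frac Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return The manifest with added columns `split` (`"train"`/`"test"`) and
#'   `fold` (1..k for training rows, `NA` for test rows).
#' @export
make_folds <- function(manifest, k = 5, train_frac = 0.7, seed = 1L) {
  need <- c("segment_id", "record_id", "class")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns segment_id, record_id, class", call. = FALSE)
  }
  recs <- dplyr::distinct(manifest, .data$record_id, .data$class)
  counts <- table(recs$class)
  counts <- counts[counts > 0]
  if (any(counts < k)) {
    stop(sprintf("every class needs at least k = %d records for stratified folds", k),
         call. = FALSE)
  }
  # each class needs at least k records on the training side so every fold
  # can be evaluated against both trial classes
  n_train_cls <- pmin(pmax(round(train_frac * counts), k), counts - 1)
  if (any(n_train_cls < k)) {
    stop(sprintf("every class needs at least k = %d training records for stratified folds", k),
         call. = FALSE)
  }
  assign_tbl <- with_seed(seed, function() {
    purrr::map(names(counts), function(cl) {
      ids <- sample(recs$record_id[recs$class == cl])
      n_tr <- n_train_cls[[cl]]
      tr <- ids[seq_len(n_tr)]
      te <- ids[-seq_len(n_tr)]
      tibble::tibble(
        record_id = c(tr, te),
        split = c(rep("train", length(tr)), rep("test", length(te))),
        fold = c(rep_len(seq_len(k), length(tr)), rep(NA_integer_, length(te)))
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::left_join(manifest, assign_tbl, by = "record_id")
}
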