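# three spectra with distinct, known content for channel tests
make_specs <- function() {
  list(hilbert_spectrum(list(tone(1.2, 5))),
       hilbert_spectrum(list(tone(3.1, 5))),
       hilbert_spectrum(list(tone(6.4, 5))))
}

test_that("compose_ppgplus maps PPG, PPG', PPG'' onto R, G, B", {
  sp <- make_specs()
  img <- compose_ppgplus(sp[[1]], sp[[2]], sp[[3]], label = "NT",
                         segment_id = "s1")
  expect_equal(dim(img), c(770, 1247, 3))
  expect_identical(attr(img, "label"), "NT")
  expect_equal(unclass(img)[, , 1], render_channel(sp[[1]]))
  expect_equal(unclass(img)[, , 2], render_channel(sp[[2]]))
  expect_equal(unclass(img)[, , 3], render_channel(sp[[3]]))

  # identical spectra -> R == G == B everywhere
  same <- compose_ppgplus(sp[[1]], sp[[1]], sp[[1]])
  expect_equal(unclass(same)[, , 1], unclass(same)[, , 2])
  expect_equal(unclass(same)[, , 2], unclass(same)[, , 3])

  # channel-role property: permuting inputs permutes channels identically
  perm <- compose_ppgplus(sp[[3]], sp[[1]], sp[[2]])
  expect_equal(unclass(perm)[, , 1], unclass(img)[, , 3])
  expect_equal(unclass(perm)[, , 2], unclass(img)[, , 1])

  # PPG-only mode: zeroed derivative spectra leave only red nonzero
  zero <- sp[[2]]; zero$matrix <- zero$matrix * 0
  only_r <- compose_ppgplus(sp[[1]], zero, zero)
  expect_gt(sum(unclass(only_r)[, , 1]), 0)
  expect_equal(sum(unclass(only_r)[, , 2:3]), 0)
})

test_that("augment is seeded, flips involutively and ends square", {
  sp <- make_specs()
  img <- compose_ppgplus(sp[[1]], sp[[2]], sp[[3]])

  a1 <- augment(img, seed = 9)
  a2 <- augment(img, seed = 9)
  expect_identical(a1, a2)
  expect_equal(dim(a1)[1], dim(a1)[2])

  # forced double flip restores the unflipped crop
  f1 <- augment(img, seed = 4, force_flip = TRUE)
  f0 <- augment(img, seed = 4, force_flip = FALSE)
  f11 <- unclass(f1)[, rev(seq_len(dim(f1)[2])), , drop = FALSE]
  expect_equal(as.integer(f11), as.integer(unclass(f0)))
})

test_that("to_network_input standardises to a 3 x 224 x 224 tensor", {
  sp <- make_specs()
  img <- compose_ppgplus(sp[[1]], sp[[2]], sp[[3]])
  x <- to_network_input(img)
  expect_equal(dim(x), c(3, 224, 224))

  # deterministic evaluation path
  expect_identical(to_network_input(img), x)

  # all-zero image -> per-channel constant (0 - mean) / sd
  zero_img <- structure(array(0L, dim = c(770, 1247, 3)), label = NA,
                        segment_id = NA_character_, class = "ppgplus_image")
  z <- to_network_input(zero_img)
  means <- c(0.485, 0.456, 0.406); sds <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) {
    expect_equal(unique(round(as.numeric(z[ch, , ]), 10)),
                 round(-means[ch] / sds[ch], 10))
  }
})

test_that("ppgplus PNG writer round-trips pixel-exactly", {
  sp <- make_specs()
  img <- compose_ppgplus(sp[[1]], sp[[2]], sp[[3]], segment_id = "seg1")
  path <- withr::local_tempfile(fileext = ".png")
  write_ppgplus_png(img, path)
  back <- read_ppgplus_png(path)
  expect_equal(unclass(back), unclass(img), ignore_attr = TRUE)
})

test_that("make_folds stratifies 7:3, partitions folds and never splits a record", {
  man <- toy_manifest(50, rep(c("NT", "HT"), 25))
  out <- make_folds(man, k = 5, seed = 3)

  expect_equal(nrow(out), 100)
  expect_equal(sum(out$split == "train"), 70, tolerance = 2)

  # both segments of a record share split and fold
  by_rec <- dplyr::summarise(dplyr::group_by(out, .data$record_id),
                             n_split = dplyr::n_distinct(.data$split),
                             n_fold = dplyr::n_distinct(.data$fold))
  expect_true(all(by_rec$n_split == 1))
  expect_true(all(by_rec$n_fold == 1))

  # folds partition the training rows
  tr <- out[out$split == "train", ]
  expect_false(any(is.na(tr$fold)))
  expect_true(all(table(tr$fold) > 0))
  expect_true(all(is.na(out$fold[out$split == "test"])))

  # stratification: class balance preserved on both sides within rounding
  tab <- table(out$split, out$class)
  expect_equal(tab["train", "NT"], tab["train", "HT"], tolerance = 2)

  expect_error(make_folds(toy_manifest(6, rep(c("NT", "HT"), 3)), k = 5),
               "at least k")
})
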