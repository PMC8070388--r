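test_that("adapted backbones expose the documented head structure", {
  alex <- adapt_backbone(model_spec("alexnet", dropout_p = 0.6))
  last <- alex$layers[[length(alex$layers)]]
  expect_identical(last$type, "linear")
  expect_equal(c(last$n_in, last$n_out), c(4096, 2))
  expect_identical(alex$layers[[length(alex$layers) - 1]]$type, "dropout")
  expect_equal(alex$layers[[length(alex$layers) - 1]]$p, 0.6)

  r18 <- adapt_backbone(model_spec("resnet18"))
  head18 <- r18$layers[[length(r18$layers)]]
  expect_equal(c(head18$n_in, head18$n_out), c(512, 2))
  expect_false(r18$executable)
  expect_error(ppgplus:::model_forward(r18, array(0, c(3, 224, 224))),
               "counting/config")

  expect_error(model_spec("vgg16"))
})

test_that("adapted alexnet matches the published parameter and MAC budget", {
  alex <- adapt_backbone(model_spec("alexnet"))
  expect_equal(round(count_parameters(alex) / 1e6, 2), 57.01)
  expect_equal(round(count_macs(alex) / 1e9, 2), 0.71)

  # invariant to dropout probability (dropout carries no weights)
  alex2 <- adapt_backbone(model_spec("alexnet", dropout_p = 0.1))
  expect_equal(count_parameters(alex2), count_parameters(alex))

  # forward pass emits a length-2 output
  x <- structure(array(0.1, dim = c(3, 224, 224)), class = "network_input")
  out <- ppgplus:::model_forward(alex, x)$out
  expect_length(out, 2)
})

test_that("parameter and MAC counting agree with hand-computed layers", {
  lin_model <- structure(list(
    backbone = "toy", layers = list(ppgplus:::layer_flatten(),
                                    ppgplus:::layer_linear(4096, 2)),
    params = NULL, executable = FALSE, input_shape = c(1L, 64L, 64L)
  ), class = "ppg_model")
  expect_equal(count_parameters(lin_model), 4096 * 2 + 2)
  expect_equal(count_macs(lin_model), 8192)

  conv_model <- structure(list(
    backbone = "toy", layers = list(ppgplus:::layer_conv(1, 1, 3)),
    params = NULL, executable = FALSE, input_shape = c(1L, 12L, 12L)
  ), class = "ppg_model")
  # 3x3 kernel, valid 10x10 output: 9 kernel ops x 100 positions
  expect_equal(count_macs(conv_model), 900)
})

test_that("compute_metrics reproduces hand-computed confusion arithmetic", {
  # TP=3, FN=1, TN=2, FP=2
  scores <- c(0.9, 0.8, 0.6, 0.2, 0.7, 0.55, 0.3, 0.1)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- compute_metrics(scores, labels)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(3, 1, 2, 2))
  expect_equal(m$tpr, 0.75)
  expect_equal(m$tnr, 0.5)
  expect_equal(m$f1, 2 / 3)

  # metric identities
  fnr <- m$fn / (m$fn + m$tp); fpr <- m$fp / (m$fp + m$tn)
  expect_equal(m$tpr + fnr, 1)
  expect_equal(m$tnr + fpr, 1)

  # perfect prediction
  p <- compute_metrics(c(.9, .8, .1, .2), c(1, 1, 0, 0))
  expect_equal(c(p$f1, p$tpr, p$tnr, p$auc), c(1, 1, 1, 1))

  # constant scores: two-point diagonal, AUC 1/2
  cst <- compute_metrics(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(cst$auc, 0.5)
  expect_true(all(diff(cst$roc$fpr) >= 0) && all(diff(cst$roc$tpr) >= 0))

  expect_error(compute_metrics(c(.1, .9), c(1, 1)), "both classes")
})

test_that("ROC AUC equals the Mann-Whitney statistic", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    scores <- c(round(runif(n1), 2), round(runif(n0), 2))  # forces ties
    labels <- c(rep(1, n1), rep(0, n0))
    m <- compute_metrics(scores, labels)
    # independent oracle: pairwise enumeration with 1/2 for ties
    s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
    u <- 0
    for (a in s1) for (b in s0) u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(m$auc, u / (n1 * n0), tolerance = 1e-9)
  }
})

test_that("ROC AUC agrees with an independent ROC implementation", {
  set.seed(99)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)  # guarantee both classes
  m <- compute_metrics(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$auc, ref, tolerance = 1e-9)
})

test_that("ROC starts at (0,0), ends at (1,1) and is monotone", {
  set.seed(5)
  m <- compute_metrics(runif(30), rbinom(30, 1, 0.5) | c(1, rep(0, 29)))
  expect_equal(unlist(m$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(m$roc[nrow(m$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(m$roc$fpr) >= 0))
  expect_true(all(diff(m$roc$tpr) >= 0))
})

test_that("train_cv learns a separable toy problem and is seed-deterministic", {
  # trivially separable 3 x 224 x 224 tensors (class-dependent block pattern)
  mk <- function(cl, j) {
    base <- array(0, dim = c(3, 224, 224))
    if (cl == "NT") base[1, 1:112, ] <- 1 else base[1, 113:224, ] <- 1
    set.seed(1000 + j)
    structure(base + array(rnorm(3 * 224 * 224, 0, 0.05), dim = dim(base)),
              class = "network_input")
  }
  n <- 24
  classes <- rep(c("NT", "HT"), n / 2)
  inputs <- purrr::map(seq_len(n), ~ mk(classes[.x], .x))
  folds <- rep(1:2, each = 2, length.out = n)
  cfg <- train_config(epochs = 3, k_folds = 2, batch_size = 8, seed = 11)

  fit <- train_cv(inputs, classes, folds, trial_spec("nt_vs_ht"),
                  model_spec("small_cnn"), cfg)
  expect_gte(fit$mean_metrics$f1, 0.9)

  fit2 <- train_cv(inputs, classes, folds, trial_spec("nt_vs_ht"),
                   model_spec("small_cnn"), cfg)
  expect_equal(fit$per_fold, fit2$per_fold)

  # fold-averaged metrics are invariant to fold order
  perm <- c(which(folds == 2), which(folds == 1))
  fit3 <- train_cv(inputs[perm], classes[perm], folds[perm],
                   trial_spec("nt_vs_ht"), model_spec("small_cnn"), cfg)
  expect_equal(fit3$mean_metrics$f1, fit$mean_metrics$f1)

  # tidy/glance accessors
  expect_equal(nrow(tidy(fit)), 2)
  expect_true(all(c("trial", "backbone", "f1") %in% names(glance(fit))))
})

test_that("trial specs map JNC7 classes onto the binary tasks", {
  cls <- c("NT", "PHT", "HT")
  expect_equal(ppgplus:::trial_binary_labels(cls, trial_spec("nt_vs_ht")),
               c(1, NA, 0))
  expect_equal(ppgplus:::trial_binary_labels(cls, trial_spec("nt_vs_pht")),
               c(1, 0, NA))
  expect_equal(ppgplus:::trial_binary_labels(cls, trial_spec("ntpht_vs_ht")),
               c(1, 1, 0))
})
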