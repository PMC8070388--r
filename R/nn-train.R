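#' Binary trial specification
#'
#' Maps JNC7 classes onto the positive/negative classes of the three binary
#' trials. The normotension side is scored as the positive class for the
#' trials that contain it (sensitivity = fraction of actual NT(+PHT)
#' samples recovered); for `nt_vs_pht` the NT side is positive as well.
#'
#' @param name `"nt_vs_ht"`, `"nt_vs_pht"` or `"ntpht_vs_ht"`.
#' @return A `trial_spec` with fields `name`, `positive` and `negative`
#'   (character vectors of JNC7 classes).
#' @export
trial_spec <- function(name = c("nt_vs_ht", "nt_vs_pht", "ntpht_vs_ht")) {
  name <- match.arg(name)
  mapping <- switch(name,
    nt_vs_ht = list(positive = "NT", negative = "HT"),
    nt_vs_pht = list(positive = "NT", negative = "PHT"),
    ntpht_vs_ht = list(positive = c("NT", "PHT"), negative = "HT")
  )
  structure(c(list(name = name), mapping), class = "trial_spec")
}

# Map JNC7 labels to binary 1 (positive) / 0 (negative); NA = not in trial.
trial_binary_labels <- function(classes, trial) {
  cls <- as.character(classes)
  out <- rep(NA_real_, length(cls))
  out[cls %in% trial$positive] <- 1
  out[cls %in% trial$negative] <- 0
  out
}

#' Confusion-matrix metrics and ROC curve
#'
#' Thresholds the positive-class scores at `threshold` to obtain confusion
#' counts, and sweeps all distinct score values for the ROC curve. F1 is
#' the harmonic mean of precision and recall on the positive class; TPR is
#' sensitivity, TNR specificity. The AUC is the trapezoidal area under the
#' sweep.
#'
#' @param scores Numeric vector of positive-class scores in [0, 1].
#' @param labels Binary truth (1 = positive, 0 = negative); both classes
#'   must be present.
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_metrics` list: `f1`, `tpr`, `tnr`, `precision`,
#'   `accuracy`, `auc`, confusion counts `tp`/`fp`/`tn`/`fn`, and `roc`
#'   (tibble of `fpr`, `tpr` from (0,0) to (1,1)).
#' @examples
#' compute_metrics(c(.9, .8, .7, .4, .6, .2, .3, .1),
#'                 c(1, 1, 1, 1, 0, 0, 0, 0))$f1
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("metrics undefined: both classes must be present in the truth",
         call. = FALSE)
  }
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  # ROC threshold sweep: predict positive at score >= t for each distinct t
  ts <- sort(unique(scores), decreasing = TRUE)
  tpr_pts <- c(0, purrr::map_dbl(ts, ~ sum(scores >= .x & labels == 1) / n_pos))
  fpr_pts <- c(0, purrr::map_dbl(ts, ~ sum(scores >= .x & labels == 0) / n_neg))
  if (tpr_pts[length(tpr_pts)] != 1 || fpr_pts[length(fpr_pts)] != 1) {
    tpr_pts <- c(tpr_pts, 1); fpr_pts <- c(fpr_pts, 1)
  }
  auc <- sum(diff(fpr_pts) * (head(tpr_pts, -1) + tail(tpr_pts, -1)) / 2)

  structure(list(
    f1 = f1, tpr = recall, tnr = tn / (tn + fp),
    precision = precision, accuracy = (tp + tn) / length(labels),
    auc = auc, tp = tp, fp = fp, tn = tn, fn = fn,
    roc = tibble::tibble(fpr = fpr_pts, tpr = tpr_pts)
  ), class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> F1 %.4f | TPR %.4f | TNR %.4f | AUC %.4f (TP %d FP %d TN %d FN %d)\n",
              x$f1, x$tpr, x$tnr, x$auc, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs Training epochs per fold (default 25).
#' @param k_folds Number of cross-validation folds (default 5).
#' @param batch_size Mini-batch size (default 16).
#' @param seed Integer seed covering initialisation, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 25, k_folds = 5,
                         batch_size = 16, seed = 1L) {
  stopifnot(epochs >= 1, k_folds >= 2, batch_size >= 1, learning_rate > 0)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs), k_folds = as.integer(k_folds),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  purrr::map(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$W
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$b
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$b^2
    bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

# Softmax cross-entropy training of an executable model on a list of
# network_input tensors with binary labels (values 1..n_outputs).
# Class-balanced loss weighting (w_c = n / (K * n_c)) keeps the 0.5 score
# threshold meaningful when fold class counts are unequal and prevents
# majority-class collapse in short training runs.
train_model <- function(model, inputs, labels, cfg,
                        eval_inputs = NULL, eval_labels = NULL) {
  stopifnot(inherits(model, "ppg_model"), isTRUE(model$executable))
  n <- length(inputs)
  tab <- table(factor(labels, levels = sort(unique(labels))))
  cls_w <- as.numeric(n / (length(tab) * tab))
  names(cls_w) <- names(tab)
  state <- adam_init(model$params)
  t_step <- 0
  log <- vector("list", cfg$epochs)
  with_seed(derive_seed(cfg$seed, 17L), function() {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        grad_acc <- NULL
        for (j in idx) {
          fw <- model_forward(model, inputs[[j]], training = TRUE)
          p <- softmax(fw$out)
          y <- numeric(length(p)); y[labels[j]] <- 1
          if (which.max(p) == labels[j]) correct <- correct + 1
          wj <- cls_w[[as.character(labels[j])]]
          g <- model_backward(model, fw$caches, wj * (p - y))
          if (is.null(grad_acc)) {
            grad_acc <- g
          } else {
            for (i in seq_along(g)) {
              if (!is.null(g[[i]])) {
                grad_acc[[i]]$W <- grad_acc[[i]]$W + g[[i]]$W
                grad_acc[[i]]$b <- grad_acc[[i]]$b + g[[i]]$b
              }
            }
          }
        }
        for (i in seq_along(grad_acc)) {
          if (!is.null(grad_acc[[i]])) {
            grad_acc[[i]]$W <- grad_acc[[i]]$W / length(idx)
            grad_acc[[i]]$b <- grad_acc[[i]]$b / length(idx)
          }
        }
        t_step <<- t_step + 1
        upd <- adam_step(model$params, grad_acc, state, cfg$learning_rate, t_step)
        model$params <<- upd$params
        state <<- upd$state
      }
      train_acc <- correct / n
      eval_acc <- NA_real_
      if (!is.null(eval_inputs)) {
        preds <- purrr::map_int(eval_inputs, function(x) {
          which.max(model_forward(model, x)$out)
        })
        eval_acc <- mean(preds == eval_labels)
      }
      log[[epoch]] <<- tibble::tibble(epoch = epoch, train_acc = train_acc,
                                      eval_acc = eval_acc)
    }
  })
  model$history <- dplyr::bind_rows(log)
  model
}

# Positive-class (class index 1) softmax scores for a list of inputs.
predict_scores <- function(model, inputs) {
  purrr::map_dbl(inputs, function(x) softmax(model_forward(model, x)$out)[1])
}

#' Train and evaluate under k-fold cross-validation
#'
#' For each fold: trains a freshly initialised model on the remaining
#' folds for `cfg$epochs` epochs with Adam and softmax cross-entropy, then
#' evaluates on the held-out fold with [compute_metrics()]. Output class 1
#' is the trial's positive class. Fully deterministic given `cfg$seed`.
#'
#' @param inputs List of `network_input` tensors.
#' @param classes JNC7 classes aligned with `inputs`.
#' @param folds Integer fold assignment aligned with `inputs` (from
#'   [make_folds()]); rows with `NA` fold are ignored.
#' @param trial A [trial_spec()]; segments outside the trial are dropped.
#' @param spec A [model_spec()] (must be executable).
#' @param cfg A [train_config()].
#' @return A `cv_fit`: per-fold metrics, mean metrics, per-fold ROC curves
#'   and training history. Use [tidy()] / [glance()] to extract tables.
#' @export
train_cv <- function(inputs, classes, folds, trial, spec, cfg) {
  stopifnot(inherits(trial, "trial_spec"), inherits(spec, "model_spec"),
            inherits(cfg, "train_config"))
  ybin <- trial_binary_labels(classes, trial)
  use <- which(!is.na(ybin) & !is.na(folds))
  inputs <- inputs[use]; ybin <- ybin[use]; folds <- folds[use]
  # class index 1 = positive, 2 = negative
  ycls <- ifelse(ybin == 1, 1L, 2L)
  fold_ids <- sort(unique(folds))
  if (length(fold_ids) < 2) stop("need at least 2 folds", call. = FALSE)

  fold_results <- purrr::map(fold_ids, function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(te) == 0 || length(tr) == 0) {
      stop(sprintf("fold %d is empty", f), call. = FALSE)
    }
    model <- adapt_backbone(spec, seed = derive_seed(cfg$seed, 100L + f))
    fit_cfg <- cfg
    fit_cfg$seed <- derive_seed(cfg$seed, 200L + f)
    model <- train_model(model, inputs[tr], ycls[tr], fit_cfg)
    scores <- predict_scores(model, inputs[te])
    list(fold = f, metrics = compute_metrics(scores, ybin[te]),
         history = model$history, n_train = length(tr), n_test = length(te))
  })

  per_fold <- purrr::map_dfr(fold_results, function(r) {
    m <- r$metrics
    tibble::tibble(fold = r$fold, f1 = m$f1, tpr = m$tpr, tnr = m$tnr,
                   accuracy = m$accuracy, auc = m$auc,
                   n_train = r$n_train, n_test = r$n_test)
  })
  structure(list(
    trial = trial$name, backbone = spec$backbone,
    per_fold = per_fold,
    mean_metrics = dplyr::summarise(per_fold,
      dplyr::across(c("f1", "tpr", "tnr", "accuracy", "auc"), mean)),
    rocs = purrr::map(fold_results, ~ .x$metrics$roc),
    history = purrr::map_dfr(fold_results,
      ~ dplyr::mutate(.x$history, fold = .x$fold)),
    config = cfg
  ), class = "cv_fit")
}

#' @export
print.cv_fit <- function(x, ...) {
  cat(sprintf("<cv_fit> %s on %s, %d folds\n", x$backbone, x$trial,
              nrow(x$per_fold)))
  cat(sprintf("  mean F1 %.4f | TPR %.4f | TNR %.4f | AUC %.4f\n",
              x$mean_metrics$f1, x$mean_metrics$tpr, x$mean_metrics$tnr,
              x$mean_metrics$auc))
  invisible(x)
}

#' @rdname train_cv
#' @param x A `cv_fit`.
#' @param ... Unused.
#' @export
tidy.cv_fit <- function(x, ...) x$per_fold

#' @rdname train_cv
#' @export
glance.cv_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(trial = x$trial, backbone = x$backbone,
                   k = nrow(x$per_fold)),
    x$mean_metrics
  )
}

#' @export
autoplot.cv_fit <- function(object, type = c("roc", "history"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    df <- purrr::map_dfr(seq_along(object$rocs), function(i) {
      dplyr::mutate(object$rocs[[i]], fold = factor(i))
    })
    ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr,
                                     colour = .data$fold)) +
      ggplot2::geom_path() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate")
  } else {
    ggplot2::ggplot(object$history,
                    ggplot2::aes(.data$epoch, .data$train_acc,
                                 colour = factor(.data$fold))) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "training accuracy", colour = "fold")
  }
}
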