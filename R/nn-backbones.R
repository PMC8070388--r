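#' Model specification for backbone adaptation
#'
#' Describes which backbone to adapt for the two-output blood-pressure
#' trials, the dropout probability of the new head and whether retained
#' layers start from the "pretrained" initialisation policy. This package
#' ships no external weight archives: `pretrained = TRUE` keeps the
#' fine-tuning structure (which layers are retained vs reinitialised) with
#' seeded random weights for the retained layers.
#'
#' @param backbone One of `"alexnet"`, `"resnet18"`, `"resnet34"`,
#'   `"small_cnn"`. `alexnet` and `small_cnn` are executable; the ResNets
#'   are configuration slots supporting adaptation and parameter/MAC
#'   counting only.
#' @param dropout_p Dropout probability of the adapted head. Defaults to
#'   0.6 for the wide AlexNet/ResNet heads and 0.2 for `small_cnn`, whose
#'   64-unit head over-regularises at 0.6.
#' @param n_outputs Number of output classes (2 for the binary trials).
#' @param pretrained Initialisation policy flag (see Description).
#' @return A `model_spec` list.
#' @export
model_spec <- function(backbone = c("small_cnn", "alexnet", "resnet18", "resnet34"),
                       dropout_p = NULL, n_outputs = 2, pretrained = FALSE) {
  backbone <- match.arg(backbone)
  if (is.null(dropout_p)) {
    dropout_p <- if (backbone == "small_cnn") 0.2 else 0.6
  }
  if (!is.numeric(dropout_p) || dropout_p < 0 || dropout_p >= 1) {
    stop("dropout_p must lie in [0, 1)", call. = FALSE)
  }
  structure(list(backbone = backbone, dropout_p = dropout_p,
                 n_outputs = as.integer(n_outputs),
                 pretrained = isTRUE(pretrained)),
            class = "model_spec")
}

# AlexNet feature + classifier stack (five conv, three affine layers),
# ending in the original 1000-way layer; adaptation replaces that layer.
alexnet_layers <- function() {
  list(
    layer_conv(3, 64, 11, stride = 4, pad = 2), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(64, 192, 5, stride = 1, pad = 2), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(192, 384, 3, stride = 1, pad = 1), layer_relu(),
    layer_conv(384, 256, 3, stride = 1, pad = 1), layer_relu(),
    layer_conv(256, 256, 3, stride = 1, pad = 1), layer_relu(),
    layer_maxpool(3, 2),
    layer_flatten(),
    layer_dropout(0.5), layer_linear(9216, 4096), layer_relu(),
    layer_dropout(0.5), layer_linear(4096, 4096), layer_relu(),
    layer_linear(4096, 1000)
  )
}

# Compact 3-conv-block CNN for CPU-scale experiments: input zero-centering
# (spectrograms are mostly background, far from the natural-image channel
# statistics the standardisation constants assume), an input reduction
# (average pooling 224 -> 56), three conv/relu/pool blocks and two affine
# layers.
small_cnn_layers <- function(dropout_p, n_outputs) {
  list(
    layer_center(),
    layer_avgpool(4, 4),
    layer_conv(3, 8, 3, stride = 1, pad = 1), layer_relu(), layer_maxpool(2, 2),
    layer_conv(8, 16, 3, stride = 1, pad = 1), layer_relu(), layer_maxpool(2, 2),
    layer_conv(16, 32, 3, stride = 1, pad = 1), layer_relu(), layer_maxpool(2, 2),
    layer_flatten(),
    layer_linear(32 * 7 * 7, 64), layer_relu(), layer_dropout(dropout_p),
    layer_linear(64, n_outputs)
  )
}

resnet_basic_block <- function(in_ch, out_ch, stride) {
  blk <- list(
    layer_conv(in_ch, out_ch, 3, stride = stride, pad = 1),
    layer_batchnorm(out_ch), layer_relu(),
    layer_conv(out_ch, out_ch, 3, stride = 1, pad = 1),
    layer_batchnorm(out_ch)
  )
  if (stride != 1 || in_ch != out_ch) {
    blk <- c(blk, list(layer_conv(in_ch, out_ch, 1, stride = stride, pad = 0),
                       layer_batchnorm(out_ch)))
  }
  c(blk, list(layer_relu()))
}

resnet_layers <- function(blocks_per_stage) {
  layers <- list(
    layer_conv(3, 64, 7, stride = 2, pad = 3), layer_batchnorm(64),
    layer_relu(), layer_maxpool(3, 2, pad = 1)
  )
  widths <- c(64, 128, 256, 512)
  in_ch <- 64
  for (s in seq_along(widths)) {
    for (b in seq_len(blocks_per_stage[s])) {
      stride <- if (s > 1 && b == 1) 2 else 1
      layers <- c(layers, resnet_basic_block(in_ch, widths[s], stride))
      in_ch <- widths[s]
    }
  }
  c(layers, list(layer_avgpool(7, 1), layer_flatten(),
                 layer_linear(512, 1000)))
}

#' Adapt a backbone for the two-class blood-pressure trials
#'
#' Fine-tuning head surgery: for AlexNet, the final 1000-way affine layer is
#' removed and replaced by `dropout(dropout_p)` plus a fresh 4096 -> 2
#' affine layer; for ResNet18/34, the final affine layer is replaced by a
#' fresh 512 -> 2 layer; `small_cnn` is built directly at the requested
#' width. Retained layers keep their (seeded) initialisation, the new head
#' is always freshly initialised.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialisation.
#' @return A `ppg_model`: layer stack plus parameters, ready for
#'   [count_parameters()], [count_macs()] and (for executable backbones)
#'   training.
#' @examples
#' m <- adapt_backbone(model_spec("alexnet"))
#' count_parameters(m) / 1e6 # 57.01
#' @export
adapt_backbone <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  layers <- switch(spec$backbone,
    alexnet = {
      base <- alexnet_layers()
      c(base[seq_len(length(base) - 1)],
        list(layer_dropout(spec$dropout_p),
             layer_linear(4096, spec$n_outputs)))
    },
    small_cnn = small_cnn_layers(spec$dropout_p, spec$n_outputs),
    resnet18 = {
      base <- resnet_layers(c(2, 2, 2, 2))
      c(base[seq_len(length(base) - 1)],
        list(layer_linear(512, spec$n_outputs)))
    },
    resnet34 = {
      base <- resnet_layers(c(3, 4, 6, 3))
      c(base[seq_len(length(base) - 1)],
        list(layer_linear(512, spec$n_outputs)))
    },
    stop(sprintf("unknown backbone '%s'", spec$backbone), call. = FALSE)
  )
  executable <- spec$backbone %in% c("alexnet", "small_cnn")
  params <- if (executable) init_params(layers, seed) else NULL
  structure(list(backbone = spec$backbone, spec = spec, layers = layers,
                 params = params, executable = executable,
                 input_shape = c(3L, 224L, 224L)),
            class = "ppg_model")
}

#' @export
print.ppg_model <- function(x, ...) {
  cat(sprintf("<ppg_model> %s: %d layers, %s parameters%s\n",
              x$backbone, length(x$layers),
              format(count_parameters(x), big.mark = ","),
              if (x$executable) "" else " (counting/config slot)"))
  invisible(x)
}

#' Count trainable parameters
#'
#' Sum of the sizes of all weight and bias arrays of parametrised layers
#' (convolution, affine, batch-norm scale/shift). Dropout and pooling carry
#' no weights.
#'
#' @param model A `ppg_model`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ppg_model"))
  sum(purrr::map_dbl(model$layers, function(l) {
    switch(l$type,
      conv = l$out_ch * (l$k * l$k * l$in_ch) + l$out_ch,
      linear = l$n_out * l$n_in + l$n_out,
      batchnorm = 2 * l$ch,
      0
    )
  }))
}

#' Count multiply–accumulate operations for one forward pass
#'
#' Analytic count over convolution (kernel size x input channels x output
#' positions x output channels) and affine layers (fan-in x fan-out).
#' Biases, activations, pooling and batch-norm are excluded by convention —
#' under that convention the adapted AlexNet at 3 x 224 x 224 counts
#' 0.71 GMACs.
#'
#' @param model A `ppg_model`.
#' @param input_shape `c(channels, height, width)`; default the model's.
#' @return MAC count (double).
#' @export
count_macs <- function(model, input_shape = NULL) {
  stopifnot(inherits(model, "ppg_model"))
  if (is.null(input_shape)) input_shape <- model$input_shape
  ch <- input_shape[1]; H <- input_shape[2]; W <- input_shape[3]
  flat <- NA_real_
  total <- 0
  for (l in model$layers) {
    switch(l$type,
      conv = {
        stopifnot(ch == l$in_ch)
        H <- conv_out_dim(H, l$k, l$stride, l$pad)
        W <- conv_out_dim(W, l$k, l$stride, l$pad)
        ch <- l$out_ch
        total <- total + as.double(H) * W * ch * (l$k * l$k * l$in_ch)
      },
      maxpool = ,
      avgpool = {
        H <- conv_out_dim(H, l$k, l$stride, l$pad)
        W <- conv_out_dim(W, l$k, l$stride, l$pad)
      },
      flatten = {
        flat <- as.double(ch) * H * W
      },
      linear = {
        n_in <- if (is.na(flat)) l$n_in else flat
        stopifnot(n_in == l$n_in)
        total <- total + as.double(l$n_in) * l$n_out
        flat <- l$n_out
      },
      relu = NULL,
      center = NULL,
      dropout = NULL,
      batchnorm = NULL,
      stop(sprintf("MAC counting does not support layer type '%s'", l$type),
           call. = FALSE)
    )
  }
  total
}
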