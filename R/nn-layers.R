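# Compact CPU CNN engine: sequential layer stacks with im2col-based
# convolution, pooling, affine and dropout layers, forward + backward.
# Activations are arrays dim c(H, W, C); vectors after flatten.
# Weight layout: conv W is (out_ch, k*k*in_ch) with patch columns ordered
# channel-major then kernel column-major; linear W is (out, in).

layer_conv <- function(in_ch, out_ch, k, stride = 1, pad = 0) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       stride = stride, pad = pad)
}
layer_relu <- function() list(type = "relu")
# zero-centers the whole input tensor; conditions sparse spectrogram inputs
# (mostly-background images) for ReLU stacks without touching the dataset
layer_center <- function() list(type = "center")
layer_maxpool <- function(k, stride = k, pad = 0) {
  list(type = "maxpool", k = k, stride = stride, pad = pad)
}
layer_avgpool <- function(k, stride = k, pad = 0) {
  list(type = "avgpool", k = k, stride = stride, pad = pad)
}
layer_dropout <- function(p) list(type = "dropout", p = p)
layer_flatten <- function() list(type = "flatten")
layer_linear <- function(n_in, n_out) list(type = "linear", n_in = n_in, n_out = n_out)
layer_batchnorm <- function(ch) list(type = "batchnorm", ch = ch)

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# im2col for one (H, W, C) array -> (k*k*C, Hout*Wout) matrix
im2col <- function(x, k, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  if (pad > 0) {
    xp <- array(0, dim = c(H + 2 * pad, W + 2 * pad, C))
    xp[(pad + 1):(pad + H), (pad + 1):(pad + W), ] <- x
    x <- xp
    H <- H + 2 * pad; W <- W + 2 * pad
  }
  Hout <- (H - k) %/% stride + 1L
  Wout <- (W - k) %/% stride + 1L
  ys <- seq(1L, by = stride, length.out = Hout)
  xs <- seq(1L, by = stride, length.out = Wout)
  cols <- matrix(0, nrow = k * k * C, ncol = Hout * Wout)
  r <- 0L
  for (c in seq_len(C)) {
    for (dx in 0:(k - 1)) {
      for (dy in 0:(k - 1)) {
        r <- r + 1L
        cols[r, ] <- x[ys + dy, xs + dx, c]
      }
    }
  }
  list(cols = cols, Hout = Hout, Wout = Wout)
}

# scatter-add of column gradients back to the (H, W, C) input
col2im <- function(dcols, in_dim, k, stride, pad) {
  H <- in_dim[1] + 2 * pad; W <- in_dim[2] + 2 * pad; C <- in_dim[3]
  Hout <- (H - k) %/% stride + 1L
  Wout <- (W - k) %/% stride + 1L
  ys <- seq(1L, by = stride, length.out = Hout)
  xs <- seq(1L, by = stride, length.out = Wout)
  dx_arr <- array(0, dim = c(H, W, C))
  r <- 0L
  for (c in seq_len(C)) {
    for (dx in 0:(k - 1)) {
      for (dy in 0:(k - 1)) {
        r <- r + 1L
        dx_arr[ys + dy, xs + dx, c] <- dx_arr[ys + dy, xs + dx, c] +
          matrix(dcols[r, ], Hout, Wout)
      }
    }
  }
  if (pad > 0) {
    dx_arr <- dx_arr[(pad + 1):(in_dim[1] + pad),
                     (pad + 1):(in_dim[2] + pad), , drop = FALSE]
  }
  dx_arr
}

layer_forward <- function(layer, params, x, training = FALSE) {
  switch(layer$type,
    conv = {
      ic <- im2col(x, layer$k, layer$stride, layer$pad)
      out_mat <- params$W %*% ic$cols + params$b
      out <- array(t(out_mat), dim = c(ic$Hout, ic$Wout, layer$out_ch))
      list(out = out, cache = list(cols = ic$cols, in_dim = dim(x),
                                   Hout = ic$Hout, Wout = ic$Wout))
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = list(mask = x > 0))
    },
    center = {
      list(out = x - mean(x), cache = NULL)
    },
    maxpool = {
      C <- dim(x)[3]
      ic1 <- im2col(x[, , 1, drop = FALSE], layer$k, layer$stride, layer$pad)
      n_out <- ic1$Hout * ic1$Wout
      out <- array(0, dim = c(ic1$Hout, ic1$Wout, C))
      argmax <- matrix(0L, nrow = n_out, ncol = C)
      vals <- ic1$cols
      for (c in seq_len(C)) {
        if (c > 1) {
          vals <- im2col(x[, , c, drop = FALSE], layer$k, layer$stride,
                         layer$pad)$cols
        }
        am <- max.col(t(vals), ties.method = "first")
        out[, , c] <- matrix(vals[cbind(am, seq_len(n_out))],
                             ic1$Hout, ic1$Wout)
        argmax[, c] <- am
      }
      list(out = out, cache = list(argmax = argmax, in_dim = dim(x),
                                   Hout = ic1$Hout, Wout = ic1$Wout))
    },
    avgpool = {
      C <- dim(x)[3]
      out <- NULL
      for (c in seq_len(C)) {
        ic <- im2col(x[, , c, drop = FALSE], layer$k, layer$stride, layer$pad)
        if (is.null(out)) out <- array(0, dim = c(ic$Hout, ic$Wout, C))
        out[, , c] <- matrix(colMeans(ic$cols), ic$Hout, ic$Wout)
      }
      list(out = out, cache = list(in_dim = dim(x)))
    },
    dropout = {
      if (training && layer$p > 0) {
        mask <- runif(length(x)) >= layer$p
        out <- x * mask / (1 - layer$p)
        list(out = out, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    flatten = {
      list(out = as.numeric(x), cache = list(in_dim = dim(x)))
    },
    linear = {
      xv <- as.numeric(x)
      list(out = as.numeric(params$W %*% xv + params$b),
           cache = list(x = xv))
    },
    stop(sprintf("layer type '%s' has no forward implementation", layer$type),
         call. = FALSE)
  )
}

layer_backward <- function(layer, params, dout, cache) {
  switch(layer$type,
    conv = {
      oc <- layer$out_ch
      dout_mat <- t(matrix(dout, ncol = oc))
      dW <- dout_mat %*% t(cache$cols)
      db <- rowSums(dout_mat)
      dcols <- crossprod(params$W, dout_mat)
      dx <- col2im(dcols, cache$in_dim, layer$k, layer$stride, layer$pad)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    center = list(dx = dout - mean(dout), grads = NULL),
    maxpool = {
      in_dim <- cache$in_dim
      C <- in_dim[3]
      k <- layer$k; stride <- layer$stride; pad <- layer$pad
      H <- in_dim[1] + 2 * pad; W <- in_dim[2] + 2 * pad
      ys <- seq(1L, by = stride, length.out = cache$Hout)
      xs <- seq(1L, by = stride, length.out = cache$Wout)
      # linear index (within padded slice) of element r of pooling window p
      base_y <- rep(ys, times = cache$Wout)
      base_x <- rep(xs, each = cache$Hout)
      dx <- array(0, dim = c(H, W, C))
      for (c in seq_len(C)) {
        am <- cache$argmax[, c] - 1L
        dy <- am %% k
        dxo <- am %/% k
        lin <- (base_x + dxo - 1L) * H + (base_y + dy)
        g <- as.numeric(dout[, , c])
        acc <- rowsum(g, lin)
        slice <- dx[, , c]
        slice[as.integer(rownames(acc))] <- acc[, 1]
        dx[, , c] <- slice
      }
      if (pad > 0) {
        dx <- dx[(pad + 1):(in_dim[1] + pad),
                 (pad + 1):(in_dim[2] + pad), , drop = FALSE]
      }
      list(dx = dx, grads = NULL)
    },
    avgpool = {
      dcols_template <- 1 / (layer$k^2)
      C <- cache$in_dim[3]
      n_out <- length(dout) / C
      dx <- array(0, dim = cache$in_dim)
      for (c in seq_len(C)) {
        g <- as.numeric(dout[, , c])
        dcols <- matrix(rep(g, each = layer$k^2) * dcols_template,
                        nrow = layer$k^2)
        dx[, , c] <- col2im(dcols, c(cache$in_dim[1], cache$in_dim[2], 1L),
                            layer$k, layer$stride, layer$pad)
      }
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask / (1 - layer$p), grads = NULL)
    },
    flatten = list(dx = array(dout, dim = cache$in_dim), grads = NULL),
    linear = {
      dout <- as.numeric(dout)
      list(dx = as.numeric(crossprod(params$W, dout)),
           grads = list(W = tcrossprod(dout, cache$x), b = dout))
    },
    stop(sprintf("layer type '%s' has no backward implementation", layer$type),
         call. = FALSE)
  )
}

# He-normal initialisation of all parametrised layers, seeded.
init_params <- function(layers, seed) {
  with_seed(seed, function() {
    purrr::map(layers, function(l) {
      switch(l$type,
        conv = {
          fan_in <- l$k * l$k * l$in_ch
          list(W = matrix(rnorm(l$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                          nrow = l$out_ch),
               b = numeric(l$out_ch))
        },
        linear = {
          list(W = matrix(rnorm(l$n_out * l$n_in, 0, sqrt(2 / l$n_in)),
                          nrow = l$n_out),
               b = numeric(l$n_out))
        },
        NULL
      )
    })
  })
}

model_forward <- function(model, x, training = FALSE) {
  if (!isTRUE(model$executable)) {
    stop(sprintf("backbone '%s' is a counting/config slot; executable backbones are %s",
                 model$backbone, "alexnet and small_cnn"), call. = FALSE)
  }
  if (inherits(x, "network_input")) x <- aperm(unclass(x), c(2, 3, 1))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], model$params[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

model_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], model$params[[i]], dout,
                         caches[[i]])
    dout <- bw$dx
    grads[i] <- list(bw$grads)
  }
  grads
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
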