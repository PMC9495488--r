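# Internal neural-network primitives.
#
# Tensors flow through the lead towers as 4-d arrays (H, W, B, C) with the
# 12 leads concatenated along the channel axis; each tower layer is a
# grouped 3x3 convolution (one filter block per lead, or a single shared
# block for tied towers) running as a direct C++ kernel, followed by fused
# batch-norm + ReLU. Dense layers use BLAS matrix products. Layers are
# environments holding parameters and Adam state; forward passes return the
# activation plus a cache, backward passes take the cache and return input
# gradients plus parameter gradients.

new_gconv_layer <- function(c_in, c_out, groups, shared = FALSE, k = 3,
                            batch_norm = TRUE, activation = "relu") {
  stopifnot(k == 3)  # the tower uses 3x3 kernels; the C++ kernel is fixed
  e <- new.env(parent = emptyenv())
  e$type <- "conv"; e$k <- k; e$c_in <- c_in; e$c_out <- c_out
  e$groups <- groups; e$shared <- shared
  ncols <- c_out * (if (shared) 1L else groups)
  e$W <- matrix(rnorm(k * k * c_in * ncols) * sqrt(2 / (k * k * c_in)),
                k * k * c_in, ncols)
  e$b <- numeric(ncols)
  e$activation <- activation
  if (batch_norm) e$bn <- new_bn_state(c_out * groups)
  e
}

new_pool_layer <- function(k, stride) {
  e <- new.env(parent = emptyenv())
  e$type <- "pool"; e$k <- k; e$stride <- stride
  e
}

new_dense_layer <- function(n_in, n_out, batch_norm = TRUE,
                            activation = "relu") {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"; e$n_in <- n_in; e$n_out <- n_out
  e$W <- matrix(rnorm(n_in * n_out) * sqrt(2 / n_in), n_in, n_out)
  e$b <- numeric(n_out)
  e$activation <- activation
  if (batch_norm) e$bn <- new_bn_state(n_out)
  e
}

new_bn_state <- function(n) {
  list(gamma = rep(1, n), beta = numeric(n),
       running_mean = numeric(n), running_var = rep(1, n))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# fused batch-norm (+ ReLU) over the channel columns of an (N x C) matrix
bn_apply <- function(layer, z, training, relu) {
  r <- bn_relu_fwd_cpp(z, layer$bn$gamma, layer$bn$beta,
                       layer$bn$running_mean, layer$bn$running_var,
                       training, relu, BN_MOMENTUM, BN_EPS)
  if (training) {
    layer$bn$running_mean <- r$running_mean
    layer$bn$running_var <- r$running_var
  }
  r
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      z <- conv3g_fwd_cpp(x, layer$W, layer$b, layer$groups, layer$shared)
      if (!is.null(layer$bn)) {
        r <- bn_apply(layer, z, training, relu = TRUE)
        cache <- if (training) {
          list(x = x, z = z, out = r$out, mean = r$mean, istd = r$istd)
        } else NULL
        list(out = r$out, cache = cache)
      } else {
        out <- if (identical(layer$activation, "relu")) pmax(z, 0) else z
        list(out = out, cache = list(x = x, out = out))
      }
    },
    pool = {
      r <- maxpool_fwd_cpp(x, layer$k, layer$stride)
      list(out = r$out, cache = list(argmax = r$argmax, in_dim = dim(x)))
    },
    dense = {
      z <- x %*% layer$W
      z <- z + rep(layer$b, each = nrow(z))
      if (!is.null(layer$bn)) {
        r <- bn_apply(layer, z, training,
                      relu = identical(layer$activation, "relu"))
        cache <- if (training) {
          list(x = x, z = z, out = r$out, mean = r$mean, istd = r$istd)
        } else NULL
        list(out = r$out, cache = cache)
      } else {
        out <- if (identical(layer$activation, "relu")) pmax(z, 0) else z
        list(out = out, cache = list(x = x, out = out))
      }
    }
  )
}

layer_backward <- function(layer, cache, dout, need_dx = TRUE) {
  switch(layer$type,
    conv = {
      dgamma <- dbeta <- NULL
      if (!is.null(layer$bn)) {
        r <- bn_relu_bwd_cpp(dout, cache$z, cache$out, cache$mean,
                             cache$istd, layer$bn$gamma, TRUE)
        dz <- r$dz
        dgamma <- r$dgamma; dbeta <- r$dbeta
      } else {
        dz <- dout * (cache$out > 0)
      }
      r2 <- conv3g_bwd_cpp(cache$x, layer$W, dz, layer$groups, layer$shared,
                           need_dx)
      list(dx = r2$dx,
           grads = list(W = r2$dW, b = r2$db, gamma = dgamma, beta = dbeta))
    },
    pool = {
      d <- cache$in_dim
      dx <- maxpool_bwd_cpp(dout, cache$argmax, d[1], d[2], d[3], d[4])
      list(dx = dx, grads = NULL)
    },
    dense = {
      dgamma <- dbeta <- NULL
      if (!is.null(layer$bn)) {
        if (is.null(dim(dout))) dim(dout) <- dim(cache$out)
        r <- bn_relu_bwd_cpp(dout, cache$z, cache$out, cache$mean,
                             cache$istd, layer$bn$gamma,
                             identical(layer$activation, "relu"))
        dz <- r$dz
        dgamma <- r$dgamma; dbeta <- r$dbeta
      } else {
        dz <- if (identical(layer$activation, "relu")) {
          dout * (cache$out > 0)
        } else dout
      }
      dW <- crossprod(cache$x, dz)
      db <- colSums(dz)
      dx <- tcrossprod(dz, layer$W)
      list(dx = dx, grads = list(W = dW, b = db, gamma = dgamma, beta = dbeta))
    }
  )
}

# Adam with bias correction; state lives in the layer environment.
layer_update <- function(layer, grads, lr, step,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(grads)) return(invisible(NULL))
  if (is.null(layer$adam)) layer$adam <- list()
  upd <- function(name, param, g) {
    if (is.null(g)) return(param)
    st <- layer$adam[[name]]
    if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    layer$adam[[name]] <- st  # layers are environments: reference update
    mhat <- st$m / (1 - beta1^step)
    vhat <- st$v / (1 - beta2^step)
    param - lr * mhat / (sqrt(vhat) + eps)
  }
  layer$W <- upd("W", layer$W, grads$W)
  layer$b <- upd("b", layer$b, grads$b)
  if (!is.null(layer$bn)) {
    layer$bn$gamma <- upd("gamma", layer$bn$gamma, grads$gamma)
    layer$bn$beta <- upd("beta", layer$bn$beta, grads$beta)
  }
  invisible(NULL)
}

layer_n_params <- function(layer) {
  n <- 0
  if (!is.null(layer$W)) n <- n + length(layer$W) + length(layer$b)
  if (!is.null(layer$bn)) n <- n + length(layer$bn$gamma) + length(layer$bn$beta)
  n
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
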