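#' Output size of a convolution or pooling layer
#'
#' The standard valid-convolution arithmetic
#' `floor((input + 2 * padding - kernel) / stride) + 1`. Propagating a
#' 64-pixel input through the published tower (conv kernel 3, stride 1, no
#' padding; pool kernels 4, 3, 4 at stride 2) reproduces the printed size
#' sequence 62, 60, 29, 27, 25, 12, 10, 8, 3.
#'
#' @param input_size,kernel,stride,padding Integers (pixels).
#' @return The output size in pixels.
#' @export
#' @examples
#' layer_output_size(64, 3, 1, 0) # 62
#' layer_output_size(60, 4, 2, 0) # 29
layer_output_size <- function(input_size, kernel, stride = 1, padding = 0) {
  stopifnot(stride >= 1, padding >= 0)
  if (kernel > input_size + 2 * padding) {
    abort(sprintf("kernel %d exceeds padded input %d", kernel,
                  input_size + 2 * padding), class = "ecgmi_error_config")
  }
  floor((input_size + 2 * padding - kernel) / stride) + 1
}

#' 12-branch CNN architecture
#'
#' Defines the multi-branch network: every lead gets its own tower of six
#' 3x3 valid convolutions (batch-normalized, ReLU) interleaved with three
#' max-pooling layers; the twelve flattened tower outputs are concatenated
#' and passed through two batch-normalized ReLU dense layers and a softmax
#' output layer. Towers do not share weights by default, so the model
#' learns each lead's morphology separately; set `share_tower_weights` for
#' the tied variant. With the default widths and `n_classes = 11` the
#' layer dimensions match the published table: per-tower flatten
#' 32 x 3 x 3 = 288, concatenated 3456, head 3456 -> 2048 -> 1024 -> 11.
#'
#' @param n_classes Number of output classes (>= 2); 2 for detection, 11 or
#'   8 for localization.
#' @param conv_channels Output channels of the six convolutions.
#' @param dense_units Sizes of the two hidden dense layers.
#' @param pool_kernels,pool_strides Pooling kernels and strides (strides
#'   are forced to 2 by the published dimensions).
#' @param input_px Input image side (64).
#' @param n_leads Number of branches (12).
#' @param share_tower_weights Tie tower weights across leads?
#' @return A list of class `ecg_cnn_architecture`.
#' @export
ecg_cnn_architecture <- function(n_classes = 11,
                                 conv_channels = c(4, 8, 16, 16, 32, 32),
                                 dense_units = c(2048, 1024),
                                 pool_kernels = c(4, 3, 4),
                                 pool_strides = c(2, 2, 2),
                                 input_px = 64,
                                 n_leads = 12,
                                 share_tower_weights = FALSE) {
  stopifnot(n_classes >= 2, length(conv_channels) == 6,
            length(dense_units) == 2, length(pool_kernels) == 3,
            length(pool_strides) == 3)
  arch <- structure(list(
    n_classes = as.integer(n_classes),
    conv_channels = as.integer(conv_channels),
    dense_units = as.integer(dense_units),
    conv_kernel = 3L,
    pool_kernels = as.integer(pool_kernels),
    pool_strides = as.integer(pool_strides),
    input_px = as.integer(input_px),
    n_leads = as.integer(n_leads),
    share_tower_weights = isTRUE(share_tower_weights)
  ), class = "ecg_cnn_architecture")
  shp <- architecture_shapes(arch)  # validates the shape arithmetic
  attr(arch, "concat_features") <- attr(shp, "concat_features")
  arch
}

#' @rdname ecg_cnn_architecture
#' @param arch An `ecg_cnn_architecture`.
#' @return `architecture_shapes()` returns a tibble with one row per tower
#'   layer (`layer`, `kind`, `kernel`, `stride`, `in_px`, `out_px`,
#'   `out_channels`) and attributes `flat_per_lead` and `concat_features`.
#' @export
architecture_shapes <- function(arch) {
  stopifnot(inherits(arch, "ecg_cnn_architecture"))
  kinds <- c("conv", "conv", "pool", "conv", "conv", "pool",
             "conv", "conv", "pool")
  kernels <- integer(9); strides <- integer(9); channels <- integer(9)
  ci <- 0; pi <- 0; ch <- 1L
  for (i in seq_len(9)) {
    if (kinds[i] == "conv") {
      ci <- ci + 1
      kernels[i] <- arch$conv_kernel; strides[i] <- 1L
      ch <- arch$conv_channels[ci]
    } else {
      pi <- pi + 1
      kernels[i] <- arch$pool_kernels[pi]; strides[i] <- arch$pool_strides[pi]
    }
    channels[i] <- ch
  }
  px <- arch$input_px
  in_px <- out_px <- integer(9)
  for (i in seq_len(9)) {
    in_px[i] <- px
    px <- layer_output_size(px, kernels[i], strides[i], 0)
    out_px[i] <- px
  }
  out <- tibble::tibble(
    layer = c(paste0("conv", 1:2), "pool1", paste0("conv", 3:4), "pool2",
              paste0("conv", 5:6), "pool3"),
    kind = kinds, kernel = kernels, stride = strides,
    in_px = in_px, out_px = out_px, out_channels = channels
  )
  flat <- channels[9] * out_px[9]^2
  attr(out, "flat_per_lead") <- flat
  attr(out, "concat_features") <- flat * arch$n_leads
  out
}

#' Build an initialized 12-branch CNN
#'
#' @param arch An [ecg_cnn_architecture()].
#' @param rng_seed Seed for weight initialization (He-normal).
#' @return A list of class `ecg_cnn` holding the tower and head layers.
#' @export
build_ecg_cnn <- function(arch = ecg_cnn_architecture(), rng_seed = 1) {
  stopifnot(inherits(arch, "ecg_cnn_architecture"))
  set.seed(rng_seed)
  shapes <- architecture_shapes(arch)
  cc <- arch$conv_channels
  g <- arch$n_leads
  sh <- arch$share_tower_weights
  tower <- list(
    new_gconv_layer(1, cc[1], g, sh), new_gconv_layer(cc[1], cc[2], g, sh),
    new_pool_layer(arch$pool_kernels[1], arch$pool_strides[1]),
    new_gconv_layer(cc[2], cc[3], g, sh), new_gconv_layer(cc[3], cc[4], g, sh),
    new_pool_layer(arch$pool_kernels[2], arch$pool_strides[2]),
    new_gconv_layer(cc[4], cc[5], g, sh), new_gconv_layer(cc[5], cc[6], g, sh),
    new_pool_layer(arch$pool_kernels[3], arch$pool_strides[3])
  )
  concat <- attr(shapes, "concat_features")
  head_layers <- list(
    new_dense_layer(concat, arch$dense_units[1]),
    new_dense_layer(arch$dense_units[1], arch$dense_units[2]),
    new_dense_layer(arch$dense_units[2], arch$n_classes,
                    batch_norm = FALSE, activation = "none")
  )
  structure(list(arch = arch, tower = tower, head = head_layers,
                 flat_per_lead = attr(shapes, "flat_per_lead"),
                 final_px = shapes$out_px[9],
                 step = new.env(parent = emptyenv())),
            class = "ecg_cnn")
}

model_n_params <- function(model) {
  sum(vapply(model$tower, layer_n_params, numeric(1))) +
    sum(vapply(model$head, layer_n_params, numeric(1)))
}

# forward pass over a batch; x is an (H, W, B, 12) array, leads as channels
cnn_forward <- function(model, x, training = FALSE) {
  b <- dim(x)[3]
  tc <- vector("list", length(model$tower))
  a <- x
  for (i in seq_along(model$tower)) {
    r <- layer_forward(model$tower[[i]], a, training)
    a <- r$out; tc[[i]] <- r$cache
  }
  # (oh, ow, B, C) -> B x (oh * ow * C); column order is internal only
  feats <- t(matrix(aperm(a, c(1, 2, 4, 3)), ncol = b))
  hc <- vector("list", length(model$head))
  h <- feats
  for (i in seq_along(model$head)) {
    r <- layer_forward(model$head[[i]], h, training)
    h <- r$out; hc[[i]] <- r$cache
  }
  list(logits = h, tower_caches = tc, head_caches = hc)
}

cnn_backward_and_update <- function(model, fwd, dlogits, lr) {
  st <- model$step
  st$t <- (st$t %||% 0) + 1
  tstep <- st$t
  dx <- dlogits
  for (i in rev(seq_along(model$head))) {
    r <- layer_backward(model$head[[i]], fwd$head_caches[[i]], dx)
    layer_update(model$head[[i]], r$grads, lr, tstep)
    dx <- r$dx
  }
  px <- model$final_px
  cfin <- model$arch$conv_channels[6] * model$arch$n_leads
  b <- nrow(dx)
  da <- aperm(array(t(dx), dim = c(px, px, cfin, b)), c(1, 2, 4, 3))
  for (i in rev(seq_along(model$tower))) {
    r <- layer_backward(model$tower[[i]], fwd$tower_caches[[i]], da,
                        need_dx = i > 1)
    layer_update(model$tower[[i]], r$grads, lr, tstep)
    da <- r$dx
  }
  invisible(NULL)
}

# image-set tibble -> (H, W, N, 12) array, pixels scaled to [0,1]
image_sets_to_tensors <- function(image_sets, side, gray_levels = 256) {
  n <- nrow(image_sets)
  imgs <- image_sets$images
  for (im in imgs) {
    if (!identical(dim(im), c(12L, side, side))) {
      abort(sprintf("image sets must be 12 x %d x %d arrays", side, side),
            class = "ecgmi_error_validation")
    }
  }
  a <- array(0, dim = c(side, side, n, 12L))
  for (i in seq_len(n)) {
    a[, , i, ] <- aperm(imgs[[i]], c(2, 3, 1))
  }
  a / (gray_levels - 1)
}

#' Training configuration
#'
#' Cross-entropy loss against one-hot labels and the Adam optimizer are
#' fixed; learning rate, batch size, epoch count and the RNG seed are
#' configurable.
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param epochs Number of passes over the training data (default 30).
#' @param rng_seed Seed controlling shuffling (default 1).
#' @param verbose Print per-epoch progress?
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64,
                         epochs = 30, rng_seed = 1, verbose = FALSE) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the 12-branch CNN on labeled image sets
#'
#' Mini-batch training with Adam on the softmax cross-entropy loss. Fully
#' deterministic given the model's initialization seed and the config seed
#' (single-threaded, no stochastic layers beyond shuffling).
#'
#' @param model An [build_ecg_cnn()] model (updated in place by reference
#'   and also returned inside the fit).
#' @param image_sets Image-set tibble (see [record_to_image_sets()]) with a
#'   `label` column.
#' @param config A [train_config()].
#' @param class_levels Class ordering for the output layer; defaults to the
#'   taxonomy order of the labels present. Length must equal the
#'   architecture's `n_classes`.
#' @return A list of class `ecg_cnn_fit`: `model`, `history` (tibble of
#'   epoch, loss, accuracy), `class_levels`, `config`.
#' @export
train_ecg_cnn <- function(model, image_sets, config = train_config(),
                          class_levels = NULL) {
  stopifnot(inherits(model, "ecg_cnn"))
  labs <- image_sets$label
  present <- unique(labs)
  if (length(present) < 2) {
    abort("training set must contain at least 2 classes",
          class = "ecgmi_error_validation")
  }
  if (is.null(class_levels)) {
    taxonomy <- mi_classes()$name
    ord <- taxonomy[taxonomy %in% present]
    class_levels <- if (length(ord) == length(present)) ord else sort(present)
  }
  if (length(class_levels) != model$arch$n_classes) {
    abort(sprintf("model has %d classes but %d class levels supplied",
                  model$arch$n_classes, length(class_levels)),
          class = "ecgmi_error_validation")
  }
  if (!all(labs %in% class_levels)) {
    abort(paste0("labels outside the class set: ",
                 paste(setdiff(labs, class_levels), collapse = ", ")),
          class = "ecgmi_error_validation")
  }
  side <- model$arch$input_px
  tensors <- image_sets_to_tensors(image_sets, side)
  y <- match(labs, class_levels)
  n <- length(y)
  k <- model$arch$n_classes
  set.seed(config$rng_seed)
  history <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      b <- length(idx)
      xb <- tensors[, , idx, , drop = FALSE]
      fwd <- cnn_forward(model, xb, training = TRUE)
      p <- softmax_rows(fwd$logits)
      onehot <- matrix(0, b, k)
      onehot[cbind(seq_len(b), y[idx])] <- 1
      loss <- -mean(log(pmax(p[cbind(seq_len(b), y[idx])], 1e-12)))
      tot_loss <- tot_loss + loss * b
      tot_correct <- tot_correct + sum(max.col(p, "first") == y[idx])
      cnn_backward_and_update(model, fwd, (p - onehot) / b,
                              config$learning_rate)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = tot_loss / n,
                                    accuracy = tot_correct / n)
    if (config$verbose) {
      message(sprintf("epoch %d: loss %.4f, accuracy %.4f",
                      ep, tot_loss / n, tot_correct / n))
    }
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 class_levels = class_levels, config = config),
            class = "ecg_cnn_fit")
}

#' Predict classes for image sets
#'
#' Applies the trained network and returns per-class softmax probabilities
#' and the argmax class. Exact probability ties break toward the lowest
#' class index.
#'
#' @param object An `ecg_cnn_fit`.
#' @param new_data Image-set tibble.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return A tibble with `.pred_class` and one `.pred_<class>` probability
#'   column per class; rows sum to 1.
#' @export
predict.ecg_cnn_fit <- function(object, new_data, batch_size = 64, ...) {
  model <- object$model
  side <- model$arch$input_px
  tensors <- image_sets_to_tensors(new_data, side)
  n <- nrow(new_data)
  k <- model$arch$n_classes
  probs <- matrix(0, n, k)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    xb <- tensors[, , idx, , drop = FALSE]
    fwd <- cnn_forward(model, xb, training = FALSE)
    probs[idx, ] <- softmax_rows(fwd$logits)
  }
  colnames(probs) <- paste0(".pred_", object$class_levels)
  out <- tibble::as_tibble(probs)
  out$.pred_class <- object$class_levels[max.col(probs, ties.method = "first")]
  dplyr::relocate(out, ".pred_class")
}

#' @rdname predict.ecg_cnn_fit
#' @param x An `ecg_cnn_fit`.
#' @export
tidy.ecg_cnn_fit <- function(x, ...) x$history

#' @rdname predict.ecg_cnn_fit
#' @export
glance.ecg_cnn_fit <- function(x, ...) {
  tibble::tibble(
    n_classes = x$model$arch$n_classes,
    n_parameters = model_n_params(x$model),
    epochs = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    final_accuracy = x$history$accuracy[nrow(x$history)]
  )
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat(sprintf(
    "<ecg_cnn> %d-branch CNN, %d classes, %s towers, %d parameters\n",
    x$arch$n_leads, x$arch$n_classes,
    if (x$arch$share_tower_weights) "shared" else "independent",
    model_n_params(x)))
  invisible(x)
}

#' @export
print.ecg_cnn_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ecg_cnn_fit> %d classes, %d parameters, %d epochs, final loss %.4f, final accuracy %.4f\n",
    g$n_classes, g$n_parameters, g$epochs, g$final_loss, g$final_accuracy))
  invisible(x)
}

#' Save and load model checkpoints
#'
#' Single-file, versioned checkpoints of a fitted model (weights, batch-norm
#' statistics, Adam state, class levels and history).
#'
#' @param fit An `ecg_cnn_fit`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_checkpoint()` invisibly returns `path`;
#'   `load_checkpoint()` returns the restored `ecg_cnn_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ecg_cnn_fit"))
  saveRDS(list(format_version = 1L, fit = fit), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) {
    abort("unsupported checkpoint version", class = "ecgmi_error_format")
  }
  obj$fit
}
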