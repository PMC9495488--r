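test_that("layer size arithmetic reproduces the published tower dimensions", {
  expect_equal(layer_output_size(64, 3, 1, 0), 62)
  expect_equal(layer_output_size(60, 4, 2, 0), 29)
  expect_equal(layer_output_size(25, 3, 2, 0), 12)
  expect_equal(layer_output_size(8, 4, 2, 0), 3)
  expect_error(layer_output_size(2, 5), class = "ecgmi_error_config")
  shp <- architecture_shapes(ecg_cnn_architecture())
  expect_equal(shp$out_px, c(62, 60, 29, 27, 25, 12, 10, 8, 3))
  expect_equal(attr(shp, "flat_per_lead"), 288)
  expect_equal(attr(shp, "concat_features"), 3456)
})

test_that("parameter count is a pure function of the architecture", {
  n_params <- function(arch) {
    ecgmi:::model_n_params(build_ecg_cnn(arch, rng_seed = 1))
  }
  a <- tiny_arch()
  expect_equal(n_params(a), n_params(a))
  # closed-form oracle: conv (9*cin + 3)*cout per lead (W + b + BN gamma/beta),
  # dense in*out + 3*out (or +out without BN)
  cc <- c(2, 2, 4, 4, 4, 4); du <- c(32, 16); k <- 2
  conv_p <- function(cin, cout) (9 * cin + 1) * cout + 2 * cout
  expected <- 12 * (conv_p(1, cc[1]) + conv_p(cc[1], cc[2]) +
                    conv_p(cc[2], cc[3]) + conv_p(cc[3], cc[4]) +
                    conv_p(cc[4], cc[5]) + conv_p(cc[5], cc[6]))
  flat <- 12 * 9 * cc[6]
  expected <- expected + (flat * du[1] + 3 * du[1]) +
    (du[1] * du[2] + 3 * du[2]) + (du[2] * k + k)
  expect_equal(n_params(a), expected)
  # the 11-class full-width model matches its own closed form
  full <- ecg_cnn_architecture()
  cc <- c(4, 8, 16, 16, 32, 32)
  conv_tot <- 12 * sum(mapply(conv_p, c(1, cc[-6]), cc))
  head_tot <- 3456 * 2048 + 3 * 2048 + 2048 * 1024 + 3 * 1024 +
    1024 * 11 + 11
  expect_equal(n_params(full), conv_tot + head_tot)
})

test_that("layer gradients agree with numeric differentiation", {
  ns <- asNamespace("ecgmi")
  set.seed(2)
  conv <- ns$new_gconv_layer(2, 3, groups = 2, shared = FALSE)
  x <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  set.seed(9)
  wgt <- array(rnorm(6 * 6 * 3 * 6), c(6, 6, 3, 6))
  loss <- function() sum(ns$layer_forward(conv, x, TRUE)$out * wgt)
  fwd <- ns$layer_forward(conv, x, TRUE)
  bk <- ns$layer_backward(conv, fwd$cache, wgt)
  numgrad <- function(set, get, eps = 1e-6) {
    v <- get()
    set(v + eps); lp <- loss()
    set(v - eps); lm <- loss()
    set(v)
    (lp - lm) / (2 * eps)
  }
  for (idx in list(c(1, 1), c(4, 5), c(9, 6))) {
    ana <- bk$grads$W[idx[1], idx[2]]
    num <- numgrad(function(v) conv$W[idx[1], idx[2]] <<- v,
                   function() conv$W[idx[1], idx[2]])
    expect_equal(ana, num, tolerance = 1e-5)
  }
  for (j in c(2, 6)) {
    num <- numgrad(function(v) {
      bn <- conv$bn; bn$gamma[j] <- v; conv$bn <<- bn
    }, function() conv$bn$gamma[j])
    expect_equal(bk$grads$gamma[j], num, tolerance = 1e-5)
    num <- numgrad(function(v) {
      bn <- conv$bn; bn$beta[j] <- v; conv$bn <<- bn
    }, function() conv$bn$beta[j])
    expect_equal(bk$grads$beta[j], num, tolerance = 1e-5)
  }
  # input gradient via a full-tensor probe
  dx_num <- numgrad(function(v) x[3, 3, 2, 2] <<- v, function() x[3, 3, 2, 2])
  expect_equal(bk$dx[3, 3, 2, 2], dx_num, tolerance = 1e-5)
})

test_that("model outputs are normalized probabilities with correct shapes", {
  arch <- tiny_arch(3)
  model <- build_ecg_cnn(arch, rng_seed = 4)
  set.seed(6)
  x <- array(runif(64 * 64 * 5 * 12), c(64, 64, 5, 12))
  fwd <- ecgmi:::cnn_forward(model, x, training = FALSE)
  expect_equal(dim(fwd$logits), c(5L, 3L))
  p <- ecgmi:::softmax_rows(fwd$logits)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("training descends, is seed-reproducible, and validates inputs", {
  sets <- toy_blob_sets(n_per_class = 10)
  arch <- tiny_arch(2)
  cfg <- train_config(epochs = 3, batch_size = 10, learning_rate = 3e-3,
                      rng_seed = 5)
  fit1 <- train_ecg_cnn(build_ecg_cnn(arch, 3), sets, cfg)
  expect_equal(nrow(fit1$history), 3)
  expect_lt(fit1$history$loss[3], fit1$history$loss[1])
  fit2 <- train_ecg_cnn(build_ecg_cnn(arch, 3), sets, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_error(train_ecg_cnn(build_ecg_cnn(arch, 3),
                             dplyr::filter(sets, label == "N"), cfg),
               class = "ecgmi_error_validation")
  bad <- sets
  bad$images[[1]] <- array(0L, c(12, 32, 32))
  expect_error(train_ecg_cnn(build_ecg_cnn(arch, 3), bad, cfg),
               class = "ecgmi_error_validation")
})

test_that("separable toy images reach 100% training accuracy in 10 epochs", {
  sets <- toy_blob_sets(n_per_class = 20)
  fit <- train_ecg_cnn(build_ecg_cnn(tiny_arch(2), 3), sets,
                       train_config(epochs = 10, batch_size = 10,
                                    learning_rate = 3e-3, rng_seed = 5))
  p <- predict(fit, sets)
  expect_equal(mean(p$.pred_class == sets$label), 1)
  expect_equal(rowSums(as.matrix(p[, -1])), rep(1, nrow(sets)),
               tolerance = 1e-6)
  # glance/tidy contracts
  g <- glance(fit)
  expect_equal(g$epochs, 10)
  expect_equal(tidy(fit), fit$history)
  # checkpoint round-trip preserves predictions
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_equal(predict(fit2, sets), p)
})

test_that("predictions tolerate horizontal translation of the trace", {
  sets <- toy_blob_sets(n_per_class = 20)
  fit <- train_ecg_cnn(build_ecg_cnn(tiny_arch(2), 3), sets,
                       train_config(epochs = 10, batch_size = 10,
                                    learning_rate = 3e-3, rng_seed = 5))
  shifted <- toy_blob_sets(n_per_class = 20, col_offset = 6)
  p0 <- predict(fit, sets)
  p1 <- predict(fit, shifted)
  expect_gte(mean(p0$.pred_class == p1$.pred_class), 0.95)
})

test_that("argmax prediction breaks exact ties toward the lowest class index", {
  sets <- toy_blob_sets(n_per_class = 2)
  fit <- train_ecg_cnn(build_ecg_cnn(tiny_arch(2), 3), sets,
                       train_config(epochs = 1, batch_size = 4, rng_seed = 1))
  # zero the output layer: logits all equal, every probability tied at 0.5
  out_layer <- fit$model$head[[3]]
  out_layer$W[] <- 0
  out_layer$b[] <- 0
  p <- predict(fit, sets)
  expect_true(all(abs(as.matrix(p[, -1]) - 0.5) < 1e-12))
  expect_true(all(p$.pred_class == fit$class_levels[1]))
})
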