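# Network construction, forward tracing, gradients, and training.

test_that("shape chaining follows valid-padding arithmetic and is validated", {
  net <- net_build(list(conv_layer(3L, 2L), relu_layer()),
                   input_shape = c(25L, 25L, 1L), seed = 1)
  expect_equal(net$layers[[1L]]$out_dims, c(23L, 23L, 2L))
  expect_equal(net$layers[[2L]]$dout, 23 * 23 * 2)

  # same padding preserves the spatial size
  net2 <- net_build(list(conv_layer(3L, 2L, padding = "same")),
                    input_shape = c(25L, 25L, 1L), seed = 1)
  expect_equal(net2$layers[[1L]]$out_dims, c(25L, 25L, 2L))

  # declared dense input dimension must match the flattened chain
  expect_error(
    net_build(list(conv_layer(3L, 2L), relu_layer(), flatten_layer(),
                   dense_layer(4L, in_dim = 10L)),
              input_shape = c(25L, 25L, 1L), seed = 1),
    "shape chain mismatch.*in_dim 10"
  )
  expect_error(
    net_build(list(flatten_layer(), conv_layer(3L, 2L)),
              input_shape = c(8L, 8L, 1L), seed = 1),
    "spatial layer after flatten"
  )
})

test_that("building with the same seed is bit-identical", {
  a <- net_build(default_architecture(), c(25L, 25L, 1L), seed = 42)
  b <- net_build(default_architecture(), c(25L, 25L, 1L), seed = 42)
  expect_identical(a$params, b$params)
  c <- net_build(default_architecture(), c(25L, 25L, 1L), seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("forward pass realizes the layer definitions and records switches", {
  # rectifier on (-1, 0, 2)
  net <- net_build(list(relu_layer()), c(1L, 3L, 1L), seed = 1)
  tr <- net_forward(net, c(-1, 0, 2))
  expect_equal(tr$output, c(0, 0, 2))
  expect_equal(tr$layers[[1L]]$mask, c(0, 0, 1))

  # max pooling keeps the window maximum and records its argmax
  netp <- net_build(list(maxpool_layer(2L)), c(2L, 2L, 1L), seed = 1)
  x <- matrix(c(1, 3, 2, 4), 2, 2)   # column-major: x[2,2] = 4
  trp <- net_forward(netp, x)
  expect_equal(trp$output, 4)
  expect_equal(trp$layers[[1L]]$arg, 4L)  # last window element (2,2)

  # all-ones 2x2 kernel, zero bias, on an image of ones: sum = 4
  netc <- net_build(list(conv_layer(2L, 1L), relu_layer()), c(2L, 2L, 1L), seed = 1)
  netc$params[[1L]]$W[] <- 1
  netc$params[[1L]]$b[] <- 0
  expect_equal(net_forward(netc, matrix(1, 2, 2))$output, 4)

  # input shape is enforced
  expect_error(net_forward(net, c(1, 2)), "expects")
})

test_that("forward pass is deterministic and the trace is self-consistent", {
  net <- micro_net(11)
  img <- rand_image(12)
  t1 <- net_forward(net, img)
  t2 <- net_forward(net, img)
  expect_identical(t1$output, t2$output)
  expect_identical(t1$layers, t2$layers)
  for (i in seq_along(net$layers)) {
    ent <- t1$layers[[i]]
    if (ent$kind == "relu") expect_identical(ent$mask, as.numeric(ent$x > 0))
    if (ent$kind == "maxpool") {
      ix <- net$layers[[i]]$ix
      Z <- matrix(ent$x[ix$idx], ix$P, ix$W2)
      expect_equal(Z[cbind(seq_len(ix$P), ent$arg)], ent$y)
    }
  }
})

test_that("input gradients match chain-rule hand cases and finite differences", {
  # y = 3 * relu(2x): gradient 6 at x = 1, 0 at x = -1
  net <- net_build(list(dense_layer(1L), relu_layer(), dense_layer(1L)),
                   c(1L, 1L, 1L), seed = 1)
  net <- set_dense(net, 1L, 2)
  net <- set_dense(net, 3L, 3)
  tr <- net_forward(net, 1)
  expect_equal(as.numeric(net_input_gradient(net, tr, 1L)), 6)
  trm <- net_forward(net, -1)
  expect_equal(as.numeric(net_input_gradient(net, trm, 1L)), 0)
  expect_error(net_input_gradient(net, tr, 5L), "out of range")

  # finite-difference oracle over every layer kind (valid + same conv,
  # relu, maxpool, flatten, dense, softmax), both output conventions
  net2 <- net_build(list(conv_layer(3L, 2L, padding = "same"), relu_layer(),
                         maxpool_layer(2L), conv_layer(2L, 3L), relu_layer(),
                         flatten_layer(), dense_layer(5L), relu_layer(),
                         dense_layer(3L), softmax_layer()),
                    c(6L, 6L, 1L), seed = 5, init_scale = 2)
  img <- rand_image(6, c(6L, 6L))
  tr2 <- net_forward(net2, img)
  for (from in c("output", "logit")) {
    tgt <- 2L
    g <- as.numeric(net_input_gradient(net2, tr2, tgt, from = from))
    f <- function(x) {
      t <- net_forward(net2, matrix(x, 6, 6))
      if (from == "output") t$output[tgt]
      else t$layers[[9L]]$y[tgt]
    }
    fd <- fd_gradient(f, as.numeric(img))
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("supervised SGD learns a separable patch task reproducibly", {
  # bright vs dark 25x25 blocks, seed 0
  gen <- function(seed) {
    withr::with_seed(seed, {
      n <- 60L
      x <- rbind(matrix(stats::runif(n / 2 * 625, 0.7, 1), n / 2),
                 matrix(stats::runif(n / 2 * 625, 0, 0.3), n / 2))
      list(x = x, y = rep(c(1L, 0L), each = n / 2))
    })
  }
  d <- gen(0)
  ctrl <- train_control(learning_rate = 0.3, batch_size = 4L, epochs = 5L,
                        seed = 0)
  fit <- fbcnn_fit(d$x, d$y, input_shape = c(25L, 25L, 1L), control = ctrl)
  expect_gte(mean(predict(fit, d$x) == d$y), 0.95)
  expect_lt(fit$loss[length(fit$loss)], fit$loss[1L])

  # seeded runs are identical
  fit2 <- fbcnn_fit(d$x, d$y, input_shape = c(25L, 25L, 1L), control = ctrl)
  expect_identical(fit$net$params, fit2$net$params)
  expect_identical(fit$loss, fit2$loss)
})

test_that("zero learning rate leaves parameters untouched", {
  net <- micro_net(3)
  x <- matrix(runif(10 * 16), 10)
  y <- rep(c(0L, 1L), 5)
  tr <- net_train(net, x, y, train_control(learning_rate = 0, epochs = 3L, seed = 1))
  expect_identical(tr$net$params, net$params)
})

test_that("single-sample SGD descends monotonically", {
  net <- micro_net(4)
  x <- matrix(runif(16), 1)
  tr <- net_train(net, x, 2L,
                  train_control(learning_rate = 0.05, epochs = 25L,
                                batch_size = 1L, seed = 1))
  expect_true(all(diff(tr$loss) <= 1e-12))
})

test_that("training rejects empty and degenerate inputs", {
  net <- micro_net(5)
  expect_error(net_train(net, matrix(numeric(0), 0, 16), integer(0),
                         train_control(seed = 1)), "empty")
  expect_error(net_train(net, matrix(runif(16), 1), 7L,
                         train_control(seed = 1)), "labels")
  nohead <- net_build(list(flatten_layer(), dense_layer(2L)), c(4L, 4L, 1L), seed = 1)
  expect_error(net_train(nohead, matrix(runif(16), 1), 1L,
                         train_control(seed = 1)), "softmax head")
})

test_that("layer-wise denoising pretraining descends and is reproducible", {
  net <- net_build(list(flatten_layer(), dense_layer(8L), relu_layer(),
                        dense_layer(2L), softmax_layer()),
                   c(2L, 4L, 1L), seed = 9)
  x <- withr::with_seed(1, matrix(stats::runif(200 * 8), 200))
  p1 <- net_pretrain(net, x, noise_sigma = 0,
                     control = train_control(learning_rate = 0.2, epochs = 6L, seed = 2))
  hist <- attr(p1, "pretrain_loss")[["layer2"]]
  expect_lt(hist[length(hist)], hist[1L])                 # descent, noiseless
  expect_false(identical(p1$params[[2L]], net$params[[2L]]))  # training occurred
  expect_identical(p1$params[[4L]], net$params[[4L]])     # head untouched
  p2 <- net_pretrain(net, x, noise_sigma = 0,
                     control = train_control(learning_rate = 0.2, epochs = 6L, seed = 2))
  expect_identical(p1$params, p2$params)                  # determinism
  expect_error(net_pretrain(net, x, noise_sigma = -1,
                            control = train_control(seed = 1)), "noise_sigma")
})

test_that("model serialization round-trips bit-exactly", {
  net <- micro_net(8)
  path <- withr::local_tempfile(fileext = ".rds")
  net_save(net, path)
  expect_identical(net_load(path), net)
})
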