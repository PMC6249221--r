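test_that("the selected architecture matches the published layer table", {
  m <- build_cnne(cnn_config(Ns = 3, Nd = 1, Lr = 0.005, Mo = 0.9, Re = 0.15))
  types <- vapply(m$layers, `[[`, character(1), "type")
  expect_identical(types,
                   c("conv", "relu", "maxpool",
                     "conv", "relu", "maxpool",
                     "conv", "relu", "maxpool",
                     "flatten", "fc", "relu", "dropout", "fc", "softmax"))
  convs <- Filter(function(l) l$type == "conv", m$layers)
  expect_identical(vapply(convs, `[[`, integer(1), "n_filters"),
                   c(10L, 20L, 40L))
  for (l in convs) {
    expect_identical(l$kernel, 101L)
    expect_identical(l$stride, 1L)
    expect_identical(l$pad, 50L)
  }
  pools <- Filter(function(l) l$type == "maxpool", m$layers)
  for (l in pools) {
    expect_identical(l$kernel, 11L)
    expect_identical(l$stride, 2L)
  }
  fcs <- Filter(function(l) l$type == "fc", m$layers)
  expect_identical(vapply(fcs, `[[`, integer(1), "n_out"), c(100L, 2L))
})

test_that("the shape trace follows the conv/pool arithmetic", {
  tr <- forward_shapes(cnn_config(Ns = 3, Nd = 1))
  expect_identical(tr$length[tr$type == "conv"], c(2000L, 995L, 493L))
  expect_identical(tr$length[tr$type == "maxpool"], c(995L, 493L, 242L))
  expect_identical(attr(tr, "fc_input_width"), 9680L)

  tr1 <- forward_shapes(cnn_config(Ns = 1, Nd = 1))
  expect_identical(tr1$length, c(2000L, 2000L, 995L))
  expect_identical(attr(tr1, "fc_input_width"), 9950L)

  # a config whose temporal extent collapses is rejected
  expect_error(cnn_config(Ns = 5, Nd = 1, input_len = 64), "configuration")
})

test_that("parameter count grows strictly with depth and sections", {
  base <- cnn_n_params(cnn_config(Ns = 2, Nd = 1, input_len = 500))
  expect_gt(cnn_n_params(cnn_config(Ns = 2, Nd = 2, input_len = 500)), base)
  expect_gt(cnn_n_params(cnn_config(Ns = 3, Nd = 1, input_len = 500)), base)
})

test_that("training learns a separable synthetic problem and is seeded", {
  net <- tiny_trained_net()
  expect_gte(net$train_log$acc[nrow(net$train_log)], 0.95)

  # bit-identical rerun under the same seed
  cfg <- net$config
  net2 <- train_cnne(build_cnne(cfg, init_seed = 3), tone_stacks(),
                     epochs = 6, seed = 3)
  expect_identical(net$train_log$loss, net2$train_log$loss)

  # held-out stacks (fresh seeds) are classified correctly
  held <- c(lapply(1:10, function(i) make_tone_stack(1L, "h", 9000 + i)),
            lapply(1:10, function(i) make_tone_stack(0L, "h", 9100 + i)))
  pred <- predict_fcnn(net, held)
  expect_gte(mean(pred$label == rep(c(1L, 0L), each = 10)), 0.9)
  expect_true(all(pred$label %in% c(0L, 1L)))
  expect_equal(pred$p_nsh + pred$p_sh, rep(1, 20), tolerance = 1e-6)
})

test_that("zero learning rate leaves the weights untouched", {
  cfg <- cnn_config(Ns = 1, Nd = 1, Lr = 0, Mo = 0.9, Re = 0.15,
                    input_len = 500)
  net0 <- build_cnne(cfg, init_seed = 5)
  net1 <- train_cnne(net0, tone_stacks()[c(1:4, 25:28)], epochs = 2, seed = 5)
  for (i in seq_along(net0$layers)) {
    if (!is.null(net0$layers[[i]]$W))
      expect_identical(net1$layers[[i]]$W, net0$layers[[i]]$W)
  }
})

test_that("feature extraction is the first-FC activation, deterministic, length 100", {
  net <- tiny_trained_net()
  st <- tone_stacks()[[1]]
  f1 <- extract_features(net, st)
  f2 <- extract_features(net, st)
  expect_length(f1, 100L)
  expect_identical(f1, f2)  # dropout is inference-off

  # all-zero input through an untrained net (all biases zero upstream)
  # isolates the first-FC bias path through the ReLU
  zero <- channel_stack(numeric(500), numeric(500), numeric(500), 0L, "z")
  fresh <- build_cnne(net$config, init_seed = 11)
  fc1 <- which(vapply(fresh$layers, `[[`, character(1), "type") == "fc")[1]
  fresh$layers[[fc1]]$b <- seq(-0.5, 0.49, length.out = 100)
  expect_equal(extract_features(fresh, zero),
               pmax(fresh$layers[[fc1]]$b, 0), tolerance = 1e-12)
})

test_that("training rejects degenerate data and aborts on non-finite loss", {
  cfg <- cnn_config(Ns = 1, Nd = 1, input_len = 500)
  one_class <- tone_stacks()[1:6]
  expect_error(train_cnne(build_cnne(cfg), one_class), "single class")

  blown <- build_cnne(cfg, init_seed = 1)
  blown$layers[[1]]$W[] <- Inf  # Inf * 0 from padding yields NaN activations
  expect_error(train_cnne(blown, tone_stacks()[c(1:4, 25:28)], epochs = 1,
                          seed = 1),
               "loss")
})

test_that("stack length must match the configured input length", {
  net <- tiny_trained_net()
  long <- channel_stack(numeric(600), numeric(600), numeric(600), 0L, "x")
  expect_error(train_cnne(build_cnne(net$config), list(long, long)),
               "single class|length")
  expect_error(
    train_cnne(build_cnne(net$config),
               list(long, channel_stack(numeric(600), numeric(600),
                                        numeric(600), 1L, "y"))),
    "input_len")
})
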