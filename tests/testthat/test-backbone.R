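test_that("residual block with zeroed weights reproduces its input exactly", {
  blk <- nn_residual_block(16, 16, residual = TRUE)
  zero_params(blk$children$conv1)
  zero_params(blk$children$conv2)
  x <- array(rnorm(2 * 8 * 8 * 16), c(2, 8, 8, 16))
  expect_identical(module_forward(blk, x, train = TRUE), x)
})

test_that("residual block preserves spatial size and matches a direct oracle", {
  blk <- nn_residual_block(16, 16)
  x <- array(rnorm(1 * 32 * 32 * 16), c(1, 32, 32, 16))
  expect_equal(dim(module_forward(blk, x)), c(1, 32, 32, 16))

  # identity shortcut, hand-set conv weights, pass-through batch norm:
  # output must equal conv(relu(conv(x))) + x computed by the naive oracle
  set.seed(71)
  blk2 <- nn_residual_block(3, 3)
  neutral_bn(blk2)
  w1 <- array(rnorm(3 * 3 * 3 * 3, 0, 0.5), c(3, 3, 3, 3))
  w2 <- array(rnorm(3 * 3 * 3 * 3, 0, 0.5), c(3, 3, 3, 3))
  b1 <- rnorm(3); b2 <- rnorm(3)
  blk2$children$conv1$children$conv$params$w$value <- matrix(w1, ncol = 3)
  blk2$children$conv1$children$conv$params$b$value <- b1
  blk2$children$conv2$children$conv$params$w$value <- matrix(w2, ncol = 3)
  blk2$children$conv2$children$conv$params$b$value <- b2
  x <- array(rnorm(1 * 4 * 4 * 3), c(1, 4, 4, 3))
  h <- naive_conv(x, w1, b1); h <- h * (h > 0)
  h2 <- naive_conv(h, w2, b2); h2 <- h2 * (h2 > 0)
  expect_equal(module_forward(blk2, x), h2 + x, tolerance = 1e-4)

  expect_error(nn_residual_block(8, 0), "positive")
})

test_that("encoder produces the documented feature pyramid and rejects bad sizes", {
  cfg <- model_config(use_sfem = FALSE, use_mcem = FALSE, use_ag = FALSE)
  model <- build_model(cfg)
  st <- encoder_forward(model, array(runif(256 * 256), c(1, 256, 256, 1)))
  expect_equal(lapply(st$stages, dim),
               list(c(1, 256, 256, 16), c(1, 128, 128, 32),
                    c(1, 64, 64, 64), c(1, 32, 32, 128)))
  expect_equal(dim(st$bottleneck), c(1, 16, 16, 256))

  st64 <- encoder_forward(model, array(runif(64 * 64), c(1, 64, 64, 1)))
  expect_equal(dim(st64$bottleneck), c(1, 4, 4, 256))

  expect_error(encoder_forward(model, array(runif(250 * 250), c(1, 250, 250, 1))),
               "250")
})

test_that("end-to-end output is a probability map of the input size", {
  for (cfg in list(model_config(use_residual = FALSE, use_sfem = FALSE,
                                use_mcem = FALSE, use_ag = FALSE),
                   model_config(base_width = 4))) {
    model <- build_model(cfg)
    p <- model_predict(model, matrix(runif(64 * 64), 64))
    expect_equal(dim(p), c(1, 64, 64, 1))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("decoder accepts explicit skips and bypasses gating when disabled", {
  cfg <- model_config(use_sfem = FALSE, use_mcem = FALSE, use_ag = FALSE)
  model <- build_model(cfg)
  expect_false(any(grepl("^gate", names(model$modules$children))))
  img <- array(runif(64 * 64), c(1, 64, 64, 1))
  st <- encoder_forward(model, img)
  out <- decoder_forward(model, st, st$stages)
  # without gates, SFEM or MCEM the decoder on raw encoder skips is the whole
  # model
  expect_equal(out, model_predict(model, img))

  bad <- st$stages
  bad[[1]] <- bad[[1]][, 1:32, 1:32, , drop = FALSE]
  expect_error(decoder_forward(model, st, bad), "match")
})

test_that("build_model wires the configured number of submodules", {
  full <- build_model(model_config())
  nms <- names(full$modules$children)
  expect_length(grep("^sfem", nms), 4)
  expect_true("mcem" %in% nms)
  expect_length(grep("^gate", nms), 4)
  expect_length(grep("^enc", nms), 4)

  plain <- build_model(model_config(use_residual = FALSE, use_sfem = FALSE,
                                    use_mcem = FALSE, use_ag = FALSE))
  expect_length(grep("sfem|mcem|gate", names(plain$modules$children)), 0)
  expect_null(plain$modules$children$enc1$children$shortcut)
})

test_that("parameter counts match a first-principles per-layer tally", {
  conv <- nn_conv2d(1, 16, k = 3)
  expect_equal(count_parameters(conv), 3 * 3 * 1 * 16 + 16)

  cfgs <- list(
    plain = model_config(use_residual = FALSE, use_sfem = FALSE,
                         use_mcem = FALSE, use_ag = FALSE),
    resu = model_config(use_sfem = FALSE, use_mcem = FALSE, use_ag = FALSE),
    full = model_config(),
    deep = model_config(base_width = 8, depth = 3)
  )
  for (cfg in cfgs) {
    expect_equal(count_parameters(build_model(cfg)), tally_model(cfg))
  }
})

test_that("parameter count grows strictly as modules are enabled", {
  base <- count_parameters(build_model(
    model_config(use_residual = FALSE, use_sfem = FALSE, use_mcem = FALSE,
                 use_ag = FALSE)))
  singles <- vapply(c("use_residual", "use_sfem", "use_mcem", "use_ag"),
                    function(flag) {
    args <- list(use_residual = FALSE, use_sfem = FALSE, use_mcem = FALSE,
                 use_ag = FALSE)
    args[[flag]] <- TRUE
    count_parameters(build_model(do.call(model_config, args)))
  }, 1)
  expect_true(all(singles > base))
  full <- count_parameters(build_model(model_config()))
  expect_true(all(full > singles))
})

test_that("builds and forward passes are deterministic under a fixed seed", {
  cfg <- model_config(base_width = 4, depth = 2, seed = 99)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  p1 <- maresnet:::collect_params(m1$modules)
  p2 <- maresnet:::collect_params(m2$modules)
  expect_identical(lapply(p1, function(p) p$value),
                   lapply(p2, function(p) p$value))
  img <- matrix(runif(32 * 32), 32)
  expect_identical(model_predict(m1, img), model_predict(m2, img))

  m3 <- build_model(model_config(base_width = 4, depth = 2, seed = 100))
  expect_false(identical(p1[[1]]$value,
                         maresnet:::collect_params(m3$modules)[[1]]$value))
})

test_that("variant names follow the ablation-table convention", {
  expect_equal(variant_name(model_config(use_residual = FALSE, use_sfem = FALSE,
                                         use_mcem = FALSE, use_ag = FALSE)),
               "U-Net")
  expect_equal(variant_name(model_config()), "ResU + AG + SFEM + MCEM")
  expect_equal(variant_name(model_config(use_sfem = FALSE, use_mcem = FALSE)),
               "ResU + AG")
})
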