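# Shared small-scale fixture: a compact residual model overfit on eight easy
# synthetic images.  Built once and reused across the training tests.
overfit_env <- new.env()

overfit_fixture <- function() {
  if (!is.null(overfit_env$fit)) return(overfit_env)
  p <- synth_params(size = 64, n_lesions = c(1, 2), radius = c(8, 16),
                    preset = "easy")
  overfit_env$samples <- generate_samples(8, p, seed = 401)
  cfg <- train_config(model = model_config(base_width = 16, depth = 3,
                                           use_sfem = FALSE, use_mcem = FALSE,
                                           use_ag = FALSE, seed = 5),
                      epochs = 50, batch_size = 4, lr = 1e-3, seed = 19)
  overfit_env$config <- cfg
  overfit_env$fit <- train_model(cfg, overfit_env$samples, verbose = FALSE)
  overfit_env
}

test_that("a small model overfits eight images to near-zero Dice loss", {
  env <- overfit_fixture()
  log <- env$fit$log
  expect_equal(nrow(log), 50)
  expect_lt(log$train_loss[50], 0.1)

  # smoothed loss curve is non-increasing on the overfit fixture
  smooth <- stats::filter(log$train_loss, rep(1 / 5, 5), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) < 0.02))

  # predictions on a training image recover its mask
  s <- env$samples[[1]]
  pr <- predict_mask(env$fit$model, s$image)
  expect_gt(iou(confusion_counts(pr$mask, s$mask)), 0.9)
})

test_that("training is deterministic and a zero learning rate freezes the loss", {
  p <- synth_params(size = 32, preset = "easy")
  samples <- generate_samples(4, p, seed = 77)
  cfg <- function(lr, epochs, batch = 2) {
    train_config(model = model_config(base_width = 4, depth = 2, seed = 3),
                 epochs = epochs, batch_size = batch, lr = lr, seed = 8)
  }
  f1 <- train_model(cfg(1e-3, 1), samples, verbose = FALSE)
  f2 <- train_model(cfg(1e-3, 1), samples, verbose = FALSE)
  expect_identical(f1$log$train_loss, f2$log$train_loss)

  # single whole-set batch so the frozen-parameter loss is order-free
  f0 <- train_model(cfg(0, 3, batch = 4), samples, verbose = FALSE)
  expect_equal(f0$log$train_loss[1], f0$log$train_loss[2])
  expect_equal(f0$log$train_loss[2], f0$log$train_loss[3])
})

test_that("checkpoints round-trip bit-identically", {
  env <- overfit_fixture()
  s <- env$samples[[2]]
  before <- predict_mask(env$fit$model, s$image)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(env$fit$best, path)
  restored <- model_from_checkpoint(path)
  after <- predict_mask(restored, s$image)
  direct <- predict_mask(model_from_checkpoint(env$fit$best), s$image)
  expect_identical(after$prob, direct$prob)
  expect_identical(dim(before$prob), dim(after$prob))
  unlink(path)
})

test_that("prediction pads non-divisible inputs and crops back", {
  env <- overfit_fixture()
  img <- env$samples[[1]]$image[1:50, 1:47]
  pr <- predict_mask(env$fit$model, img)
  expect_equal(dim(pr$prob), c(50, 47))
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))

  # an all-background image yields a near-empty mask
  bg <- generate_sample(synth_params(size = 64, n_lesions = c(0, 0),
                                     preset = "easy"), 9)
  prbg <- predict_mask(env$fit$model, bg$image)
  expect_lt(mean(prbg$mask), 0.05)
})

test_that("training rejects empty data and records one row per epoch", {
  cfg <- train_config(model = model_config(base_width = 4, depth = 2))
  expect_error(train_model(cfg, list()), "empty")
  env <- overfit_fixture()
  expect_equal(env$fit$log$epoch, 1:50)
  expect_true(all(is.finite(env$fit$log$train_loss)))
})

test_that("the ablation harness trains variants and tabulates their metrics", {
  p <- synth_params(size = 32, preset = "easy")
  train <- generate_samples(4, p, seed = 51)
  test <- generate_samples(2, p, seed = 52)
  mk <- function(...) {
    train_config(model = model_config(base_width = 4, depth = 2, ...),
                 epochs = 1, batch_size = 2, lr = 1e-3, seed = 4)
  }
  tab <- run_ablation(list(mk(use_residual = FALSE, use_sfem = FALSE,
                              use_mcem = FALSE, use_ag = FALSE),
                           mk()),
                      train, val_samples = NULL, test_samples = test)
  expect_equal(dim(tab), c(2L, 5L))
  expect_equal(tab$variant, c("U-Net", "ResU + AG + SFEM + MCEM"))
  expect_true(all(c("precision", "recall", "iou", "f1") %in% names(tab)))
  expect_true(all(tab[, -1] >= 0 & tab[, -1] <= 100))
})
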