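write_pair_dirs <- function(n = 3, size = 16) {
  root <- tempfile("pairs")
  dir.create(file.path(root, "images"), recursive = TRUE)
  dir.create(file.path(root, "masks"), recursive = TRUE)
  for (i in seq_len(n)) {
    img <- matrix(runif(size * size), size)
    msk <- matrix(sample(c(0, 1), size * size, TRUE), size)
    png::writePNG(img, file.path(root, "images", sprintf("s%02d.png", i)))
    png::writePNG(msk, file.path(root, "masks", sprintf("s%02d.png", i)))
  }
  root
}

test_that("paired loading matches files, binarises masks and checks shapes", {
  root <- write_pair_dirs(3)
  samples <- load_pairs(file.path(root, "images"), file.path(root, "masks"))
  expect_length(samples, 3)
  expect_true(all(vapply(samples, function(s) all(s$mask %in% c(0, 1)), TRUE)))
  expect_equal(samples[[1]]$source_id, "s01")

  # a mid-gray mask file binarises at 127/255
  png::writePNG(matrix(c(0, 100 / 255, 200 / 255, 1), 2),
                file.path(root, "masks", "s01.png"))
  png::writePNG(matrix(0.5, 2, 2), file.path(root, "images", "s01.png"))
  s1 <- load_pairs(file.path(root, "images"), file.path(root, "masks"))[[1]]
  expect_equal(as.vector(s1$mask), c(0, 0, 1, 1))

  png::writePNG(matrix(0.2, 4, 4), file.path(root, "images", "orphan.png"))
  expect_error(load_pairs(file.path(root, "images"), file.path(root, "masks")),
               "orphan")
  file.remove(file.path(root, "images", "orphan.png"))

  png::writePNG(matrix(1, 8, 8), file.path(root, "masks", "s02.png"))
  expect_error(load_pairs(file.path(root, "images"), file.path(root, "masks")),
               "s02")
})

test_that("splits are seeded, exhaustive, disjoint and floor-sized", {
  ids <- sprintf("img%04d", 1:1535)
  # the documented floor rule, recomputed here from first principles
  ratios <- c(922, 307, 306) / 1535
  sp <- split_dataset(ids, ratios, seed = 3)
  expect_length(sp$validation, floor(1535 * ratios[2]))
  expect_length(sp$test, floor(1535 * ratios[3]))
  expect_length(sp$train, 1535 - length(sp$validation) - length(sp$test))
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 922, validation = 307, test = 306))
  expect_setequal(c(sp$train, sp$validation, sp$test), ids)

  expect_identical(split_dataset(ids, ratios, seed = 3), sp)
  expect_false(identical(split_dataset(ids, ratios, seed = 4), sp))

  all_train <- split_dataset(ids, c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 1535)

  expect_error(split_dataset(ids[1:2], c(0.6, 0.2, 0.2), 1), "at least 3")
  expect_error(split_dataset(ids, c(0.5, 0.2, 0.2), 1), "summing to 1")
})

test_that("a zero-range recipe duplicates samples exactly", {
  s <- generate_sample(synth_params(size = 32), 8)
  spec <- augmentation_spec(flip_p = 0, rotation = 0, scale = c(1, 1),
                            translation = 0, elastic_magnitude = 0, copies = 2)
  copies <- augment(s, spec, seed = 2)
  expect_length(copies, 2)
  for (cp in copies) {
    expect_equal(cp$image, s$image)
    expect_equal(cp$mask, s$mask)
  }
})

test_that("augmentation multiplies the dataset and keeps masks binary", {
  samples <- generate_samples(5, synth_params(size = 32), seed = 6)
  spec <- augmentation_spec(copies = 2)
  aug <- augment_dataset(samples, spec, seed = 13)
  expect_length(aug, 15)  # originals retained plus two copies each
  expect_true(all(vapply(aug, function(s) all(s$mask %in% c(0, 1)), TRUE)))
  expect_true(all(vapply(aug, function(s) identical(dim(s$image), c(32L, 32L)),
                         TRUE)))

  expect_identical(augment_dataset(samples, spec, seed = 13), aug)
  expect_false(identical(augment_dataset(samples, spec, seed = 14)[[2]]$image,
                         aug[[2]]$image))
})

test_that("pure integer translation shifts the mask rigidly", {
  s <- generate_sample(synth_params(size = 48, n_lesions = c(1, 1),
                                    radius = c(8, 8)), 21)
  for (shift in list(c(3, 5), c(-4, 2), c(0, -6))) {
    out <- maresnet:::transform_pair(s$image, s$mask, flip = FALSE, angle = 0,
                                     scale = 1, dx = shift[1], dy = shift[2])
    expected <- matrix(0, 48, 48)
    src_r <- seq_len(48) - shift[2]
    src_c <- seq_len(48) - shift[1]
    ok_r <- src_r >= 1 & src_r <= 48
    ok_c <- src_c >= 1 & src_c <= 48
    expected[ok_r, ok_c] <- s$mask[src_r[ok_r], src_c[ok_c]]
    expect_identical(out$mask, expected)
  }
})

test_that("augmented copies keep geometric image/mask correspondence", {
  s <- generate_sample(synth_params(size = 64, n_lesions = c(1, 1),
                                    radius = c(10, 14),
                                    preset = "easy"), 33)
  spec <- augmentation_spec(copies = 3)
  for (cp in augment(s, spec, seed = 17)) {
    # lesion pixels must still be darker than their surroundings on average
    expect_gt(mean(cp$image[cp$mask == 0]), mean(cp$image[cp$mask == 1]))
    # lesion area is roughly preserved under the default scale range
    expect_gt(sum(cp$mask), 0.5 * sum(s$mask))
    expect_lt(sum(cp$mask), 1.6 * sum(s$mask))
  }
})
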