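tiny_images <- function(n, side = 8, mean = 100) {
  lapply(seq_len(n), function(i) matrix(mean + i, side, side))
}

test_that("SMOTE reaches the target count with convex synthetic samples", {
  set.seed(61)
  imgs <- lapply(1:14, function(i) matrix(runif(64, 0, 255), 8, 8))
  out <- smote_oversample(imgs, 28, k_neighbors = 5, seed = 9)
  expect_length(out$images, 28L)
  expect_identical(sum(out$provenance == "smote"), 14L)
  expect_identical(out$images[1:14], imgs)     # originals untouched
  # determinism
  out2 <- smote_oversample(imgs, 28, k_neighbors = 5, seed = 9)
  expect_identical(out, out2)
  # every synthetic pixel lies between its parents elementwise: bounded by
  # the global min/max over the originals
  lo <- Reduce(pmin, imgs); hi <- Reduce(pmax, imgs)
  for (m in out$images[15:28]) {
    expect_true(all(m >= lo - 1e-12))
    expect_true(all(m <= hi + 1e-12))
  }
  # target == current returns the input unchanged
  same <- smote_oversample(imgs, 14, seed = 1)
  expect_identical(same$images, imgs)
  expect_true(all(same$provenance == "real"))
  expect_error(smote_oversample(imgs, 10, seed = 1), "below")
  expect_error(smote_oversample(imgs, 28, k_neighbors = 14, seed = 1), "k_neighbors")
  expect_error(smote_oversample(imgs[1], 5, seed = 1), "at least 2")
})

test_that("balancing combines the first per_class of each side", {
  sm <- smote_oversample(tiny_images(14), 28, seed = 2)
  bal <- balance_dataset(sm, tiny_images(62, mean = 200), 28)
  expect_length(bal$images, 56L)
  expect_identical(sum(bal$labels == 0L), 28L)
  expect_identical(sum(bal$labels == 1L), 28L)
  # majority truncation is stable input order
  expect_identical(bal$images[[29]], matrix(201, 8, 8))
  # smote provenance carried through
  expect_identical(sum(bal$provenance == "smote"), 14L)
  expect_error(balance_dataset(sm, tiny_images(10), 28), "insufficient")
})

test_that("augmentation hits the target exactly with valid outputs", {
  set.seed(62)
  base <- labelled_image_set(
    images = lapply(1:10, function(i) matrix(runif(256, 0, 255), 16, 16)),
    labels = rep(c(0L, 1L), each = 5))
  ops <- list(out_size = c(32L, 32L))
  aug <- augment_to_target(base, 64, ops, seed = 5)
  expect_length(aug$images, 64L)
  expect_identical(sum(aug$provenance == "augmented"), 54L)
  expect_true(all(vapply(aug$images, function(m)
    all(dim(m) == c(32L, 32L)), logical(1))))
  rng <- range(unlist(aug$images))
  expect_gte(rng[1], 0); expect_lte(rng[2], 255)
  # class proportions preserved within one item
  expect_lte(abs(sum(aug$labels == 0L) - sum(aug$labels == 1L)), 1L)
  # determinism
  expect_identical(augment_to_target(base, 64, ops, seed = 5)$images,
                   aug$images)
  # target == current size: unchanged apart from the resize
  same <- augment_to_target(base, 10, ops, seed = 5)
  expect_length(same$images, 10L)
  expect_identical(same$provenance, base$provenance)
  expect_error(augment_to_target(base, 5, ops, seed = 1), "below")
})

test_that("stratified split partitions with floor-based sizes", {
  ds <- labelled_image_set(tiny_images(2048, side = 1),
                           labels = rep(c(0L, 1L), each = 1024))
  sp <- split_dataset(ds, 0.8, seed = 3)
  expect_length(sp$train$images, 1638L)   # floor(0.8 * 2048)
  expect_length(sp$val$images, 410L)
  expect_identical(sum(sp$train$labels == 0L), 819L)
  # balanced small case
  ds10 <- labelled_image_set(tiny_images(10), rep(c(0L, 1L), 5))
  sp10 <- split_dataset(ds10, 0.5, seed = 1)
  expect_length(sp10$train$images, 5L)
  expect_lte(abs(sum(sp10$train$labels == 1L) - sum(sp10$train$labels == 0L)), 1L)
  # partition: union is the dataset, intersection empty
  key <- function(m) paste(m, collapse = ",")
  all_keys <- sort(c(sapply(sp10$train$images, key), sapply(sp10$val$images, key)))
  expect_identical(all_keys, sort(sapply(ds10$images, key)))
  expect_error(split_dataset(ds10, 1.2, seed = 1), "0, 1")
  ds_bad <- labelled_image_set(tiny_images(3), c(0L, 1L, 1L))
  expect_error(split_dataset(ds_bad, 0.5, seed = 1), "at least 2")
})

test_that("the count trace of the study pipeline reproduces exactly", {
  # 14/62 -> 28 (SMOTE) -> 56 (balance) -> 200 (augment) -> 160/40 (split),
  # the same arithmetic as the full-scale 2048-image program
  set.seed(63)
  imgs <- lapply(1:76, function(i) matrix(runif(64, 0, 255), 8, 8))
  ds <- labelled_image_set(imgs, c(rep(0L, 14), rep(1L, 62)))
  sm <- smote_oversample(ds$images[ds$labels == 0L], 28, seed = 11)
  expect_length(sm$images, 28L)
  bal <- balance_dataset(sm, ds$images[ds$labels == 1L], 28)
  expect_length(bal$images, 56L)
  aug <- augment_to_target(bal, 200, list(out_size = c(16L, 16L)), seed = 12)
  expect_length(aug$images, 200L)
  sp <- split_dataset(aug, 0.8, seed = 13)
  expect_length(sp$train$images, 160L)
  expect_length(sp$val$images, 40L)
})
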