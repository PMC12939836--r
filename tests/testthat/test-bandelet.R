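test_that("bandeletisation is an orthonormal, invertible block transform", {
  set.seed(31)
  for (shape in list(c(4, 4), c(8, 8), c(2, 8))) {
    blk <- matrix(rnorm(prod(shape), sd = 30), shape[1], shape[2])
    for (s in c(-1.5, 0, 0.75)) {
      co <- bandeletize_block(blk, s)
      expect_length(co, prod(shape))
      expect_equal(sum(co^2), sum(blk^2), tolerance = 1e-9)    # orthonormal
      back <- inverse_bandeletize_block(co, s, shape)
      expect_lt(max(abs(back - blk)), 1e-8)
    }
  }
  # 1x1 block: trivial transform
  expect_equal(bandeletize_block(matrix(3.5, 1, 1), 1), 3.5)
  # zero coefficients invert to the zero block
  expect_equal(inverse_bandeletize_block(numeric(16), 0.5, c(4, 4)),
               matrix(0, 4, 4))
  expect_error(bandeletize_block(matrix(1, 2, 2), NA), "NO_FLOW|raw")
  expect_error(inverse_bandeletize_block(numeric(3), 1, c(2, 2)), "length")
})

test_that("bandeletisation matches the loop-based warped-DWT reference", {
  set.seed(32)
  filt_h <- wavelet_filter("db2")$h
  blk <- matrix(rnorm(64, sd = 25), 8, 8)
  for (s in c(-2, 0.26666667, 1)) {
    expect_equal(bandeletize_block(blk, s),
                 oracle_fdwt(as.vector(blk)[oracle_warp(8, 8, s)], filt_h),
                 tolerance = 1e-10)
  }
})

test_that("blocks constant along the flow become maximally sparse", {
  s <- 1
  blk <- outer(0:7, 0:7, function(x2, x1) 10 * (x2 - s * x1))  # depends on key only
  co <- bandeletize_block(blk, s)
  raw_sig <- sum(abs(blk) > 5)
  band_sig <- sum(abs(co) > 5)
  expect_lt(band_sig, raw_sig)
  # an impulse in the coarsest 1D position spreads a constant-energy atom
  imp <- numeric(64); imp[1] <- 1
  atom <- inverse_bandeletize_block(imp, s, c(8, 8))
  expect_equal(sum(atom^2), 1, tolerance = 1e-10)
})

test_that("block_cost implements the Lagrangian rate-distortion sum", {
  # zero block, NO_FLOW: cost = lambda T^2 (1 + 0)
  expect_equal(block_cost(matrix(0, 4, 4), NA, T = 7, lambda = 1,
                          geometry_bits = 5), 49)
  # all coefficients significant: zero distortion, full rate
  blk <- matrix(100, 4, 4) + matrix(rnorm(16), 4, 4)
  expect_equal(block_cost(blk, NA, T = 30, lambda = 2, geometry_bits = 5),
               2 * 900 * (1 + 16))
  # non-decreasing in lambda
  set.seed(33)
  b2 <- matrix(rnorm(16, sd = 20), 4, 4)
  costs <- sapply(c(0.5, 1, 2, 4), function(l)
    block_cost(b2, 0.5, T = 15, lambda = l, geometry_bits = 4))
  expect_true(all(diff(costs) >= 0))
  expect_error(block_cost(b2, 0, T = -2, lambda = 1, geometry_bits = 4),
               "nonnegative")
  # agreement with the independent arithmetic
  filt_h <- wavelet_filter("db2")$h
  for (s in c(NA, -1, 0.5)) {
    expect_equal(block_cost(b2, s, 15, 1.5, 4),
                 oracle_block_cost(b2, s, 15, 1.5, 4, filt_h),
                 tolerance = 1e-9)
  }
})

test_that("best_quadtree keeps featureless regions whole", {
  # zero detail block: subdivision can only add the lambda T^2 overhead
  tree <- best_quadtree(matrix(0, 8, 8), T = 10, lambda = 1,
                        build_dictionary(4, 2), min_block = 2)
  expect_identical(tree$decision, "DIRECT")
  expect_true(is_no_flow(tree$flow$slope))
  expect_equal(tree$L0, tree$L_direct)
  # a nonzero constant region still stays whole (DC concentration makes a
  # flowed direct encoding cheapest; splitting only multiplies the overhead)
  tree2 <- best_quadtree(matrix(3, 8, 8), T = 10, lambda = 1,
                         build_dictionary(4, 2), min_block = 2)
  expect_identical(tree2$decision, "DIRECT")
})

test_that("best_quadtree matches exhaustive enumeration", {
  set.seed(34)
  d <- build_dictionary(4, 2)
  filt_h <- wavelet_filter("db2")$h
  for (i in 1:6) {
    sub <- if (i <= 3) matrix(rnorm(64, sd = 30), 8, 8)
           else edge_block(8, 8, c(-1, 0.5, 2)[i - 3], 2.7) +
                matrix(rnorm(64, sd = 4), 8, 8)
    for (mb in c(2, 4)) {
      tree <- best_quadtree(sub, T = 20, lambda = 1, d, min_block = mb)
      or <- oracle_quadtree_L0(sub, 0, 0, 8, d$slopes[-1], d$geometry_bits,
                               20, 1, mb, filt_h)
      expect_equal(tree$L0, or, tolerance = 1e-9)
    }
  }
})

test_that("best_quadtree invariants hold on structured input", {
  # an oblique edge confined to one quadrant: the tree splits and flows
  # only where the geometry is
  sub <- matrix(0, 16, 16)
  sub[1:8, 1:8] <- edge_block(8, 8, 1, 3.2)
  d <- build_dictionary(8, 2)
  tree <- best_quadtree(sub, T = 30, lambda = 1, d, min_block = 4)
  expect_identical(tree$decision, "SUBDIVIDE")
  expect_equal(tree$L_tilde,
               30^2 + sum(sapply(tree$children, `[[`, "L0")),
               tolerance = 1e-9)
  expect_lt(tree$L_tilde, tree$L_direct)
  expect_equal(tree$L0, min(tree$L_direct, tree$L_tilde))
  # children tile the parent exactly
  regs <- t(sapply(tree$children, `[[`, "region"))
  expect_setequal(paste(regs[, 1], regs[, 2]), c("0 0", "8 0", "0 8", "8 8"))
  expect_true(all(regs[, 3:4] == 8))
  expect_error(best_quadtree(matrix(0, 8, 12), 10, 1), "square|pad")
})

test_that("enlarging the flow dictionary never increases the optimal cost", {
  set.seed(35)
  small <- build_dictionary(4, 2)
  # a superset: same slopes plus finer intermediate ones
  big <- small
  big$slopes <- c(NA, unique(c(small$slopes[-1], seq(-2, 2, length.out = 16))))
  big$geometry_bits <- small$geometry_bits  # equal bit cost isolates the min
  for (i in 1:4) {
    sub <- edge_block(8, 8, runif(1, -2, 2), 3) + matrix(rnorm(64, 3), 8, 8)
    L_small <- best_quadtree(sub, 25, 1, small, 2)$L0
    L_big <- best_quadtree(sub, 25, 1, big, 2)$L0
    expect_lte(L_big, L_small + 1e-9)
  }
})

test_that("the full bandelet transform is exactly invertible", {
  set.seed(36)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  fit <- bandelet(img, levels = 2, T = 30)
  expect_lt(max(abs(predict(fit) - img)), 1e-8)
  expect_identical(dim(predict(fit)), dim(img))
  # constant image: every tree is a DIRECT NO_FLOW root, zero significance
  fitc <- bandelet(matrix(42, 32, 32), levels = 1, T = 10)
  expect_identical(fitc$significant_count, 0L)
  for (tr in fitc$subband_trees) expect_identical(tr$decision, "DIRECT")
  # total leaf coefficient count equals the detail coefficient count
  # (dyadic shapes: padding is a no-op)
  n_leaf <- sum(unlist(lapply(fit$leaves, function(lf)
    sum(lengths(lf$coeffs)))))
  n_det <- sum(unlist(lapply(fit$pad_shapes, prod)))
  expect_identical(as.integer(n_leaf), as.integer(n_det))
})

test_that("thresholded reconstruction error equals discarded energy", {
  set.seed(37)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  fit <- bandelet(img, levels = 2, T = 30)
  for (T in c(10, 30, 60)) {
    rec <- predict(fit, threshold = T)
    discarded <- sum(unlist(lapply(fit$leaves, function(lf)
      lapply(lf$coeffs, function(v) sum(v[abs(v) <= T]^2)))))
    expect_equal(sum((rec - img)^2), discarded, tolerance = 1e-6 * (1 + discarded))
  }
  expect_error(predict(fit, threshold = -3), "nonnegative")
})

test_that("significant_count is non-increasing in T and cost continuous in lambda", {
  set.seed(38)
  img <- edge_block(32, 32, 0.8, 9) + matrix(rnorm(1024, sd = 6), 32, 32)
  sigs <- sapply(c(5, 15, 30, 60), function(T)
    bandelet(img, levels = 1, T = T,
             dictionary = build_dictionary(4, 2))$significant_count)
  expect_true(all(diff(sigs) <= 0))
  costs <- sapply(c(0.9, 1, 1.1), function(l)
    bandelet(img, levels = 1, T = 30, lambda = l,
             dictionary = build_dictionary(4, 2))$total_cost)
  expect_lt(max(abs(diff(costs))) / costs[2], 0.35)  # no jumps, smooth in lambda
})

test_that("bandelet significance never exceeds the wavelet baseline on edges", {
  set.seed(39)
  img <- edge_block(64, 64, 1.3, 12) + matrix(rnorm(4096, sd = 5), 64, 64)
  tab <- compare_wavelet(img, T_values = c(20, 30),
                         dictionary = build_dictionary(8, 2))
  expect_true(all(tab$bandelet_significant <= tab$wavelet_significant))
})

test_that("bandelet archives round-trip bit-exactly and methods run", {
  set.seed(40)
  img <- matrix(runif(32 * 32, 0, 255), 32, 32)
  fit <- bandelet(img, levels = 1, T = 30,
                  dictionary = build_dictionary(4, 2))
  f <- tempfile(fileext = ".rds")
  write_bandelet(fit, f)
  expect_identical(read_bandelet(f), fit)
  unlink(f)
  expect_output(print(fit), "Bandelet representation")
  expect_output(print(summary(fit)), "best-basis")
  expect_type(coef(fit), "list")
  expect_equal(residuals(fit, img), img - predict(fit))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
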