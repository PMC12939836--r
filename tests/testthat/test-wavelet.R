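test_that("constant images put all energy in the approximation", {
  for (wv in c("haar", "db2", "db4")) {
    sb <- dwt2(matrix(7, 8, 8), wv, 1)
    details <- c(sb$details[[1]]$LH, sb$details[[1]]$HL, sb$details[[1]]$HH)
    expect_lt(max(abs(details)), 1e-10)
    expect_equal(sum(sb$LL^2), sum(rep(7, 64)^2), tolerance = 1e-10)
  }
})

test_that("dwt2/idwt2 is a perfect-reconstruction pair", {
  set.seed(11)
  for (wv in c("haar", "db2", "db4")) for (lv in 1:2) {
    x <- matrix(rnorm(16 * 16), 16, 16)
    expect_lt(max(abs(idwt2(dwt2(x, wv, lv)) - x)), 1e-8)
  }
  # non-square and odd shapes (periodised by sample replication)
  y <- matrix(rnorm(15 * 22), 15, 22)
  expect_lt(max(abs(idwt2(dwt2(y, "db2", 2)) - y)), 1e-8)
})

test_that("orthonormal filters conserve energy under periodic extension", {
  set.seed(12)
  x <- matrix(rnorm(16 * 16), 16, 16)
  for (wv in c("haar", "db2", "db4")) {
    sb <- dwt2(x, wv, 2)
    total <- sum(sb$LL^2) + sum(unlist(lapply(sb$details, function(d)
      sum(d$LH^2) + sum(d$HL^2) + sum(d$HH^2))))
    expect_equal(total, sum(x^2), tolerance = 1e-6)
  }
})

test_that("dwt2 matches the loop-based reference step", {
  set.seed(13)
  x <- matrix(rnorm(8 * 8), 8, 8)
  filt <- wavelet_filter("db2")
  # reference: column step then row step, all in loops
  Ly <- matrix(0, 4, 8); Hy <- matrix(0, 4, 8)
  for (j in 1:8) {
    st <- oracle_dwt_step(x[, j], filt$h)
    Ly[, j] <- st$a; Hy[, j] <- st$d
  }
  LL <- matrix(0, 4, 4); HL <- matrix(0, 4, 4)
  LH <- matrix(0, 4, 4); HH <- matrix(0, 4, 4)
  for (i in 1:4) {
    st <- oracle_dwt_step(Ly[i, ], filt$h); LL[i, ] <- st$a; HL[i, ] <- st$d
    st <- oracle_dwt_step(Hy[i, ], filt$h); LH[i, ] <- st$a; HH[i, ] <- st$d
  }
  sb <- dwt2(x, "db2", 1)
  expect_equal(sb$LL, LL, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$LH, LH, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$HL, HL, tolerance = 1e-12)
  expect_equal(sb$details[[1]]$HH, HH, tolerance = 1e-12)
})

test_that("a coarsest-LL impulse reconstructs the scaling atom", {
  sb <- dwt2(matrix(0, 8, 8), "db2", 1)
  sb$LL[2, 3] <- 1
  rec <- idwt2(sb)
  filt <- wavelet_filter("db2")
  # synthesis oracle: upsample the impulse through the filters directly
  a_col <- matrix(0, 4, 4); a_col[2, 3] <- 1
  mid <- matrix(0, 8, 4)
  for (j in 1:4) mid[, j] <- oracle_idwt_step(a_col[, j], numeric(4), filt$h)
  out <- matrix(0, 8, 8)
  for (i in 1:8) out[i, ] <- oracle_idwt_step(mid[i, ], numeric(4), filt$h)
  expect_equal(rec, out, tolerance = 1e-12)
})

test_that("invalid transform inputs are rejected with diagnostics", {
  expect_error(dwt2(array(1, c(2, 2, 2)), "db2", 1), "2D")
  expect_error(dwt2(matrix(c(1, NA, 3, 4), 2, 2), "haar", 1), "finite")
  expect_error(dwt2(matrix(1, 8, 8), "db2", 9), "levels")
  expect_error(dwt2(matrix(1, 8, 8), "nosuch", 1), "unknown wavelet")
  expect_error(idwt2(list()), "subband_set")
  sb <- dwt2(matrix(rnorm(64), 8, 8), "db2", 1)
  bad <- sb; bad$details[[1]]$LH <- matrix(0, 2, 2)
  expect_error(idwt2(bad), "shape")
})

test_that("hard thresholding follows the strict significance rule", {
  sb <- dwt2(matrix(rnorm(64, sd = 40), 8, 8), "db2", 1)
  # T = 0 keeps every nonzero detail
  th0 <- hard_threshold(sb, 0)
  nz <- sum(unlist(lapply(sb$details, function(d)
    sum(d$LH != 0) + sum(d$HL != 0) + sum(d$HH != 0))))
  expect_identical(attr(th0, "n_significant"), nz)
  expect_equal(th0$details, sb$details)

  # T above max detail kills everything, LL untouched
  big <- max(abs(unlist(lapply(sb$details, unlist))))
  thb <- hard_threshold(sb, big + 1)
  expect_identical(attr(thb, "n_significant"), 0L)
  expect_true(all(unlist(lapply(thb$details, unlist)) == 0))
  expect_equal(thb$LL, sb$LL)

  # the |c| > T rule is strict: {-12, 5, 30, -31} at T = 30 keeps only -31
  sbm <- sb
  sbm$details[[1]]$LH[] <- 0
  sbm$details[[1]]$HL[] <- 0
  sbm$details[[1]]$HH[] <- 0
  sbm$details[[1]]$LH[1:4] <- c(-12, 5, 30, -31)
  thm <- hard_threshold(sbm, 30)
  expect_identical(attr(thm, "n_significant"), 1L)
  expect_equal(sort(thm$details[[1]]$LH[1:4]), c(-31, 0, 0, 0))

  expect_error(hard_threshold(sb, -1), "nonnegative")
})

test_that("thresholding is idempotent", {
  sb <- dwt2(matrix(rnorm(64, sd = 40), 8, 8), "db2", 1)
  once <- hard_threshold(sb, 25)
  twice <- hard_threshold(once, 25)
  expect_equal(unclass(twice), unclass(once))
  expect_identical(attr(twice, "n_significant"), attr(once, "n_significant"))
})

test_that("subband archives round-trip bit-exactly", {
  sb <- dwt2(matrix(rnorm(256), 16, 16), "db4", 2)
  f <- tempfile(fileext = ".rds")
  write_subbands(sb, f)
  expect_identical(read_subbands(f), sb)
  unlink(f)
})
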