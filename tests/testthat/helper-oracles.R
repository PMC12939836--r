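# Independent reference implementations used as oracles. Deliberately
# written in a plain, loop-heavy style, sharing no code with the package
# internals they check.

# one periodic analysis step of an orthonormal filter pair
oracle_dwt_step <- function(x, h) {
  n <- length(x)
  g <- numeric(length(h))
  for (i in seq_along(h)) g[i] <- (-1)^(i - 1) * h[length(h) - i + 1]
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  for (k in 0:(half - 1)) {
    for (m in seq_along(h)) {
      xi <- x[((2 * k + m - 1) %% n) + 1]
      a[k + 1] <- a[k + 1] + h[m] * xi
      d[k + 1] <- d[k + 1] + g[m] * xi
    }
  }
  list(a = a, d = d)
}

oracle_idwt_step <- function(a, d, h) {
  g <- numeric(length(h))
  for (i in seq_along(h)) g[i] <- (-1)^(i - 1) * h[length(h) - i + 1]
  n <- 2 * length(a)
  x <- numeric(n)
  for (k in 0:(length(a) - 1)) {
    for (m in seq_along(h)) {
      pos <- ((2 * k + m - 1) %% n) + 1
      x[pos] <- x[pos] + h[m] * a[k + 1] + g[m] * d[k + 1]
    }
  }
  x
}

# full-depth 1D DWT of a power-of-two-length vector
oracle_fdwt <- function(v, h) {
  len <- length(v)
  while (len >= 2 && len %% 2 == 0) {
    st <- oracle_dwt_step(v[1:len], h)
    v[1:len] <- c(st$a, st$d)
    len <- len / 2
  }
  v
}

# warped ordering by explicit data.frame sort (x1 = column, x2 = row, 0-based)
oracle_warp <- function(h, w, slope) {
  df <- expand.grid(x2 = 0:(h - 1), x1 = 0:(w - 1))
  df$lin <- seq_len(nrow(df))          # column-major linear index
  df$key <- df$x2 - slope * df$x1
  df <- df[order(df$key, df$x1), ]
  df$lin
}

# Lagrangian block cost recomputed from first principles
oracle_block_cost <- function(block, slope, T, lambda, gbits, h_filter) {
  if (is.na(slope)) {
    co <- as.vector(block)
    rg <- 1
  } else {
    co <- oracle_fdwt(as.vector(block)[oracle_warp(nrow(block), ncol(block), slope)],
                      h_filter)
    rg <- gbits
  }
  keep <- abs(co) > T
  sum(co[!keep]^2) + lambda * T^2 * (rg + sum(keep))
}

# best flow by exhaustive scan with the documented tie rule
oracle_estimate_flow <- function(block, slopes, gbits, T, lambda, h_filter) {
  best <- list(slope = NA_real_,
               cost = oracle_block_cost(block, NA, T, lambda, gbits, h_filter))
  ord <- order(abs(slopes), slopes)
  for (s in slopes[ord]) {
    cst <- oracle_block_cost(block, s, T, lambda, gbits, h_filter)
    if (cst < best$cost) best <- list(slope = s, cost = cst)
  }
  best
}

# exhaustive quadtree minimisation (no memoisation): the optimal Lagrangian
# cost of a square region is min(direct cost, split overhead + children)
oracle_quadtree_L0 <- function(sub, x1, x2, side, slopes, gbits, T, lambda,
                               min_block, h_filter) {
  block <- sub[x2 + 1:side, x1 + 1:side, drop = FALSE]
  direct <- oracle_estimate_flow(block, slopes, gbits, T, lambda, h_filter)$cost
  if (side / 2 < min_block) return(direct)
  h2 <- side / 2
  split <- lambda * T^2 +
    oracle_quadtree_L0(sub, x1,      x2,      h2, slopes, gbits, T, lambda, min_block, h_filter) +
    oracle_quadtree_L0(sub, x1 + h2, x2,      h2, slopes, gbits, T, lambda, min_block, h_filter) +
    oracle_quadtree_L0(sub, x1,      x2 + h2, h2, slopes, gbits, T, lambda, min_block, h_filter) +
    oracle_quadtree_L0(sub, x1 + h2, x2 + h2, h2, slopes, gbits, T, lambda, min_block, h_filter)
  min(direct, split)
}

# confusion-table metrics by direct arithmetic
oracle_metrics <- function(tp, tn, fp, fn) {
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(p) && !is.na(sen) && p + sen > 0) 2 * p * sen / (p + sen)
        else NA_real_
  list(Acc = acc, Sen = sen, Spe = spe, P = p, F1 = f1)
}

# evaluate expr under a temporary seed, restoring the RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# a straight step edge of given slope through an h x w block
edge_block <- function(h, w, slope, intercept, lo = 60, hi = 180) {
  m <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w)
    m[r, c] <- if ((r - 1) - slope * (c - 1) > intercept) hi else lo
  m
}

# random tensor fixture for classifier tests
fixture_tensor <- function(cls, ts = 16L, sd = 0.3) {
  a <- array(stats::rnorm(4 * ts * ts, sd = sd), c(4, ts, ts))
  if (cls == 1) a[2, 4:(ts - 4), 4:(ts - 4)] <- a[2, 4:(ts - 4), 4:(ts - 4)] + 2
  structure(a, class = "bandelet_tensor", channel_order = c("A", "H", "V", "D"),
            normalised = FALSE, source_id = NA_character_)
}
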