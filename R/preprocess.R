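## Data program of the classification study: SMOTE oversampling of the
## minority class, balanced combination, geometric/photometric augmentation
## to a target count, and the stratified 80/20 split.

#' SMOTE oversampling of minority-class images
#'
#' Images are flattened to vectors; each synthetic sample is
#' \eqn{x_{new} = x_i + u (x_{nn} - x_i)} with \eqn{u \sim U(0,1)} and
#' \eqn{x_{nn}} one of the `k_neighbors` nearest minority neighbours of
#' \eqn{x_i} (Euclidean distance). Base samples are cycled round-robin until
#' `target_count` is reached. Deterministic given `seed`.
#'
#' @param minority list of equal-sized numeric matrices (>= 2).
#' @param target_count desired output count (>= current count).
#' @param k_neighbors neighbourhood size, `<= length(minority) - 1`.
#' @param seed integer seed.
#' @return List with `images` (originals first, then synthetics) and
#'   `provenance` (`"real"` / `"smote"`).
#' @export
smote_oversample <- function(minority, target_count, k_neighbors = 5L, seed = 1L) {
  n <- length(minority)
  if (n < 2L) stop_bandelet("SMOTE needs at least 2 minority samples")
  target_count <- as.integer(target_count)
  if (target_count < n)
    stop_bandelet("target_count (", target_count, ") below current count (", n, ")")
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L || k_neighbors > n - 1L)
    stop_bandelet("k_neighbors must be in [1, ", n - 1L, "]")
  if (target_count == n)
    return(list(images = minority, provenance = rep("real", n)))
  shp <- dim(minority[[1]])
  X <- t(vapply(minority, function(m) {
    if (!all(dim(m) == shp)) stop_bandelet("SMOTE requires equal image sizes")
    as.vector(m)
  }, numeric(prod(shp))))
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k_neighbors)]))
  n_new <- target_count - n
  synth <- with_seed(seed, {
    lapply(seq_len(n_new), function(j) {
      i <- ((j - 1L) %% n) + 1L
      pick <- nn[i, sample.int(k_neighbors, 1L)]
      u <- stats::runif(1)
      matrix(X[i, ] + u * (X[pick, ] - X[i, ]), shp[1], shp[2])
    })
  })
  list(images = c(minority, synth),
       provenance = c(rep("real", n), rep("smote", n_new)))
}

#' Combine oversampled minority and majority into a balanced set
#'
#' Takes the first `per_class` items of each class in stable input order
#' (the majority class is truncated by file order) and attaches labels:
#' minority = benign = 0, majority = malignant = 1.
#'
#' @param minority_oversampled output of [smote_oversample()] (or a plain
#'   list of matrices).
#' @param majority list of majority-class matrices.
#' @param per_class items kept per class.
#' @return A `labelled_image_set` with `2 * per_class` items.
#' @export
balance_dataset <- function(minority_oversampled, majority, per_class) {
  if (is.list(minority_oversampled) && !is.null(minority_oversampled$images)) {
    min_imgs <- minority_oversampled$images
    min_prov <- minority_oversampled$provenance
  } else {
    min_imgs <- minority_oversampled
    min_prov <- rep("real", length(min_imgs))
  }
  per_class <- as.integer(per_class)
  if (per_class < 0L) stop_bandelet("per_class must be nonnegative")
  if (length(min_imgs) < per_class || length(majority) < per_class)
    stop_bandelet("insufficient items: need ", per_class, " per class, have ",
                  length(min_imgs), " minority / ", length(majority), " majority")
  idx <- seq_len(per_class)
  labelled_image_set(
    images = c(min_imgs[idx], majority[idx]),
    labels = c(rep(0L, per_class), rep(1L, per_class)),
    provenance = c(min_prov[idx], rep("real", per_class)))
}

## nearest-neighbour geometric warps; exposed pixels take the nearest valid
## source pixel (coordinate clamping)
nn_rotate <- function(img, angle_deg) {
  h <- nrow(img); w <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  u <- matrix(seq_len(h), h, w) - cy
  v <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  sr <- pmin(pmax(round(cy + cos(th) * u - sin(th) * v), 1), h)
  sc <- pmin(pmax(round(cx + sin(th) * u + cos(th) * v), 1), w)
  matrix(img[cbind(as.vector(sr), as.vector(sc))], h, w)
}

nn_height_scale <- function(img, factor) {
  h <- nrow(img)
  cy <- (h + 1) / 2
  sr <- pmin(pmax(round(cy + (seq_len(h) - cy) / factor), 1), h)
  img[sr, , drop = FALSE]
}

#' Augment a labelled set to a target size
#'
#' Originals are retained (resized to the output size); additional items are
#' produced by cycling over the base images in class-interleaved round-robin
#' order, each time applying a random composition of operations — each
#' applied independently with probability `p`: brightness scaling
#' `U[0.8, 1.2]`, horizontal flip, rotation `U[-15, 15]` degrees with
#' nearest-neighbour fill, height scaling `U[0.9, 1.1]` with
#' nearest-neighbour fill. Every output is resized to `ops_config$out_size`
#' and clipped to [0, 255]. Class proportions of the base set are preserved
#' within one item. Deterministic given `seed`.
#'
#' @param dataset a `labelled_image_set`.
#' @param target_total desired total count (>= current size).
#' @param ops_config list with `brightness` (range), `rotation` (max degrees),
#'   `height_scale` (range), `p` (per-op probability), `out_size` (h, w).
#' @param seed integer seed.
#' @return A `labelled_image_set` of exactly `target_total` items.
#' @export
augment_to_target <- function(dataset, target_total = 2048L,
                              ops_config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(brightness = c(0.8, 1.2), rotation = 15,
                                height_scale = c(0.9, 1.1), p = 0.5,
                                out_size = c(512L, 512L)), ops_config)
  n <- length(dataset$images)
  if (n == 0L) stop_bandelet("cannot augment an empty dataset")
  target_total <- as.integer(target_total)
  if (target_total < n)
    stop_bandelet("target_total (", target_total, ") below current size (", n, ")")
  rs <- function(m) resize_image(m, cfg$out_size)
  base_imgs <- lapply(dataset$images, rs)
  if (target_total == n)
    return(labelled_image_set(base_imgs, dataset$labels, dataset$provenance,
                              seed = seed))
  # class-interleaved cycling order: any prefix is class-balanced within +-1
  i0 <- which(dataset$labels == 0L); i1 <- which(dataset$labels == 1L)
  pos <- c((seq_along(i0) - 0.5) / max(1, length(i0)),
           (seq_along(i1) - 0.5) / max(1, length(i1)))
  cycle <- c(i0, i1)[order(pos)]
  n_new <- target_total - n
  out <- with_seed(seed, {
    lapply(seq_len(n_new), function(j) {
      b <- cycle[((j - 1L) %% n) + 1L]
      img <- dataset$images[[b]]
      if (stats::runif(1) < cfg$p)
        img <- img * stats::runif(1, cfg$brightness[1], cfg$brightness[2])
      if (stats::runif(1) < cfg$p)
        img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
      if (stats::runif(1) < cfg$p)
        img <- nn_rotate(img, stats::runif(1, -cfg$rotation, cfg$rotation))
      if (stats::runif(1) < cfg$p)
        img <- nn_height_scale(img, stats::runif(1, cfg$height_scale[1],
                                                 cfg$height_scale[2]))
      list(img = clip01(rs(img)), label = dataset$labels[b])
    })
  })
  labelled_image_set(
    images = c(base_imgs, lapply(out, `[[`, "img")),
    labels = c(dataset$labels, vapply(out, `[[`, integer(1), "label")),
    provenance = c(dataset$provenance, rep("augmented", n_new)),
    seed = seed)
}

#' Stratified train/validation split
#'
#' Splits by label so both sides keep the class proportions; the training
#' size is `floor(train_fraction * N)` (per-class floors, remainders assigned
#' by largest fractional part), the two sides partition the input exactly.
#' Deterministic given `seed`.
#'
#' @param dataset a `labelled_image_set`.
#' @param train_fraction in (0, 1).
#' @param seed integer seed.
#' @return List with elements `train` and `val`, both `labelled_image_set`s.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_bandelet("train_fraction must lie in (0, 1)")
  labs <- dataset$labels
  if (any(table(factor(labs, levels = c(0L, 1L))) < 2L))
    stop_bandelet("each class needs at least 2 items to split")
  N <- length(labs)
  n_train <- floor(train_fraction * N)
  cls <- lapply(c(0L, 1L), function(l) which(labs == l))
  exact <- vapply(cls, length, numeric(1)) * train_fraction
  take <- floor(exact)
  short <- n_train - sum(take)
  if (short > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(cls), function(i) {
      ix <- cls[[i]]
      ix[sample.int(length(ix), take[i])]
    }))
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(N), train_idx)
  subset_lis <- function(ix)
    labelled_image_set(dataset$images[ix], labs[ix], dataset$provenance[ix],
                       seed = seed)
  list(train = subset_lis(train_idx), val = subset_lis(val_idx))
}
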