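#' Orthonormal wavelet filters
#'
#' Analysis lowpass filters for the supported orthogonal wavelets. The
#' highpass is derived by the quadrature-mirror rule
#' \eqn{g[n] = (-1)^n h[L-1-n]}. All filters are orthonormal, so with
#' periodic boundary extension the transform matrix is orthogonal and
#' Parseval's identity holds exactly.
#'
#' @param name one of `"haar"`, `"db2"`, `"db4"`.
#' @return list with elements `h` (lowpass) and `g` (highpass).
#' @export
wavelet_filter <- function(name = "db2") {
  h <- switch(name,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855, 0.714846570552542, 0.630880767929590,
            -0.027983769416984, -0.187034811718881, 0.030841381835987,
            0.032883011666983, -0.010597401784997),
    stop_bandelet("unknown wavelet name: '", name,
                  "' (supported: haar, db2, db4)")
  )
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  list(h = h, g = g, name = name)
}

## One analysis step of the periodic 1D DWT, applied down the columns of a
## matrix. Odd column counts are periodised by replicating the last sample
## (the standard periodisation convention); the inverse drops the pad.
dwt_step_cols <- function(x, filt) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (n %% 2L == 1L) {
    x <- rbind(x, x[n, , drop = FALSE])
    n <- n + 1L
  }
  half <- n %/% 2L
  L <- length(filt$h)
  a <- matrix(0, half, ncol(x))
  d <- matrix(0, half, ncol(x))
  base <- 2L * (0:(half - 1L))
  for (k in 0:(L - 1L)) {
    idx <- ((base + k) %% n) + 1L
    a <- a + filt$h[k + 1L] * x[idx, , drop = FALSE]
    d <- d + filt$g[k + 1L] * x[idx, , drop = FALSE]
  }
  list(a = a, d = d)
}

## Inverse of dwt_step_cols. `n_out` is the original (possibly odd) length.
idwt_step_cols <- function(a, d, filt, n_out) {
  half <- nrow(a)
  n <- 2L * half
  L <- length(filt$h)
  x <- matrix(0, n, ncol(a))
  base <- 2L * (0:(half - 1L))
  for (k in 0:(L - 1L)) {
    idx <- ((base + k) %% n) + 1L
    x[idx, ] <- x[idx, ] + filt$h[k + 1L] * a + filt$g[k + 1L] * d
  }
  x[seq_len(n_out), , drop = FALSE]
}

#' Multilevel separable 2D discrete wavelet transform
#'
#' Decomposes a greyscale image into LL/LH/HL/HH subbands per level using an
#' orthonormal filter pair with periodic boundary extension. Only the
#' coarsest approximation (LL) is retained; detail subbands are kept at every
#' level. Subband orientation follows the usual convention: LH is lowpass
#' along x and highpass along y (responds to horizontal structure), HL the
#' converse (vertical structure), HH diagonal.
#'
#' @param image numeric matrix (rows = y, columns = x), finite values.
#' @param wavelet filter name, see [wavelet_filter()].
#' @param levels decomposition depth, `1 <= levels <= floor(log2(min(dim)))`.
#' @return An object of class `subband_set`: list with `LL` (coarsest
#'   approximation), `details` (list of `levels` lists with `LH`, `HL`, `HH`),
#'   `levels`, `wavelet`, `original_shape`, and the per-level input shapes
#'   needed for exact inversion.
#' @seealso [idwt2()], [hard_threshold()]
#' @examples
#' x <- matrix(rnorm(256), 16, 16)
#' sb <- dwt2(x, "db2", 2)
#' max(abs(idwt2(sb) - x)) < 1e-10
#' @export
dwt2 <- function(image, wavelet = "db2", levels = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_bandelet("dwt2 expects a 2D numeric matrix")
  if (any(!is.finite(image)))
    stop_bandelet("dwt2 expects finite-valued input")
  levels <- as.integer(levels)
  max_lev <- floor(log2(min(dim(image))))
  if (levels < 1L || levels > max_lev)
    stop_bandelet("levels must be in [1, ", max_lev, "] for a ",
                  nrow(image), "x", ncol(image), " image")
  filt <- wavelet_filter(wavelet)

  details <- vector("list", levels)
  shapes <- vector("list", levels)
  cur <- image
  for (j in seq_len(levels)) {
    shapes[[j]] <- dim(cur)
    cs <- dwt_step_cols(cur, filt)                  # along y (rows)
    Ly <- cs$a; Hy <- cs$d
    rsL <- dwt_step_cols(t(Ly), filt)               # along x (columns)
    rsH <- dwt_step_cols(t(Hy), filt)
    LL <- t(rsL$a); HL <- t(rsL$d)                  # HL: highpass x, lowpass y
    LH <- t(rsH$a); HH <- t(rsH$d)                  # LH: lowpass x, highpass y
    details[[j]] <- list(LH = LH, HL = HL, HH = HH)
    cur <- LL
  }
  structure(list(LL = cur, details = details, levels = levels,
                 wavelet = wavelet, original_shape = dim(image),
                 level_shapes = shapes),
            class = "subband_set")
}

#' Inverse multilevel 2D discrete wavelet transform
#'
#' Exact synthesis inverse of [dwt2()].
#'
#' @param subbands a `subband_set`.
#' @return Numeric matrix of the original shape.
#' @export
idwt2 <- function(subbands) {
  if (!inherits(subbands, "subband_set"))
    stop_bandelet("idwt2 expects a subband_set")
  filt <- wavelet_filter(subbands$wavelet)
  cur <- subbands$LL
  for (j in rev(seq_len(subbands$levels))) {
    dt <- subbands$details[[j]]
    shape <- subbands$level_shapes[[j]]
    if (!all(dim(cur) == dim(dt$LH)) || !all(dim(dt$HL) == dim(dt$HH)) ||
        !all(dim(cur) == dim(dt$HL)))
      stop_bandelet("shape-inconsistent subbands at level ", j)
    Ly <- t(idwt_step_cols(t(cur), t(dt$HL), filt, shape[2]))    # undo x step
    Hy <- t(idwt_step_cols(t(dt$LH), t(dt$HH), filt, shape[2]))
    cur <- idwt_step_cols(Ly, Hy, filt, shape[1])                # undo y step
  }
  cur
}

#' Hard-threshold detail coefficients
#'
#' Sets detail coefficients with \eqn{|c| \le T} to zero; the coarsest LL is
#' never touched. Survivors are counted with the strict rule \eqn{|c| > T},
#' the same significance rule used by the bandelet Lagrangian cost.
#'
#' @param subbands a `subband_set`.
#' @param T nonnegative threshold on the 8-bit intensity scale.
#' @return The thresholded `subband_set`, with attribute `n_significant`
#'   giving the surviving detail count (also see [significant_count()]).
#' @export
hard_threshold <- function(subbands, T) {
  if (!inherits(subbands, "subband_set"))
    stop_bandelet("hard_threshold expects a subband_set")
  if (length(T) != 1L || !is.finite(T) || T < 0)
    stop_bandelet("threshold T must be a single nonnegative number")
  n_sig <- 0L
  for (j in seq_len(subbands$levels)) {
    for (o in c("LH", "HL", "HH")) {
      m <- subbands$details[[j]][[o]]
      keep <- abs(m) > T
      m[!keep] <- 0
      n_sig <- n_sig + sum(keep)
      subbands$details[[j]][[o]] <- m
    }
  }
  attr(subbands, "n_significant") <- n_sig
  subbands
}

#' Count significant detail coefficients of a subband set
#'
#' @param subbands a `subband_set`.
#' @param T nonnegative threshold; a coefficient is significant when
#'   \eqn{|c| > T}.
#' @return Integer count.
#' @export
significant_count <- function(subbands, T) {
  if (T < 0) stop_bandelet("threshold T must be nonnegative")
  s <- 0L
  for (j in seq_len(subbands$levels))
    for (o in c("LH", "HL", "HH"))
      s <- s + sum(abs(subbands$details[[j]][[o]]) > T)
  s
}

#' @export
print.subband_set <- function(x, ...) {
  cat("2D DWT subband set\n")
  cat("  wavelet:", x$wavelet, "  levels:", x$levels, "\n")
  cat("  original shape:", paste(x$original_shape, collapse = " x "), "\n")
  for (j in seq_len(x$levels))
    cat(sprintf("  level %d details: %s\n", j,
                paste(dim(x$details[[j]]$LH), collapse = " x ")))
  cat("  coarsest LL:", paste(dim(x$LL), collapse = " x "), "\n")
  invisible(x)
}

#' Write/read a subband set archive
#'
#' Stores the named coefficient arrays plus a small header (wavelet name,
#' levels, original shape) in one file; the round trip is bit-exact.
#'
#' @param subbands a `subband_set`.
#' @param path file path.
#' @return `path` (write) or the restored `subband_set` (read).
#' @export
write_subbands <- function(subbands, path) {
  stopifnot(inherits(subbands, "subband_set"))
  saveRDS(subbands, path)
  invisible(path)
}

#' @rdname write_subbands
#' @export
read_subbands <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "subband_set")) stop_bandelet("not a subband_set archive")
  x
}
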