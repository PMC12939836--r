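## Geometric flow: per-block direction candidates, the unit tangent of a
## slope, and the exact warped reordering that bandeletisation transforms
## along. Coordinates follow the transform convention: x1 is the horizontal
## axis (matrix column), x2 the vertical axis (matrix row); a slope c' is the
## vertical displacement per unit horizontal step.

NO_FLOW <- NA_real_

#' Is a flow candidate the no-flow marker?
#' @param slope numeric slope or `NA` (no flow).
#' @return logical.
#' @export
is_no_flow <- function(slope) is.na(slope)

#' Build a discrete dictionary of flow candidates
#'
#' Entry 0 is the distinguished NO_FLOW candidate (block treated as uniformly
#' regular, no warping). The remaining entries are `n_directions` slopes
#' uniformly spaced on `[-max_slope, max_slope]`, with slope 0 appended when
#' the uniform grid misses it; duplicates are removed. The slope multiset is
#' symmetric about 0 by construction.
#'
#' @param n_directions even positive integer, number of uniform slopes (>= 2).
#' @param max_slope positive real, largest |slope| represented.
#' @return Object of class `flow_dictionary`: list with `slopes` (numeric,
#'   `NA` first for NO_FLOW), `geometry_bits` (= ceil(log2(#entries)), >= 1).
#' @examples
#' d <- build_dictionary(16, 2)
#' d$geometry_bits  # 5: 16 slopes + forced 0 + NO_FLOW = 18 entries
#' @export
build_dictionary <- function(n_directions = 16L, max_slope = 2) {
  n_directions <- as.integer(n_directions)
  if (n_directions < 2L || n_directions %% 2L != 0L)
    stop_bandelet("n_directions must be an even integer >= 2")
  if (!is.finite(max_slope) || max_slope <= 0)
    stop_bandelet("max_slope must be positive")
  # uniform grid on [-max_slope, max_slope], built as mirrored halves so the
  # multiset is exactly closed under negation (bitwise)
  if (n_directions == 2L) {
    s <- c(-max_slope, max_slope)
  } else {
    pos <- max_slope * (2 * seq_len(n_directions %/% 2L) - 1) / (n_directions - 1)
    s <- c(-rev(pos), pos)
  }
  if (!any(s == 0)) s <- c(s, 0)
  s <- unique(s)
  slopes <- c(NO_FLOW, s)
  structure(list(slopes = slopes,
                 geometry_bits = max(1L, as.integer(ceiling(log2(length(slopes)))))),
            class = "flow_dictionary")
}

#' @export
print.flow_dictionary <- function(x, ...) {
  cat("Flow dictionary:", length(x$slopes), "entries (incl. NO_FLOW),",
      x$geometry_bits, "geometry bits\n")
  cat("  slopes:", paste(signif(x$slopes[-1], 4), collapse = " "), "\n")
  invisible(x)
}

#' Unit tangent vector of a geometric flow
#'
#' Maps a slope c' to the unit vector \eqn{(1, c')/\sqrt{1 + c'^2}} tangent to
#' the flow curve.
#'
#' @param slope finite real slope; the NO_FLOW marker is rejected (no
#'   direction is defined for an unflowed block).
#' @return Numeric length-2 unit vector.
#' @export
flow_vector <- function(slope) {
  if (length(slope) != 1L || is_no_flow(slope) || !is.finite(slope))
    stop_bandelet("flow_vector requires a single finite slope (not NO_FLOW)")
  c(1, slope) / sqrt(1 + slope^2)
}

# permutation cache: warp orders depend only on (h, w, slope) and are reused
# heavily across quadtree nodes of equal size
.warp_cache <- new.env(parent = emptyenv())

#' Warped ordering of a block's grid positions
#'
#' Realises the coordinate warp \eqn{x_2 \mapsto x_2 - c'(x_1)} as an exact
#' reordering: positions (x1, x2) are sorted by the warped key
#' `x2 - slope * x1`, ties broken by ascending x1. The result is a
#' permutation (a bijection), so warping is losslessly invertible —
#' interpolation-free, preserving orthonormality of the downstream 1D
#' transform.
#'
#' @param block_shape integer (h, w), both >= 1.
#' @param slope finite real slope.
#' @return Integer permutation of `1:(h*w)`; entries are column-major linear
#'   indices into the block, in warped order.
#' @examples
#' warp_order(c(2, 2), 1)  # (1,0),(0,0),(1,1),(0,1) in (x1,x2) coordinates
#' @export
warp_order <- function(block_shape, slope) {
  h <- as.integer(block_shape[1]); w <- as.integer(block_shape[2])
  if (h < 1L || w < 1L) stop_bandelet("empty block")
  if (!is.finite(slope)) stop_bandelet("warp_order requires a finite slope")
  key <- sprintf("%d_%d_%.17g", h, w, slope)
  hit <- .warp_cache[[key]]
  if (!is.null(hit)) return(hit)
  x1 <- rep(0:(w - 1L), each = h)   # column index, column-major enumeration
  x2 <- rep(0:(h - 1L), times = w)  # row index
  perm <- order(x2 - slope * x1, x1)
  .warp_cache[[key]] <- perm
  perm
}

#' Estimate the geometric flow of a block
#'
#' Exhaustively evaluates every dictionary entry: the NO_FLOW cost is the
#' Lagrangian cost of the raw (untransformed) block; each slope's cost is the
#' Lagrangian cost after bandeletisation along that slope (see
#' [block_cost()]). Ties are broken in favour of NO_FLOW, then the smaller
#' |slope|, then the negative slope, so the simplest geometric model wins and
#' output is deterministic.
#'
#' @param block numeric matrix of coefficients.
#' @param dictionary a `flow_dictionary`.
#' @param T nonnegative threshold (quantisation step).
#' @param lambda positive Lagrangian multiplier.
#' @return List with `slope` (`NA` for NO_FLOW), `index` (position in the
#'   dictionary, 0-based with NO_FLOW = 0), and `cost`.
#' @export
estimate_flow <- function(block, dictionary, T, lambda) {
  if (!inherits(dictionary, "flow_dictionary") || length(dictionary$slopes) == 0L)
    stop_bandelet("estimate_flow requires a non-empty flow_dictionary")
  gb <- dictionary$geometry_bits
  slopes <- dictionary$slopes[-1]
  # tie order: smaller |slope| first, negative before positive at equal |s|
  ord <- order(abs(slopes), slopes)
  best_cost <- block_cost(block, NO_FLOW, T, lambda, gb)
  best_slope <- NO_FLOW
  best_index <- 0L
  for (i in ord) {
    cst <- block_cost(block, slopes[i], T, lambda, gb)
    if (cst < best_cost) {
      best_cost <- cst; best_slope <- slopes[i]; best_index <- i
    }
  }
  list(slope = best_slope, index = best_index, cost = best_cost)
}
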