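## Four-channel geometry-aware feature tensors: the bandelet coefficient
## maps (approximation + horizontal/vertical/diagonal detail) that replace
## the raw greyscale image as classifier input, plus the training-set
## z-score normaliser.

#' Resize a greyscale image
#'
#' Bilinear (default) or nearest-neighbour resampling to an exact target
#' shape.
#'
#' @param image numeric matrix.
#' @param target integer (h, w), both positive.
#' @param method `"bilinear"` or `"nearest"`.
#' @return Numeric matrix of shape `target`.
#' @export
resize_image <- function(image, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!is.matrix(image) || nrow(image) < 1L || ncol(image) < 1L)
    stop_bandelet("resize_image expects a nonempty matrix")
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L))
    stop_bandelet("target shape must be two positive integers")
  if (all(dim(image) == target)) return(image)
  # EBImage convention: dim1 -> w argument, dim2 -> h argument
  out <- EBImage::resize(image, w = target[1], h = target[2],
                         filter = if (method == "bilinear") "bilinear" else "none")
  matrix(as.numeric(out), target[1], target[2])
}

#' Default parameters for bandelet tensor extraction
#'
#' @param resize_to working resolution the image is resized to before the
#'   transform (square side, default 512).
#' @param tensor_size spatial size of each output channel (default 224).
#' @param wavelet,levels,T,lambda,dictionary,min_block passed to [bandelet()];
#'   the four channels are taken from decomposition level 1.
#' @return Named list of parameters.
#' @export
tensor_params <- function(resize_to = 512L, tensor_size = 224L,
                          wavelet = "db2", levels = 1L, T = 30, lambda = 1,
                          dictionary = build_dictionary(), min_block = 4L) {
  list(resize_to = as.integer(resize_to), tensor_size = as.integer(tensor_size),
       wavelet = wavelet, levels = as.integer(levels), T = T, lambda = lambda,
       dictionary = dictionary, min_block = as.integer(min_block))
}

#' Extract the four-channel bandelet tensor of an image
#'
#' Resizes the image to `resize_to` square, fits the bandelet representation,
#' and materialises four coefficient-domain maps: the approximation (LL) plus
#' the level-1 LH/HL/HH detail subbands with each leaf's bandelet
#' coefficients placed back at their grid positions (these are coefficient
#' maps, not partial reconstructions). Each map is resized to `tensor_size`
#' and the four are stacked along the channel dimension in order
#' A (approximation), H (horizontal detail), V (vertical), D (diagonal).
#'
#' @param image numeric greyscale matrix.
#' @param params see [tensor_params()].
#' @param source_id provenance string carried on the tensor.
#' @return Object of class `bandelet_tensor`: numeric array
#'   `(4, tensor_size, tensor_size)` with attributes `channel_order`,
#'   `normalised`, `source_id`.
#' @export
extract_bandelet_tensor <- function(image, params = tensor_params(),
                                    source_id = NA_character_) {
  img <- resize_image(image, c(params$resize_to, params$resize_to))
  fit <- bandelet(img, wavelet = params$wavelet, levels = params$levels,
                  T = params$T, lambda = params$lambda,
                  dictionary = params$dictionary, min_block = params$min_block)
  maps <- list(
    A = fit$LL,
    H = rebuild_subband(fit, "L1_LH", coefficient_domain = TRUE),
    V = rebuild_subband(fit, "L1_HL", coefficient_domain = TRUE),
    D = rebuild_subband(fit, "L1_HH", coefficient_domain = TRUE))
  ts <- params$tensor_size
  out <- array(0, dim = c(4L, ts, ts))
  for (i in 1:4) out[i, , ] <- resize_image(maps[[i]], c(ts, ts))
  structure(out, class = "bandelet_tensor",
            channel_order = c("A", "H", "V", "D"),
            normalised = FALSE, source_id = source_id)
}

#' @export
print.bandelet_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Bandelet tensor: %d channels (%s), %d x %d, %s\n",
              d[1], paste(attr(x, "channel_order"), collapse = ""),
              d[2], d[3],
              if (isTRUE(attr(x, "normalised"))) "normalised" else "raw"))
  invisible(x)
}

#' Fit per-channel z-score normalisation parameters
#'
#' Computes the per-channel mean and population standard deviation over all
#' pixels of the training tensors. Degenerate (constant) channels get
#' sigma = 1 so normalisation is well defined. Statistics must come from the
#' training split only; applying them elsewhere never re-fits.
#'
#' @param tensors list of `bandelet_tensor`s (>= 2).
#' @param fitted_on identifier of the training set.
#' @return Object of class `tensor_normalizer`: list with `mu`, `sigma`
#'   (length-4 numeric) and `fitted_on`.
#' @export
fit_normalizer <- function(tensors, fitted_on = "train") {
  if (length(tensors) < 2L)
    stop_bandelet("fit_normalizer needs at least 2 training tensors")
  ch <- lapply(1:4, function(i)
    unlist(lapply(tensors, function(tns) as.vector(tns[i, , ])), use.names = FALSE))
  mu <- vapply(ch, mean, numeric(1))
  sigma <- vapply(ch, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
  sigma[sigma == 0] <- 1
  structure(list(mu = mu, sigma = sigma, fitted_on = fitted_on),
            class = "tensor_normalizer")
}

#' Apply a fitted z-score normaliser to a tensor
#'
#' Channel-wise \eqn{\hat x = (x - \mu)/\sigma}. Re-normalising an already
#' normalised tensor is rejected.
#'
#' @param tensor a `bandelet_tensor`.
#' @param params a `tensor_normalizer`.
#' @return The normalised `bandelet_tensor`.
#' @export
apply_normalizer <- function(tensor, params) {
  if (!inherits(params, "tensor_normalizer"))
    stop_bandelet("params must be a fitted tensor_normalizer")
  if (isTRUE(attr(tensor, "normalised")))
    stop_bandelet("tensor is already normalised")
  out <- tensor
  for (i in 1:4) out[i, , ] <- (tensor[i, , ] - params$mu[i]) / params$sigma[i]
  attr(out, "normalised") <- TRUE
  out
}
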