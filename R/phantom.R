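## Synthetic B-mode ultrasound phantoms: a smooth tissue background with an
## embedded hypoechoic nodule whose boundary regularity, echogenicity and
## aspect ratio differ by class, under multiplicative positive-skew speckle.
## Benign nodules are near-elliptical with at most gentle low-order boundary
## modulation; malignant nodules are taller than wide with strong
## higher-order boundary irregularity — the discriminative cues mirror
## clinical descriptors (margin irregularity, taller-than-wide shape).

#' Specification of one ultrasound phantom
#'
#' @param size integer (h, w) image size in pixels.
#' @param class_label `"benign"` or `"malignant"`.
#' @param centre nodule centre (row, col); default: image centre.
#' @param axes nodule semi-axes (vertical, horizontal) in pixels; defaults
#'   are class-dependent (malignant taller than wide).
#' @param contrast echogenicity contrast in (0, 1): the nodule interior is
#'   darker than the surrounding tissue by this fraction.
#' @param boundary_amplitude radial boundary-modulation amplitude as a
#'   fraction of the radius (benign <= 0.03, malignant >= 0.12 by default).
#' @param n_harmonics number of random boundary harmonics (benign <= 2,
#'   malignant >= 5 by default).
#' @param speckle multiplicative speckle scale (0 = noiseless).
#' @param seed integer seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256, 256),
                         class_label = c("benign", "malignant"),
                         centre = NULL, axes = NULL, contrast = 0.4,
                         boundary_amplitude = NULL, n_harmonics = NULL,
                         speckle = 0.15, seed = 1L) {
  class_label <- match.arg(class_label)
  h <- size[1]; w <- size[2]
  if (is.null(centre)) centre <- c(h / 2, w / 2)
  if (is.null(axes)) {
    base <- min(h, w) / 5
    axes <- if (class_label == "benign") c(base, base * 1.1)
            else c(base * 1.35, base * 0.85)  # taller than wide
  }
  if (is.null(boundary_amplitude))
    boundary_amplitude <- if (class_label == "benign") 0.02 else 0.16
  if (is.null(n_harmonics))
    n_harmonics <- if (class_label == "benign") 2L else 6L
  if (contrast <= 0 || contrast >= 1)
    stop_bandelet("contrast must lie in (0, 1)")
  rmax <- max(axes) * (1 + boundary_amplitude)
  if (centre[1] - rmax < 1 || centre[1] + rmax > h ||
      centre[2] - rmax < 1 || centre[2] + rmax > w)
    stop_bandelet("nodule does not fit inside the frame")
  structure(list(size = as.integer(size), class_label = class_label,
                 centre = centre, axes = axes, contrast = contrast,
                 boundary_amplitude = boundary_amplitude,
                 n_harmonics = as.integer(n_harmonics),
                 speckle = speckle, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one ultrasound-like phantom image
#'
#' Renders a smooth background (slow vertical attenuation plus a low-frequency
#' random field), carves the hypoechoic nodule whose radius is modulated by a
#' random harmonic series, then applies multiplicative speckle
#' \eqn{x (1 + s\,\eta)} with \eqn{\eta} a standardised log-normal
#' (unit-variance, positive skew) field, and clips to [0, 255]. Deterministic
#' given the spec's seed.
#'
#' @param spec a `phantom_spec`.
#' @return Numeric matrix (h x w) with values in [0, 255].
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$size[1]; w <- spec$size[2]
  with_seed(spec$seed, {
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    # background: mild depth attenuation + smooth random undulation
    bg <- 170 - 25 * (rr - 1) / (h - 1)
    fx <- runif(2, 0.5, 1.5); ph <- runif(2, 0, 2 * pi)
    bg <- bg + 8 * sin(2 * pi * fx[1] * (rr - 1) / h + ph[1]) *
               cos(2 * pi * fx[2] * (cc - 1) / w + ph[2])
    # nodule boundary: ellipse with harmonic radial modulation
    dy <- (rr - spec$centre[1]) / spec$axes[1]
    dx <- (cc - spec$centre[2]) / spec$axes[2]
    theta <- atan2(dy, dx)
    rho <- sqrt(dy^2 + dx^2)
    kmax <- spec$n_harmonics
    amp <- spec$boundary_amplitude
    mod <- matrix(0, h, w)
    if (kmax >= 1) {
      ks <- seq_len(kmax)
      aks <- runif(kmax, 0.4, 1) * amp / sqrt(kmax)
      phs <- runif(kmax, 0, 2 * pi)
      # weight toward the highest harmonics for irregular (malignant) bounds
      for (i in seq_len(kmax))
        mod <- mod + aks[i] * cos(ks[i] * theta + phs[i])
    }
    inside <- rho <= 1 + mod
    img <- bg
    img[inside] <- bg[inside] * (1 - spec$contrast)
    # multiplicative speckle: standardised log-normal field
    if (spec$speckle > 0) {
      sig <- 0.6
      ln <- exp(sig * matrix(rnorm(h * w), h, w))
      m <- exp(sig^2 / 2)
      v <- sqrt((exp(sig^2) - 1) * exp(sig^2))
      eta <- (ln - m) / v
      img <- img * (1 + spec$speckle * eta)
    }
    clip01(img)
  })
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_benign` + `n_malignant` phantoms with per-image seeds derived
#' from the master seed, labelled benign = 0 / malignant = 1, provenance
#' "real". The 14/62 default mirrors the class imbalance of the public
#' thyroid B-mode collection the phantoms emulate.
#'
#' @param n_benign,n_malignant nonnegative counts.
#' @param seed master seed.
#' @param size image size passed to [phantom_spec()].
#' @param speckle speckle scale passed to [phantom_spec()].
#' @return A `labelled_image_set` (see [labelled_image_set()]).
#' @export
generate_dataset <- function(n_benign = 14L, n_malignant = 62L, seed = 1L,
                             size = c(256, 256), speckle = 0.15) {
  n_benign <- as.integer(n_benign); n_malignant <- as.integer(n_malignant)
  stopifnot(n_benign >= 0L, n_malignant >= 0L)
  make <- function(i, lab) {
    sd_i <- derive_seed(seed, paste0("phantom_", lab, "_", i))
    sp <- with_seed(sd_i, phantom_spec(
      size = size, class_label = lab,
      centre = c(size[1] / 2 + runif(1, -0.08, 0.08) * size[1],
                 size[2] / 2 + runif(1, -0.08, 0.08) * size[2]),
      contrast = runif(1, 0.3, 0.5),
      speckle = speckle,
      seed = derive_seed(sd_i, "render")))
    generate_phantom(sp)
  }
  imgs <- c(lapply(seq_len(n_benign), make, lab = "benign"),
            lapply(seq_len(n_malignant), make, lab = "malignant"))
  labelled_image_set(images = imgs,
                     labels = c(rep(0L, n_benign), rep(1L, n_malignant)),
                     provenance = rep("real", n_benign + n_malignant),
                     seed = seed)
}

#' Generate a curved-boundary test image
#'
#' A noiseless piecewise-constant image split by a smooth sinusoidal
#' boundary: the canonical fixture for demonstrating the anisotropy gain of
#' the bandelet best basis over the separable wavelet (edges that are curved
#' but locally straight). Deterministic given `seed`; boundary amplitude,
#' period, phase and offset are drawn from the stated ranges.
#'
#' @param size square image side in pixels (default 128).
#' @param lo,hi intensities below/above the boundary.
#' @param seed integer seed.
#' @return Numeric `size` x `size` matrix.
#' @export
curved_boundary_phantom <- function(size = 128L, lo = 60, hi = 170, seed = 1L) {
  n <- as.integer(size)
  with_seed(seed, {
    amp <- stats::runif(1, n / 12, n / 5.5)
    ph <- stats::runif(1, 0, 2 * pi)
    off <- stats::runif(1, 0.38 * n, 0.62 * n)
    per <- sample(c(1, 2), 1)
    outer(0:(n - 1), 0:(n - 1), function(r, c)
      ifelse(r > off + amp * sin(2 * pi * per * c / n + ph), hi, lo))
  })
}

#' Construct a labelled image set
#'
#' The container moved through the preprocessing pipeline: greyscale images,
#' binary labels (benign = 0, malignant = 1) and per-item provenance in
#' `{"real", "smote", "augmented"}`.
#'
#' @param images list of numeric matrices.
#' @param labels integer vector in {0, 1}.
#' @param provenance character vector.
#' @param seed seed recorded for reproducibility (optional).
#' @return Object of class `labelled_image_set`.
#' @export
labelled_image_set <- function(images, labels, provenance = rep("real", length(images)),
                               seed = NA_integer_) {
  if (length(images) != length(labels) || length(labels) != length(provenance))
    stop_bandelet("images, labels and provenance must have equal length")
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop_bandelet("labels must be binary (0 = benign, 1 = malignant)")
  if (length(provenance) && !all(provenance %in% c("real", "smote", "augmented")))
    stop_bandelet("provenance must be in {real, smote, augmented}")
  structure(list(images = images, labels = labels, provenance = provenance,
                 seed = seed),
            class = "labelled_image_set")
}

#' @export
length.labelled_image_set <- function(x) length(x$images)

#' @export
print.labelled_image_set <- function(x, ...) {
  cat("Labelled image set:", length(x$images), "images\n")
  cat("  labels: ", sum(x$labels == 0L), "benign /", sum(x$labels == 1L),
      "malignant\n")
  cat("  provenance:", paste(names(table(x$provenance)),
                             table(x$provenance), collapse = ", "), "\n")
  if (length(x$images))
    cat("  image size:", paste(dim(x$images[[1]]), collapse = " x "), "\n")
  invisible(x)
}
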