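## Confusion-matrix metrics and repeated-fold descriptive statistics.

#' Classification metrics from binary predictions
#'
#' Computes the confusion counts (positive class = malignant = 1) and the
#' five percentage metrics: accuracy, sensitivity (recall on malignant),
#' specificity, precision and F1 (harmonic mean of precision and
#' sensitivity). Ratios with zero denominators are reported as `NA`
#' (absent), never as 0.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1).
#' @return Object of class `metrics_report`: list with `TP`, `TN`, `FP`,
#'   `FN`, `Acc`, `Sen`, `Spe`, `P`, `F1` (percentages).
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_bandelet("y_true and y_pred must have equal length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L)))
    stop_bandelet("labels must be binary 0/1")
  TP <- sum(y_true == 1L & y_pred == 1L)
  TN <- sum(y_true == 0L & y_pred == 0L)
  FP <- sum(y_true == 0L & y_pred == 1L)
  FN <- sum(y_true == 1L & y_pred == 0L)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  Acc <- ratio(TP + TN, TP + FP + TN + FN)
  Sen <- ratio(TP, TP + FN)
  Spe <- ratio(TN, TN + FP)
  P <- ratio(TP, TP + FP)
  F1 <- if (is.na(P) || is.na(Sen) || (P + Sen) == 0) NA_real_
        else 2 * P * Sen / (P + Sen)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 Acc = Acc, Sen = Sen, Spe = Spe, P = P, F1 = F1),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Confusion: TP=%d TN=%d FP=%d FN=%d (N=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat(sprintf("Acc %s | Sen %s | Spe %s | P %s | F1 %s\n",
              fmt(x$Acc), fmt(x$Sen), fmt(x$Spe), fmt(x$P), fmt(x$F1)))
  invisible(x)
}

#' Descriptive statistics of a metric across folds
#'
#' Mean, median, variance, standard deviation, first/third quartiles
#' (linear interpolation), minimum and maximum.
#'
#' @param per_fold_values numeric vector (>= 2 values; NAs dropped).
#' @return Named numeric vector of class `fold_statistics` with elements
#'   `mean`, `median`, `variance`, `sd`, `q1`, `q3`, `min`, `max`.
#' @export
fold_statistics <- function(per_fold_values) {
  v <- per_fold_values[!is.na(per_fold_values)]
  if (length(v) < 2L)
    stop_bandelet("fold_statistics needs at least 2 non-missing values")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(c(mean = mean(v), median = q[2], variance = stats::var(v),
              sd = stats::sd(v), q1 = q[1], q3 = q[3],
              min = min(v), max = max(v)),
            class = "fold_statistics")
}

#' @export
print.fold_statistics <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Repeated stratified k-fold cross-validation of the classifier
#'
#' Partitions the tensors into `k` stratified folds per repeat (seeded from
#' `config$seed`), trains the small CNN on each training side and evaluates
#' [compute_metrics()] on the held-out fold, then aggregates each metric
#' across all `k * repeats` fold records with [fold_statistics()].
#'
#' @param tensors list of `bandelet_tensor`s.
#' @param labels binary labels.
#' @param k number of folds (>= 2, no larger than the smaller class).
#' @param repeats number of repeats.
#' @param config a [training_config()].
#' @return List with `folds` (data.frame of per-fold metrics) and `stats`
#'   (list of `fold_statistics` per metric).
#' @export
cross_validate <- function(tensors, labels, k = 5L, repeats = 1L,
                           config = training_config()) {
  k <- as.integer(k)
  labels <- as.integer(labels)
  if (k < 2L) stop_bandelet("k must be >= 2")
  if (min(table(factor(labels, levels = c(0L, 1L)))) < k)
    stop_bandelet("each class must have at least k items")
  rows <- list()
  for (r in seq_len(repeats)) {
    fold_of <- integer(length(labels))
    assign_seed <- derive_seed(config$seed, paste0("cv_repeat_", r))
    with_seed(assign_seed, {
      for (l in c(0L, 1L)) {
        ix <- sample(which(labels == l))
        fold_of[ix] <- rep_len(seq_len(k), length(ix))
      }
    })
    for (f in seq_len(k)) {
      tr <- which(fold_of != f); va <- which(fold_of == f)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0("cv_fit_", r, "_", f))
      fit <- train_classifier(tensors[tr], labels[tr],
                              tensors[va], labels[va], cfg)
      pred <- predict(fit, tensors[va])
      m <- compute_metrics(labels[va], pred)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, Acc = m$Acc, Sen = m$Sen,
                   Spe = m$Spe, P = m$P, F1 = m$F1)
    }
  }
  folds <- do.call(rbind, rows)
  stats <- lapply(c("Acc", "Sen", "Spe", "P", "F1"),
                  function(nm) fold_statistics(folds[[nm]]))
  names(stats) <- c("Acc", "Sen", "Spe", "P", "F1")
  list(folds = folds, stats = stats)
}
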