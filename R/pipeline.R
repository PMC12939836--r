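## End-to-end workflow: load or synthesise images, SMOTE-balance, augment,
## extract bandelet tensors, normalise with training-set statistics, train
## the classifier and evaluate — writing a reproducible run directory.

#' Read a class-labelled image directory
#'
#' Expects `root/benign/*.png` and `root/malignant/*.png` (8-bit greyscale;
#' RGB images are averaged to grey). File-name order is the stable item
#' order.
#'
#' @param root directory containing `benign/` and `malignant/`.
#' @return A `labelled_image_set` with provenance `"real"`.
#' @export
read_image_dir <- function(root) {
  read_class <- function(sub) {
    files <- sort(list.files(file.path(root, sub), pattern = "\\.png$",
                             full.names = TRUE))
    lapply(files, function(f) {
      a <- png::readPNG(f)
      m <- if (length(dim(a)) == 3L) apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
           else a
      m * 255
    })
  }
  ben <- read_class("benign"); mal <- read_class("malignant")
  if (!length(ben) && !length(mal))
    stop_bandelet("no PNG images under ", root, "/{benign,malignant}")
  labelled_image_set(c(ben, mal),
                     c(rep(0L, length(ben)), rep(1L, length(mal))),
                     rep("real", length(ben) + length(mal)))
}

#' Write a labelled image set as PNG files
#'
#' @param dataset a `labelled_image_set`.
#' @param root output directory; `benign/` and `malignant/` are created.
#' @return `root`, invisibly.
#' @export
write_image_dir <- function(dataset, root) {
  for (sub in c("benign", "malignant"))
    dir.create(file.path(root, sub), recursive = TRUE, showWarnings = FALSE)
  counts <- c(0L, 0L)
  for (i in seq_along(dataset$images)) {
    l <- dataset$labels[i]
    counts[l + 1L] <- counts[l + 1L] + 1L
    sub <- if (l == 0L) "benign" else "malignant"
    png::writePNG(clip01(dataset$images[[i]]) / 255,
                  file.path(root, sub, sprintf("%s_%04d.png", sub, counts[l + 1L])))
  }
  invisible(root)
}

#' Run the full classification pipeline
#'
#' Executes the study workflow: load (or synthesise) the imbalanced image
#' set, SMOTE-oversample the benign class, combine into a balanced set,
#' augment to the target count, split stratified train/validation, extract
#' four-channel bandelet tensors, fit the z-score normaliser on the training
#' split only, train the small CNN and evaluate. With
#' `split_before_augment = TRUE` the balanced base set is split first and
#' each side augmented independently (no augmented siblings across the
#' split); the default `FALSE` keeps the classical augment-then-split order.
#'
#' Writes into `out_dir`: `config.yaml`, `counts.json` (the count trace),
#' `manifest.tsv` (item, label, provenance, split), `history.tsv`,
#' `metrics.tsv`, and returns the same objects invisibly.
#'
#' @param config configuration list, see [default_config()] / [load_config()].
#' @param out_dir run directory (created); `NULL` skips writing.
#' @param dataset optional pre-loaded `labelled_image_set` (overrides
#'   `input_dir` / synthesis).
#' @param dry_run validate the configuration and return without computing.
#' @return Invisibly, a list with `counts`, `metrics`, `history`, `model`,
#'   `normalizer`, `split`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         dataset = NULL, dry_run = FALSE) {
  cfg <- validate_config(utils::modifyList(default_config(), config))
  if (dry_run) return(invisible(list(config = cfg)))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_log <- function(...) message("[pipeline] ", ...)
  fail <- function(stage, e)
    stop_bandelet("stage '", stage, "' failed: ", conditionMessage(e))

  # --- load -----------------------------------------------------------
  ds <- tryCatch({
    if (!is.null(dataset)) dataset
    else if (!is.null(cfg$input_dir)) read_image_dir(cfg$input_dir)
    else generate_dataset(cfg$n_benign, cfg$n_malignant,
                          seed = derive_seed(cfg$seed, "synth"),
                          size = rep(cfg$phantom_size, 2), speckle = cfg$speckle)
  }, error = function(e) fail("load", e))
  n_benign0 <- sum(ds$labels == 0L)
  stage_log("loaded ", length(ds$images), " images (", n_benign0, " benign)")

  # --- SMOTE + balance ------------------------------------------------
  sm <- tryCatch(
    smote_oversample(ds$images[ds$labels == 0L], cfg$smote_target,
                     cfg$k_neighbors, seed = derive_seed(cfg$seed, "smote")),
    error = function(e) fail("smote", e))
  bal <- tryCatch(
    balance_dataset(sm, ds$images[ds$labels == 1L], cfg$per_class),
    error = function(e) fail("balance", e))
  stage_log("balanced to ", length(bal$images))

  ops <- list(out_size = rep(cfg$out_size, 2))

  # --- augment / split ------------------------------------------------
  if (isTRUE(cfg$split_before_augment)) {
    sp0 <- split_dataset(bal, cfg$train_fraction,
                         seed = derive_seed(cfg$seed, "split"))
    n_tr <- round(cfg$target_total * cfg$train_fraction)
    train_set <- augment_to_target(sp0$train, n_tr, ops,
                                   seed = derive_seed(cfg$seed, "augment_train"))
    val_set <- augment_to_target(sp0$val, cfg$target_total - n_tr, ops,
                                 seed = derive_seed(cfg$seed, "augment_val"))
    n_aug <- length(train_set$images) + length(val_set$images)
  } else {
    aug <- tryCatch(
      augment_to_target(bal, cfg$target_total, ops,
                        seed = derive_seed(cfg$seed, "augment")),
      error = function(e) fail("augment", e))
    n_aug <- length(aug$images)
    sp <- tryCatch(
      split_dataset(aug, cfg$train_fraction,
                    seed = derive_seed(cfg$seed, "split")),
      error = function(e) fail("split", e))
    train_set <- sp$train; val_set <- sp$val
  }
  stage_log("augmented to ", n_aug, "; split ",
            length(train_set$images), "/", length(val_set$images))

  # --- features -------------------------------------------------------
  tp <- tensor_params(resize_to = cfg$resize_to, tensor_size = cfg$tensor_size,
                      wavelet = cfg$wavelet, levels = cfg$levels, T = cfg$T,
                      lambda = cfg$lambda,
                      dictionary = build_dictionary(cfg$n_directions, cfg$max_slope),
                      min_block = cfg$min_block)
  extract_all <- function(set, tag)
    lapply(seq_along(set$images), function(i)
      extract_bandelet_tensor(set$images[[i]], tp,
                              source_id = paste0(tag, "_", i)))
  tens_tr <- tryCatch(extract_all(train_set, "train"),
                      error = function(e) fail("features", e))
  tens_va <- extract_all(val_set, "val")
  stage_log("extracted ", length(tens_tr) + length(tens_va), " tensors")

  norm <- fit_normalizer(tens_tr, fitted_on = "train")
  tens_tr <- lapply(tens_tr, apply_normalizer, params = norm)
  tens_va <- lapply(tens_va, apply_normalizer, params = norm)

  # --- train + evaluate ----------------------------------------------
  tc <- training_config(input_size = cfg$input_size,
                        freeze_epochs = cfg$freeze_epochs,
                        total_epochs = cfg$total_epochs,
                        learning_rate = cfg$learning_rate,
                        lr_decay = cfg$lr_decay, momentum = cfg$momentum,
                        unfreeze_lr_factor = cfg$unfreeze_lr_factor,
                        lambda_mix = cfg$lambda_mix,
                        batch_size = cfg$batch_size, restarts = cfg$restarts,
                        seed = derive_seed(cfg$seed, "train"))
  model <- tryCatch(
    train_classifier(tens_tr, train_set$labels, tens_va, val_set$labels, tc),
    error = function(e) fail("train", e))
  pred <- predict(model, tens_va)
  metrics <- compute_metrics(val_set$labels, pred)

  counts <- list(n_benign_initial = n_benign0,
                 n_after_smote = length(sm$images),
                 n_balanced = length(bal$images),
                 n_augmented = n_aug,
                 n_train = length(train_set$images),
                 n_val = length(val_set$images))

  if (!is.null(out_dir)) {
    write_config(cfg, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE)
    manifest <- data.frame(
      item = c(paste0("train_", seq_along(train_set$labels)),
               paste0("val_", seq_along(val_set$labels))),
      label = c(train_set$labels, val_set$labels),
      provenance = c(train_set$provenance, val_set$provenance),
      split = c(rep("train", length(train_set$labels)),
                rep("val", length(val_set$labels))))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(model$history, file.path(out_dir, "history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    mrow <- data.frame(Acc = metrics$Acc, Sen = metrics$Sen, Spe = metrics$Spe,
                       P = metrics$P, F1 = metrics$F1)
    utils::write.table(mrow, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(counts = counts, metrics = metrics, history = model$history,
                 model = model, normalizer = norm,
                 split = list(train = train_set, val = val_set)))
}
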