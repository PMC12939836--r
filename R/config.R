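## Run configuration: a flat YAML file of transform / preprocessing /
## training parameters with validated defaults.

#' Default run configuration
#'
#' @return Named list with every supported key and its default.
#' @export
default_config <- function() {
  list(
    # transform
    wavelet = "db2", levels = 1L, T = 30, lambda = 1,
    n_directions = 16L, max_slope = 2, min_block = 4L,
    # feature extraction
    resize_to = 512L, tensor_size = 224L,
    # preprocessing
    smote_target = 28L, per_class = 28L, k_neighbors = 5L,
    target_total = 2048L, train_fraction = 0.8,
    split_before_augment = FALSE, out_size = 512L,
    # data source
    input_dir = NULL, n_benign = 14L, n_malignant = 62L,
    phantom_size = 256L, speckle = 0.15,
    # training
    input_size = 32L, freeze_epochs = 0L, total_epochs = 30L,
    learning_rate = 0.05, lr_decay = 0, momentum = 0,
    unfreeze_lr_factor = 0.1, lambda_mix = 0, batch_size = 32L,
    restarts = 1L,
    # global
    seed = 17L)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_bandelet("invalid config: ", msg)
  chk(cfg$T >= 0, paste0("T must be >= 0 (got ", cfg$T, ")"))
  chk(cfg$lambda > 0, "lambda must be > 0")
  chk(cfg$levels >= 1, "levels must be >= 1")
  chk(cfg$min_block >= 2, "min_block must be >= 2")
  chk(cfg$n_directions >= 2 && cfg$n_directions %% 2 == 0,
      "n_directions must be an even integer >= 2")
  chk(cfg$max_slope > 0, "max_slope must be > 0")
  chk(cfg$train_fraction > 0 && cfg$train_fraction < 1,
      "train_fraction must lie in (0, 1)")
  chk(cfg$smote_target >= 2, "smote_target must be >= 2")
  chk(cfg$per_class >= 1, "per_class must be >= 1")
  chk(cfg$k_neighbors >= 1, "k_neighbors must be >= 1")
  chk(cfg$target_total >= 1, "target_total must be >= 1")
  chk(cfg$learning_rate > 0, "learning_rate must be > 0")
  chk(cfg$lr_decay >= 0, "lr_decay must be >= 0")
  chk(cfg$momentum >= 0 && cfg$momentum < 1, "momentum must lie in [0, 1)")
  chk(cfg$restarts >= 1, "restarts must be >= 1")
  chk(cfg$lambda_mix >= 0 && cfg$lambda_mix <= 1, "lambda_mix must be in [0, 1]")
  chk(cfg$freeze_epochs <= cfg$total_epochs,
      "freeze_epochs must not exceed total_epochs")
  chk(cfg$speckle >= 0, "speckle must be >= 0")
  cfg
}

#' Load and validate a run configuration
#'
#' Reads a YAML key-value file, fills unset keys with the defaults of
#' [default_config()], rejects unknown keys (named in the error) and
#' out-of-range values. An empty or missing-keys file yields pure defaults.
#'
#' @param path path to a YAML file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_bandelet("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_bandelet("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, user)
  int_keys <- c("levels", "n_directions", "min_block", "resize_to",
                "tensor_size", "smote_target", "per_class", "k_neighbors",
                "target_total", "out_size", "n_benign", "n_malignant",
                "phantom_size", "input_size", "freeze_epochs", "total_epochs",
                "batch_size", "restarts", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}
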