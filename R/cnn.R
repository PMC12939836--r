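## Small convolutional classifier over four-channel bandelet tensors. A
## three-block CNN (3x3 conv + ReLU + 2x2 max-pool, channel widths 8/16/32)
## with global average pooling and a softmax head, trained by mini-batch
## gradient descent (theta <- theta - alpha * grad of the cross-entropy).
## Supports the transfer-learning schedule: the convolutional base can be
## frozen for the first epochs and is then unfrozen at a reduced learning
## rate. Implemented in base R with im2col/col2im convolutions so the test
## backbone trains on one CPU in minutes.

#' Training configuration for the classifier
#'
#' @param backbone backbone identifier; `"small_cnn"` is the built-in test
#'   backbone (an external pretrained backbone can be plugged in by giving a
#'   weight list of the same shape as `init_small_cnn()` produces via
#'   `source_weights`).
#' @param input_size square side the tensor channels are downsampled to
#'   before entering the network (default 32).
#' @param freeze_epochs epochs during which the convolutional base is frozen
#'   (only the dense head trains).
#' @param total_epochs total training epochs (>= freeze_epochs).
#' @param learning_rate step size alpha of the gradient-descent update.
#' @param lr_decay per-epoch decay: the epoch-e step size is
#'   `learning_rate / (1 + lr_decay * (e - 1))` (0 = constant alpha).
#' @param momentum classical momentum coefficient mu in [0, 1): the update
#'   keeps a velocity `v <- mu v + grad; theta <- theta - alpha v`. The
#'   default 0 reduces to the plain rule `theta <- theta - alpha grad`.
#' @param restarts number of independent training runs (distinct seeded
#'   initialisations); the run with the lowest final training loss is kept.
#'   Selection never looks at validation data. `restarts = 1` (default)
#'   trains once with `seed` itself.
#' @param unfreeze_lr_factor multiplier applied to alpha once the base is
#'   unfrozen (fine-tuning at reduced rate).
#' @param lambda_mix weight of the optional source-task loss in the mixed
#'   objective `lambda * L_S + (1 - lambda) * L_T`; 0 (default) is pure
#'   target fine-tuning.
#' @param batch_size mini-batch size.
#' @param source_weights optional initial weights (transfer initialisation).
#' @param source_data optional list(tensors, labels) for the mixed loss.
#' @param seed integer seed; training is deterministic given the seed.
#' @return Named list of class `training_config`.
#' @export
training_config <- function(backbone = "small_cnn", input_size = 32L,
                            freeze_epochs = 0L, total_epochs = 30L,
                            learning_rate = 0.05, lr_decay = 0,
                            momentum = 0, unfreeze_lr_factor = 0.1,
                            lambda_mix = 0, batch_size = 32L,
                            restarts = 1L,
                            source_weights = NULL, source_data = NULL,
                            seed = 1L) {
  if (freeze_epochs > total_epochs)
    stop_bandelet("freeze_epochs must not exceed total_epochs")
  if (learning_rate <= 0) stop_bandelet("learning_rate must be positive")
  if (lambda_mix < 0 || lambda_mix > 1)
    stop_bandelet("lambda_mix must lie in [0, 1]")
  if (momentum < 0 || momentum >= 1)
    stop_bandelet("momentum must lie in [0, 1)")
  if (restarts < 1L) stop_bandelet("restarts must be >= 1")
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 freeze_epochs = as.integer(freeze_epochs),
                 total_epochs = as.integer(total_epochs),
                 learning_rate = learning_rate, lr_decay = lr_decay,
                 momentum = momentum,
                 unfreeze_lr_factor = unfreeze_lr_factor,
                 lambda_mix = lambda_mix, batch_size = as.integer(batch_size),
                 restarts = as.integer(restarts),
                 source_weights = source_weights, source_data = source_data,
                 seed = as.integer(seed)),
            class = "training_config")
}

# architecture constants: channels per conv block, kernel 3x3, pad 1
.cnn_widths <- c(8L, 16L, 32L)

init_small_cnn <- function(in_channels = 4L, input_size = 32L) {
  cs <- c(in_channels, .cnn_widths)
  w <- list()
  for (l in 1:3) {
    fan_in <- 9L * cs[l]
    w[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * cs[l + 1],
                                               sd = sqrt(2 / fan_in)),
                                  fan_in, cs[l + 1])
    w[[paste0("b", l)]] <- numeric(cs[l + 1])
  }
  # dense head on the flattened final feature map (input_size / 8 per side)
  n_feat <- (input_size %/% 8L)^2 * .cnn_widths[3]
  w$Wd <- matrix(stats::rnorm(n_feat * 2, sd = sqrt(1 / n_feat)), n_feat, 2)
  w$bd <- numeric(2)
  w
}

## im2col index matrix for an S x S plane padded by 1: rows = output
## positions (column-major), columns = the 9 kernel offsets
.im2col_idx <- function(S) {
  P <- S + 2L
  pos_r <- rep(seq_len(S), times = S)   # row of output position
  pos_c <- rep(seq_len(S), each = S)
  idx <- matrix(0L, S * S, 9L)
  k <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    k <- k + 1L
    idx[, k] <- (pos_r + dr - 1L) + (pos_c + dc - 1L) * P + 1L
  }
  idx
}

## x: array (S, S, C, n) -> list(cols = (S*S*n) x 9C matrix, pad dims)
conv_im2col <- function(x, idx) {
  S <- dim(x)[1]; C <- dim(x)[3]; n <- dim(x)[4]
  P <- S + 2L
  xp <- array(0, c(P, P, C, n))
  xp[2:(S + 1L), 2:(S + 1L), , ] <- x
  xpv <- as.vector(xp)
  plane <- P * P
  img_off <- (seq_len(n) - 1L) * plane * C
  cols <- matrix(0, S * S * n, 9L * C)
  j <- 0L
  for (c in seq_len(C)) {
    ch_off <- (c - 1L) * plane
    for (k in 1:9) {
      j <- j + 1L
      cols[, j] <- xpv[as.vector(outer(idx[, k] + ch_off, img_off, `+`))]
    }
  }
  cols
}

## inverse scatter of conv_im2col for gradients
conv_col2im <- function(dcols, S, C, n, idx) {
  P <- S + 2L
  plane <- P * P
  img_off <- (seq_len(n) - 1L) * plane * C
  dxp <- numeric(plane * C * n)
  j <- 0L
  for (c in seq_len(C)) {
    ch_off <- (c - 1L) * plane
    for (k in 1:9) {
      j <- j + 1L
      ii <- as.vector(outer(idx[, k] + ch_off, img_off, `+`))
      dxp[ii] <- dxp[ii] + dcols[, j]
    }
  }
  dxp <- array(dxp, c(P, P, C, n))
  dxp[2:(S + 1L), 2:(S + 1L), , , drop = FALSE]
}

maxpool2 <- function(x) {
  S <- dim(x)[1]
  o <- seq(1L, S, by = 2L); e <- o + 1L
  a <- x[o, o, , , drop = FALSE]; b <- x[e, o, , , drop = FALSE]
  cc <- x[o, e, , , drop = FALSE]; d <- x[e, e, , , drop = FALSE]
  m <- pmax(a, b, cc, d)
  # first-max-wins masks for the backward pass
  ma <- a == m
  mb <- (b == m) & !ma
  mc <- (cc == m) & !(ma | mb)
  md <- !(ma | mb | mc)
  list(out = m, masks = list(ma, mb, mc, md))
}

maxpool2_back <- function(dm, masks, S) {
  C <- dim(dm)[3]; n <- dim(dm)[4]
  dx <- array(0, c(S, S, C, n))
  o <- seq(1L, S, by = 2L); e <- o + 1L
  dx[o, o, , ] <- dm * masks[[1]]
  dx[e, o, , ] <- dm * masks[[2]]
  dx[o, e, , ] <- dm * masks[[3]]
  dx[e, e, , ] <- dm * masks[[4]]
  dx
}

## forward pass; returns logits and, when `keep` is TRUE, the activations
## needed for backprop
cnn_forward <- function(x, w, idxs, keep = FALSE) {
  n <- dim(x)[4]
  act <- list(x = x)
  cur <- x
  for (l in 1:3) {
    S <- dim(cur)[1]
    cols <- conv_im2col(cur, idxs[[l]])
    z <- sweep(cols %*% w[[paste0("W", l)]], 2L, w[[paste0("b", l)]], `+`)
    relu_mask <- z > 0
    z <- z * relu_mask
    f <- array(aperm(array(z, c(S * S, n, ncol(z))), c(1L, 3L, 2L)),
               c(S, S, ncol(z), n))
    pl <- maxpool2(f)
    if (keep) {
      act[[paste0("cols", l)]] <- cols
      act[[paste0("relu", l)]] <- relu_mask
      act[[paste0("masks", l)]] <- pl$masks
      act[[paste0("S", l)]] <- S
    }
    cur <- pl$out
  }
  Sf <- dim(cur)[1]
  feats <- t(matrix(cur, ncol = n))          # n x (Sf*Sf*F) flattened map
  logits <- sweep(feats %*% w$Wd, 2L, w$bd, `+`)
  if (keep) { act$feats <- feats; act$Sf <- Sf }
  list(logits = logits, act = act)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

## cross-entropy loss and parameter gradients for one batch
cnn_batch_grad <- function(x, y, w, idxs) {
  n <- dim(x)[4]
  fw <- cnn_forward(x, w, idxs, keep = TRUE)
  p <- softmax_rows(fw$logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y + 1L)], 1e-12)))
  dlogit <- p
  dlogit[cbind(seq_len(n), y + 1L)] <- dlogit[cbind(seq_len(n), y + 1L)] - 1
  dlogit <- dlogit / n
  g <- list()
  g$Wd <- t(fw$act$feats) %*% dlogit
  g$bd <- colSums(dlogit)
  dfeat <- dlogit %*% t(w$Wd)                     # n x (Sf*Sf*F) flattened
  Sf <- fw$act$Sf
  dcur <- array(t(dfeat), c(Sf, Sf, .cnn_widths[3], n))
  for (l in 3:1) {
    S <- fw$act[[paste0("S", l)]]
    dpool <- maxpool2_back(dcur, fw$act[[paste0("masks", l)]], S)
    dz <- matrix(aperm(dpool, c(1L, 2L, 4L, 3L)), S * S * n, dim(dpool)[3])
    dz <- dz * fw$act[[paste0("relu", l)]]
    cols <- fw$act[[paste0("cols", l)]]
    g[[paste0("W", l)]] <- t(cols) %*% dz
    g[[paste0("b", l)]] <- colSums(dz)
    if (l > 1L) {
      dcols <- dz %*% t(w[[paste0("W", l)]])
      C_prev <- .cnn_widths[l - 1L]
      dcur <- conv_col2im(dcols, S, C_prev, n, idxs[[l]])
    }
  }
  list(loss = loss, grads = g, probs = p)
}

## downsample a bandelet tensor (4, ts, ts) to network input (S, S, 4)
tensor_to_input <- function(tensor, S) {
  out <- array(0, c(S, S, 4L))
  for (i in 1:4) out[, , i] <- resize_image(matrix(tensor[i, , ],
                                                   dim(tensor)[2], dim(tensor)[3]),
                                            c(S, S))
  out
}

stack_inputs <- function(tensors, S) {
  n <- length(tensors)
  x <- array(0, c(S, S, 4L, n))
  for (i in seq_len(n)) x[, , , i] <- tensor_to_input(tensors[[i]], S)
  x
}

#' Train the classifier on bandelet tensors
#'
#' Mini-batch gradient descent on the softmax cross-entropy with the update
#' rule theta <- theta - alpha * grad. For the first `freeze_epochs` the
#' convolutional base is frozen (bit-identical across steps) and only the
#' dense head trains; afterwards all parameters train at
#' `alpha * unfreeze_lr_factor`. With `lambda_mix > 0` and source data
#' supplied, each step descends the mixed objective
#' `lambda * L_S + (1 - lambda) * L_T`. Fully deterministic given
#' `config$seed`.
#'
#' @param train_x,val_x lists of `bandelet_tensor`s (4-channel).
#' @param train_y,val_y binary labels.
#' @param config a [training_config()].
#' @return Object of class `bandelet_cnn`: fitted weights, the config, and a
#'   per-epoch `history` data.frame (train/val loss and accuracy).
#' @export
train_classifier <- function(train_x, train_y, val_x = NULL, val_y = NULL,
                             config = training_config()) {
  if (!length(train_x)) stop_bandelet("empty training split")
  train_y <- as.integer(train_y)
  if (length(train_x) != length(train_y))
    stop_bandelet("train_x and train_y lengths differ")
  if (dim(train_x[[1]])[1] != 4L)
    stop_bandelet("expected 4-channel tensors")
  S <- config$input_size
  idxs <- list(.im2col_idx(S), .im2col_idx(S %/% 2L), .im2col_idx(S %/% 4L))
  x_all <- stack_inputs(train_x, S)
  has_val <- !is.null(val_x) && length(val_x) > 0L
  if (has_val) { xv <- stack_inputs(val_x, S); val_y <- as.integer(val_y) }
  use_src <- config$lambda_mix > 0 && !is.null(config$source_data)
  if (use_src) {
    xs_all <- stack_inputs(config$source_data$tensors, S)
    ys_all <- as.integer(config$source_data$labels)
  }
  n <- length(train_y)
  bs <- min(config$batch_size, n)
  conv_names <- c("W1", "b1", "W2", "b2", "W3", "b3")

  train_once <- function(run_seed) {
  history <- data.frame()
  w <- NULL
  with_seed(run_seed, {
    w <- if (!is.null(config$source_weights)) config$source_weights
         else init_small_cnn(4L, S)
    vel <- lapply(w, function(m) m * 0)
    for (epoch in seq_len(config$total_epochs)) {
      frozen <- epoch <= config$freeze_epochs
      lr <- config$learning_rate / (1 + config$lr_decay * (epoch - 1))
      if (!frozen && config$freeze_epochs > 0L)
        lr <- lr * config$unfreeze_lr_factor
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1L, n)]
        bg <- cnn_batch_grad(x_all[, , , ix, drop = FALSE], train_y[ix], w, idxs)
        grads <- bg$grads
        loss <- bg$loss
        if (use_src) {
          six <- sample.int(dim(xs_all)[4], min(bs, dim(xs_all)[4]))
          sg <- cnn_batch_grad(xs_all[, , , six, drop = FALSE], ys_all[six], w, idxs)
          lam <- config$lambda_mix
          loss <- lam * sg$loss + (1 - lam) * loss
          for (nm in names(grads))
            grads[[nm]] <- lam * sg$grads[[nm]] + (1 - lam) * grads[[nm]]
        }
        for (nm in names(grads)) {
          if (frozen && nm %in% conv_names) next
          if (config$momentum > 0) {
            vel[[nm]] <- config$momentum * vel[[nm]] + grads[[nm]]
            w[[nm]] <- w[[nm]] - lr * vel[[nm]]
          } else {
            w[[nm]] <- w[[nm]] - lr * grads[[nm]]
          }
        }
        ep_loss <- ep_loss + bg$loss * length(ix)
        ep_correct <- ep_correct + sum(max.col(bg$probs) - 1L == train_y[ix])
      }
      row <- data.frame(epoch = epoch, frozen = frozen,
                        train_loss = ep_loss / n, train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        fv <- cnn_forward(xv, w, idxs)
        pv <- softmax_rows(fv$logits)
        row$val_loss <- -mean(log(pmax(pv[cbind(seq_along(val_y), val_y + 1L)],
                                       1e-12)))
        row$val_acc <- mean(max.col(pv) - 1L == val_y)
      }
      history <- rbind(history, row)
    }
  })
  list(weights = w, history = history)
  }

  # multiple seeded restarts: keep the run with the lowest final TRAINING
  # loss (validation data never informs the choice)
  if (config$restarts == 1L) {
    best <- train_once(config$seed)
  } else {
    best <- NULL
    for (r in seq_len(config$restarts)) {
      cand <- train_once(derive_seed(config$seed, paste0("restart_", r)))
      if (is.null(best) ||
          utils::tail(cand$history$train_loss, 1) <
            utils::tail(best$history$train_loss, 1))
        best <- cand
    }
  }
  structure(list(weights = best$weights, config = config,
                 history = best$history, idxs = idxs, n_train = n),
            class = "bandelet_cnn")
}

#' Predict with a trained classifier
#'
#' @param object a `bandelet_cnn`.
#' @param tensors list of `bandelet_tensor`s.
#' @param type `"class"` (0/1 labels) or `"prob"` (malignant probability).
#' @param ... unused.
#' @return Integer labels or numeric probabilities.
#' @export
predict.bandelet_cnn <- function(object, tensors, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- stack_inputs(tensors, object$config$input_size)
  p <- softmax_rows(cnn_forward(x, object$weights, object$idxs)$logits)
  if (type == "prob") p[, 2] else max.col(p) - 1L
}

#' @export
print.bandelet_cnn <- function(x, ...) {
  h <- x$history
  cat("Small CNN classifier (4-channel bandelet tensors)\n")
  cat(sprintf("  input %dx%d, %d epochs (%d frozen), lr %g, trained on %d\n",
              x$config$input_size, x$config$input_size,
              x$config$total_epochs, x$config$freeze_epochs,
              x$config$learning_rate, x$n_train))
  last <- h[nrow(h), ]
  cat(sprintf("  final: train acc %.3f%s\n", last$train_acc,
              if (!is.na(last$val_acc))
                sprintf(", val acc %.3f", last$val_acc) else ""))
  invisible(x)
}

## mixed transfer objective; the lambda endpoints reduce to the pure source
## (1) and pure target (0) losses
mixed_loss <- function(loss_source, loss_target, lambda_mix) {
  if (lambda_mix < 0 || lambda_mix > 1)
    stop_bandelet("lambda_mix must lie in [0, 1]")
  lambda_mix * loss_source + (1 - lambda_mix) * loss_target
}
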