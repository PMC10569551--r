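#' Training configuration
#'
#' Training minimises the binary focal loss with Adam, monitors the
#' validation loss after every epoch and stops early once no improvement
#' larger than `min_delta` has been seen for `patience` consecutive epochs,
#' restoring the best-validation weights.
#'
#' @param max_epochs epoch budget (default 100).
#' @param patience consecutive non-improving epochs tolerated (default 30).
#' @param min_delta minimal validation-loss improvement that counts (1e-4).
#' @param learning_rate Adam learning rate (1e-4).
#' @param gamma focal-loss focusing exponent (2).
#' @param split_ratio training fraction of the patch-level split (0.8).
#' @param batch_size patches per optimisation step (16).
#' @param augment_copies augmented copies of each training patch added per
#'   epoch to enlarge the training set (3; 0 disables augmentation).
#' @param seed master RNG seed controlling split, augmentation and shuffling.
#' @return a `vs_train_config`.
#' @export
train_config <- function(max_epochs = 100L, patience = 30L, min_delta = 1e-4,
                         learning_rate = 1e-4, gamma = 2, split_ratio = 0.8,
                         batch_size = 16L, augment_copies = 3L, seed = 1L) {
  stopifnot(split_ratio > 0, split_ratio < 1, gamma >= 0,
            patience <= max_epochs, batch_size >= 1)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 learning_rate = learning_rate, gamma = gamma,
                 split_ratio = split_ratio, batch_size = as.integer(batch_size),
                 augment_copies = as.integer(augment_copies),
                 seed = as.integer(seed)),
            class = "vs_train_config")
}

#' Augmentation configuration
#'
#' Each transform is applied independently with `apply_prob`: a flip along
#' the x axis, a flip along the y axis (both flips applied identically to the
#' label patch), a single scalar brightness shift drawn from
#' `Normal(0, brightness_sigma)`, and voxelwise noise from
#' `Normal(0, noise_sigma)`; the image is re-clipped to `[0, 1]`.
#'
#' @param brightness_sigma brightness shift scale (0.1).
#' @param noise_sigma voxel noise scale (0.05).
#' @param apply_prob per-transform application probability (0.5).
#' @return a `vs_augment_config`.
#' @export
augment_config <- function(brightness_sigma = 0.1, noise_sigma = 0.05,
                           apply_prob = 0.5) {
  stopifnot(brightness_sigma >= 0, noise_sigma >= 0,
            apply_prob >= 0, apply_prob <= 1)
  structure(list(brightness_sigma = brightness_sigma,
                 noise_sigma = noise_sigma, apply_prob = apply_prob),
            class = "vs_augment_config")
}

#' Augment one labelled patch
#'
#' @param image normalised image patch (rank-3 array in `[0, 1]`).
#' @param label binary label patch of identical shape.
#' @param config an [augment_config()].
#' @return `list(image, label)`; the label stays binary (only flips touch it).
#' @export
augment <- function(image, label, config = augment_config()) {
  if (!identical(dim(image), dim(label))) stop("image and label shapes differ")
  p <- config$apply_prob
  flips <- runif(2) < p   # x axis, y axis
  if (flips[1]) { image <- flip_axis(image, 3L); label <- flip_axis(label, 3L) }
  if (flips[2]) { image <- flip_axis(image, 2L); label <- flip_axis(label, 2L) }
  if (runif(1) < p) image <- image + rnorm(1, sd = config$brightness_sigma)
  if (runif(1) < p) image <- image + rnorm(length(image), sd = config$noise_sigma)
  image <- pmin(pmax(image, 0), 1)
  list(image = image, label = label)
}

flip_axis <- function(x, axis) {
  idx <- rev(seq_len(dim(x)[axis]))
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

#' Binary focal loss
#'
#' Mean over voxels of `-[y (1-p)^g log p + (1-y) p^g log(1-p)]` with no
#' class-balancing weight; `gamma = 0` recovers binary cross-entropy.
#' Predictions are clipped to `[eps, 1-eps]`.
#'
#' @param pred probabilities.
#' @param target binary targets of identical shape.
#' @param gamma focusing exponent `>= 0`.
#' @param eps clipping epsilon.
#' @param grad also return the gradient with respect to `pred`.
#' @return the scalar loss, or `list(loss, grad)` when `grad = TRUE`.
#' @export
focal_loss <- function(pred, target, gamma = 2, eps = 1e-7, grad = FALSE) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (length(pred) != length(target)) stop("pred and target shapes differ")
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- target
  loss <- mean(-(y * (1 - p)^gamma * log(p) + (1 - y) * p^gamma * log1p(-p)))
  if (!grad) return(loss)
  n <- length(p)
  g1 <- if (gamma == 0) -1 / p else
    gamma * (1 - p)^(gamma - 1) * log(p) - (1 - p)^gamma / p
  g0 <- if (gamma == 0) 1 / (1 - p) else
    -gamma * p^(gamma - 1) * log1p(-p) + p^gamma / (1 - p)
  g <- (y * g1 + (1 - y) * g0) / n
  dim(g) <- dim(pred)
  list(loss = loss, grad = g)
}

#' Split labelled patches into training and validation sets
#'
#' Uniformly random, disjoint and exhaustive split at patch level; the
#' training set holds `round(ratio * n)` patches. The validation partition is
#' the early-stopping monitor.
#'
#' @param patches list of labelled patches.
#' @param ratio training fraction.
#' @param seed RNG seed.
#' @return `list(train, val)` of index-preserving sublists.
#' @export
split_patches <- function(patches, ratio = 0.8, seed = 1L) {
  n <- length(patches)
  if (n < 5L) stop("need at least 5 patches to split, got ", n)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- floor(ratio * n + 0.5)
  list(train = patches[sort(idx[seq_len(n_train)])],
       val = patches[sort(idx[-seq_len(n_train)])])
}

## ---- Adam ---------------------------------------------------------------

adam_init <- function(grads) rapply(grads, function(g) list(m = g * 0, v = g * 0),
                                    how = "list", classes = "ANY")

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (layer in names(grads)) {
    for (nm in names(grads[[layer]])) {
      g <- grads[[layer]][[nm]]
      st <- state[[layer]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[layer]][[nm]] <- params[[layer]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[layer]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

## ---- training loop ------------------------------------------------------

#' Train the network
#'
#' Adam minimisation of the focal loss over minibatches of patches, with the
#' per-epoch dataset enlarged by augmented copies. After every epoch the
#' validation loss is recorded (evaluation-mode forward pass); training stops
#' at `max_epochs` or when `patience` consecutive epochs bring no improvement
#' greater than `min_delta`, and the best-validation weights (together with
#' their batch-norm running statistics) are restored, so inference is
#' deterministic.
#'
#' @param model a `vs_unet`.
#' @param train list of `list(image, label)` training patches.
#' @param val list of `list(image, label)` validation patches.
#' @param config a [train_config()].
#' @param augment_cfg an [augment_config()].
#' @param verbose print per-epoch losses.
#' @return the trained `vs_unet`, with a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`) attached.
#' @export
train_model <- function(model, train, val, config = train_config(),
                        augment_cfg = augment_config(), verbose = FALSE) {
  if (!length(train) || !length(val)) stop("empty training or validation set")
  block <- dim(train[[1]]$image)[1]
  d <- dim(train[[1]]$image)
  V <- prod(d)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  adam <- NULL
  t_step <- 0L
  best <- Inf; best_params <- model$params; best_bn <- model$bn_state
  wait <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    samples <- train
    if (config$augment_copies > 0)
      for (r in seq_len(config$augment_copies))
        samples <- c(samples, lapply(train, function(s)
          augment(s$image, s$label, augment_cfg)))
    samples <- samples[sample.int(length(samples))]
    epoch_loss <- 0; nb <- 0L
    for (start in seq(1L, length(samples), by = config$batch_size)) {
      idx <- start:min(start + config$batch_size - 1L, length(samples))
      x <- array(0, c(V, 1L, length(idx)))
      y <- array(0, c(V, 1L, length(idx)))
      for (j in seq_along(idx)) {
        x[, 1L, j] <- samples[[idx[j]]]$image
        y[, 1L, j] <- samples[[idx[j]]]$label
      }
      fw <- unet_forward(model, x, d, training = TRUE, keep_cache = TRUE)
      model$bn_state <- fw$bn_state
      fl <- focal_loss(fw$prob, y, config$gamma, grad = TRUE)
      if (!is.finite(fl$loss))
        stop("training diverged to non-finite loss at epoch ", epoch)
      grads <- unet_backward(model, fw$cache, fl$grad)
      if (is.null(adam)) adam <- adam_init(grads)
      t_step <- t_step + 1L
      upd <- adam_step(model$params, grads, adam, config$learning_rate, t_step)
      model$params <- upd$params
      adam <- upd$state
      epoch_loss <- epoch_loss + fl$loss; nb <- nb + 1L
    }
    val_loss <- eval_loss(model, val, d, config$gamma)
    history[[epoch]] <- c(epoch = epoch, train_loss = epoch_loss / nb,
                          val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      epoch_loss / nb, val_loss))
    if (val_loss < best - config$min_delta) {
      best <- val_loss
      best_params <- model$params
      best_bn <- model$bn_state
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  model$bn_state <- best_bn
  model$history <- tibble::as_tibble(do.call(rbind, history))
  model
}

eval_loss <- function(model, patches, d, gamma, batch_size = 8L) {
  V <- prod(d)
  total <- 0; n <- 0L
  for (start in seq(1L, length(patches), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(patches))
    x <- array(0, c(V, 1L, length(idx)))
    y <- array(0, c(V, 1L, length(idx)))
    for (j in seq_along(idx)) {
      x[, 1L, j] <- patches[[idx[j]]]$image
      y[, 1L, j] <- patches[[idx[j]]]$label
    }
    fw <- unet_forward(model, x, d, training = FALSE)
    total <- total + focal_loss(fw$prob, y, gamma) * length(idx)
    n <- n + length(idx)
  }
  total / n
}

# Early-stopping decision sequence on an injected validation-loss history;
# returns the 1-based stopping epoch and the best epoch.
#' Simulate early stopping on a validation-loss sequence
#'
#' Pure decision logic used by [train_model()]: an epoch improves when its
#' loss is below the best so far by more than `min_delta`; after `patience`
#' consecutive non-improving epochs training stops.
#'
#' @param losses numeric vector of per-epoch validation losses.
#' @param patience,min_delta as in [train_config()].
#' @return `list(stop_epoch, best_epoch)` (1-based; `stop_epoch` is the last
#'   epoch run).
#' @export
early_stop_epoch <- function(losses, patience = 30L, min_delta = 1e-4) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best - min_delta) {
      best <- losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(stop_epoch = e, best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(losses), best_epoch = best_epoch)
}
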