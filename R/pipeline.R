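#' Patchify a label mask with an existing geometry
#'
#' Applies the crop/pad/patchify part of the pre-processing chain (no blur,
#' no normalisation -- labels are binary) so label patches align exactly with
#' the image patches produced by [preprocess_stack()].
#'
#' @param gt a `vs_mask` in the original stack frame.
#' @param geometry the `vs_geometry` of the matching image patch set.
#' @return a `vs_patchset` of binary patches.
#' @export
patchify_labels <- function(gt, geometry) {
  lo <- geometry$bbox_low; hi <- geometry$bbox_high
  sub <- bare(unclass(gt))[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2],
                           (lo[3] + 1L):hi[3], drop = FALSE]
  block <- geometry$block
  target <- ceiling(dim(sub) / block) * block
  out <- array(0L, target)
  out[seq_len(dim(sub)[1]), seq_len(dim(sub)[2]), seq_len(dim(sub)[3])] <- sub
  patchify(as_volume(out * 1.0, "float"), geometry, block)
}

#' Build labelled training patches from a stack
#'
#' @param volume raw intensity `vs_volume` (or a `vs_phantom`).
#' @param mask brain `vs_mask`.
#' @param gt vessel ground-truth `vs_mask`.
#' @param config a [preprocess_config()].
#' @param tag stack provenance tag attached to every patch.
#' @return list of `list(image, label, stack)` patches.
#' @export
labelled_patches <- function(volume, mask = NULL, gt = NULL,
                             config = preprocess_config(), tag = NA) {
  if (inherits(volume, "vs_phantom")) {
    mask <- volume$brain_mask; gt <- volume$vessel_gt
    volume <- volume$intensity
  }
  ps <- preprocess_stack(volume, mask, config)
  ls <- patchify_labels(gt, ps$geometry)
  lapply(seq_along(ps$patches), function(i)
    list(image = ps$patches[[i]], label = ls$patches[[i]], stack = tag))
}

#' Segment a stack with a trained network
#'
#' Full route: pre-processing, patch-wise inference, reassembly of the
#' probability map into the original frame, and post-processing.
#'
#' @param model a trained `vs_unet`.
#' @param volume raw `vs_volume`.
#' @param mask brain `vs_mask`.
#' @param preprocess a [preprocess_config()].
#' @param postprocess a [postprocess_config()].
#' @return `list(segmentation = vs_mask, probabilities = vs_volume)` in the
#'   original stack frame.
#' @export
segment_stack <- function(model, volume, mask,
                          preprocess = preprocess_config(),
                          postprocess = postprocess_config()) {
  ps <- preprocess_stack(volume, mask, preprocess)
  pred <- predict_patches(model, ps)
  if (postprocess$scope == "per_patch") {
    seg <- apply_postprocess(pred, postprocess)
    prob <- reassemble(pred)
  } else {
    prob <- reassemble(pred)
    seg <- apply_postprocess(prob, postprocess)
  }
  list(segmentation = seg, probabilities = prob)
}

#' Leave-one-out cross-validation over a set of stacks
#'
#' For every fold, the network is trained from scratch on the labelled
#' patches of all other stacks (with the 80/20 patch-level split internal to
#' those stacks serving as the early-stopping monitor), the held-out stack is
#' predicted, every post-processing setting of the grid is applied, and the
#' metrics against the ground truth are computed within the brain mask.
#' Training sets never contain any patch of the held-out stack.
#'
#' @param stacks list of stacks; each element is a `vs_phantom` or a
#'   `list(volume/intensity, brain_mask, vessel_gt)`.
#' @param train_cfg a [train_config()].
#' @param preprocess_cfg a [preprocess_config()].
#' @param post_grid list of [postprocess_config()] settings to evaluate.
#' @param unet_cfg a [unet_config()].
#' @param verbose print fold progress.
#' @return a `vs_loocv`: `list(per_fold = tibble, average = tibble)`; the
#'   per-fold table has one row per fold x setting.
#' @export
run_loocv <- function(stacks, train_cfg = train_config(),
                      preprocess_cfg = preprocess_config(),
                      post_grid = list(postprocess_config(t = 0.45)),
                      unet_cfg = unet_reference_config(),
                      verbose = FALSE) {
  n <- length(stacks)
  if (n < 2L) stop("leave-one-out needs at least 2 stacks")
  get_parts <- function(s) {
    if (inherits(s, "vs_phantom"))
      list(volume = s$intensity, mask = s$brain_mask, gt = s$vessel_gt)
    else list(volume = s$volume %||% s$intensity, mask = s$brain_mask,
              gt = s$vessel_gt)
  }
  rows <- list()
  for (fold in seq_len(n)) {
    if (verbose) message("fold ", fold, " / ", n)
    pool <- list()
    for (j in setdiff(seq_len(n), fold)) {
      p <- get_parts(stacks[[j]])
      pool <- c(pool, labelled_patches(p$volume, p$mask, p$gt,
                                       preprocess_cfg, tag = j))
    }
    stopifnot(!any(vapply(pool, function(s) identical(s$stack, fold), logical(1))))
    sp <- split_patches(pool, train_cfg$split_ratio,
                        seed = train_cfg$seed + fold)
    model <- build_unet(unet_cfg, seed = train_cfg$seed + 1000L + fold)
    model <- train_model(model, sp$train, sp$val, train_cfg,
                         verbose = verbose)
    held <- get_parts(stacks[[fold]])
    ps <- preprocess_stack(held$volume, held$mask, preprocess_cfg)
    prob <- reassemble(predict_patches(model, ps))
    for (pc in post_grid) {
      seg <- apply_postprocess(prob, pc)
      met <- compute_metrics(confusion_counts(seg, held$gt, held$mask))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = fold, mode = pc$mode, t = pc$t, s = pc$s %||% NA_real_, met)
    }
  }
  per_fold <- do.call(rbind, rows)
  settings <- unique(per_fold[, c("mode", "t", "s")])
  avg <- do.call(rbind, lapply(seq_len(nrow(settings)), function(i) {
    sel <- per_fold$mode == settings$mode[i] & per_fold$t == settings$t[i] &
      (is.na(settings$s[i]) | per_fold$s %in% settings$s[i])
    cbind(settings[i, ],
          aggregate_metrics(per_fold[sel, c("accuracy", "recall",
                                            "precision", "dsc")]))
  }))
  structure(list(per_fold = per_fold, average = tibble::as_tibble(avg)),
            class = "vs_loocv")
}

#' @export
print.vs_loocv <- function(x, ...) {
  cat("<vs_loocv> averages across", length(unique(x$per_fold$fold)), "folds:\n")
  print(x$average)
  invisible(x)
}
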