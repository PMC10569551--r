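#' Vesselness (Frangi) baseline configuration
#'
#' Multiscale Hessian tube-likelihood: at each scale the volume is smoothed
#' with a Gaussian of that scale, scale-normalised second derivatives form
#' the Hessian, and the eigenvalue ratios score how tube-like (versus
#' plate-like or blob-like) the local structure is; the response is the
#' maximum over scales. Vessels are dark on bright tissue here, so the dark
#' polarity (positive transverse eigenvalues) is the default.
#'
#' @param scales Gaussian scales in voxels.
#' @param alpha plate/line discrimination parameter.
#' @param beta blob suppression parameter.
#' @param c_mode `"half_max_frobenius"`: the structureness parameter `c` is
#'   half the maximum Frobenius norm of the Hessian at each scale.
#' @param dark_ridges detect dark tubes (TRUE) or bright tubes.
#' @param threshold per-stack binarization threshold in `(0, 1)`; the
#'   reference protocol selects it per stack within `[0.02, 0.03]`.
#' @return a `vs_vesselness_config`.
#' @export
vesselness_config <- function(scales = c(0.5, 1, 1.5, 2), alpha = 0.5,
                              beta = 0.5, c_mode = "half_max_frobenius",
                              dark_ridges = TRUE, threshold = 0.02) {
  stopifnot(length(scales) >= 1, all(scales > 0),
            threshold > 0, threshold < 1)
  structure(list(scales = scales, alpha = alpha, beta = beta, c_mode = c_mode,
                 dark_ridges = isTRUE(dark_ridges), threshold = threshold),
            class = "vs_vesselness_config")
}

# shift with reflected (edge-repeating) boundaries along one axis
shift_reflect <- function(x, axis, by) {
  n <- dim(x)[axis]
  idx <- seq_len(n) + by
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
         x[, , idx, drop = FALSE])
}

# scale-normalised Hessian components of a smoothed volume (gamma = 2)
hessian_components <- function(g, sigma) {
  d2 <- function(axis)
    shift_reflect(g, axis, 1L) - 2 * g + shift_reflect(g, axis, -1L)
  dcross <- function(a1, a2) {
    (shift_reflect(shift_reflect(g, a1, 1L), a2, 1L) -
     shift_reflect(shift_reflect(g, a1, 1L), a2, -1L) -
     shift_reflect(shift_reflect(g, a1, -1L), a2, 1L) +
     shift_reflect(shift_reflect(g, a1, -1L), a2, -1L)) / 4
  }
  s2 <- sigma^2
  list(hzz = s2 * d2(1L), hyy = s2 * d2(2L), hxx = s2 * d2(3L),
       hzy = s2 * dcross(1L, 2L), hzx = s2 * dcross(1L, 3L),
       hyx = s2 * dcross(2L, 3L))
}

#' Multiscale Frangi vesselness response
#'
#' @param volume a normalised `vs_volume` (values in `[0, 1]`).
#' @param config a [vesselness_config()].
#' @return a float `vs_volume` of vesselness in `[0, 1]`.
#' @export
frangi_response <- function(volume, config = vesselness_config()) {
  if (!length(config$scales)) stop("no scales given")
  x <- bare(unclass(volume))
  best <- array(0, dim(x))
  for (sigma in config$scales) {
    g <- bare(unclass(gaussian_smooth(as_volume(x, "float"), sigma)))
    h <- hessian_components(g, sigma)
    frob <- sqrt(h$hzz^2 + h$hyy^2 + h$hxx^2 +
                 2 * (h$hzy^2 + h$hzx^2 + h$hyx^2))
    cpar <- max(frob) / 2
    if (cpar == 0) next
    resp <- frangi_from_hessian_cpp(h$hzz, h$hyy, h$hxx, h$hzy, h$hzx, h$hyx,
                                    config$alpha, config$beta, cpar,
                                    config$dark_ridges)
    dim(resp) <- dim(x)
    best <- pmax(best, resp)
  }
  as_volume(best, "float")
}

#' Vesselness-based segmentation of a stack
#'
#' Identical pre-processing to the network route -- ROI extraction, padding,
#' Gaussian smoothing, min-max normalisation -- except that the patch
#' separation is not needed: the vesselness response is thresholded directly,
#' mapped back to the original stack frame and restricted to the brain mask.
#'
#' @param volume raw `vs_volume`.
#' @param mask brain `vs_mask`.
#' @param config a [vesselness_config()].
#' @param preprocess a [preprocess_config()].
#' @return a `vs_mask` segmentation in the original stack frame.
#' @export
vesselness_segment <- function(volume, mask, config = vesselness_config(),
                               preprocess = preprocess_config()) {
  roi <- extract_roi(volume, mask)
  padded <- pad_to_block(roi$volume, roi$geometry, preprocess$block)
  normed <- minmax_normalize(gaussian_smooth(padded$volume,
                                             preprocess$blur_sigma))
  resp <- frangi_response(normed, config)
  seg_padded <- bare(unclass(resp)) >= config$threshold
  geom <- padded$geometry
  roi_len <- geom$bbox_high - geom$bbox_low
  out <- array(0L, geom$original_shape)
  out[geom$bbox_low[1] + seq_len(roi_len[1]),
      geom$bbox_low[2] + seq_len(roi_len[2]),
      geom$bbox_low[3] + seq_len(roi_len[3])] <-
    seg_padded[seq_len(roi_len[1]), seq_len(roi_len[2]), seq_len(roi_len[3])]
  as_mask(out * bare(unclass(mask)))
}
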