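#' Post-processing configuration
#'
#' Two ways to binarize the reassembled probability map: a plain threshold at
#' `t`, or seeded region growing that thresholds the most confident voxels at
#' `s` as seeds and grows them through connected neighbours with probability
#' `>= t`. `scope` selects whether post-processing runs on the reassembled
#' full volume (default; vessels may cross patch seams) or inside each patch
#' before reassembly.
#'
#' @param mode `"threshold"` or `"region_growing"`.
#' @param t binarization / growth threshold in `(0, 1]`.
#' @param s seed threshold (region growing only), `t <= s <= 1`.
#' @param connectivity 6 (face neighbours, default) or 26.
#' @param scope `"full_volume"` or `"per_patch"`.
#' @return a `vs_postprocess_config`.
#' @export
postprocess_config <- function(mode = c("threshold", "region_growing"),
                               t = 0.45, s = NULL, connectivity = 6L,
                               scope = c("full_volume", "per_patch")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  stopifnot(t > 0, t <= 1, connectivity %in% c(6L, 26L))
  if (mode == "region_growing") {
    if (is.null(s)) stop("region growing requires a seed threshold s")
    if (t > s || s > 1) stop("need 0 < t <= s <= 1")
  }
  structure(list(mode = mode, t = t, s = s,
                 connectivity = as.integer(connectivity), scope = scope),
            class = "vs_postprocess_config")
}

#' Threshold a probability volume
#'
#' A voxel is foreground iff its probability is `>= t` (inclusive, so region
#' growing with `s = t` degenerates exactly to thresholding).
#'
#' @param prob probability `vs_volume` (values in `[0, 1]`) or bare array.
#' @param t threshold in `(0, 1]`.
#' @return a `vs_mask` segmentation.
#' @export
threshold_mask <- function(prob, t) {
  if (t <= 0 || t > 1) stop("threshold t must lie in (0, 1]")
  as_mask((bare(unclass(prob)) >= t) * 1L)
}

#' Seeded region growing
#'
#' Seeds are the voxels with probability `>= s`; the result is the union of
#' the connected components of `{p >= t}` that contain at least one seed
#' (breadth-first growth from all seeds through neighbours with `p >= t`).
#' Satisfies the sandwich property `{p >= s}` subset of result subset of
#' `{p >= t}`.
#'
#' @param prob probability `vs_volume` or array.
#' @param s seed threshold.
#' @param t growth threshold, `t <= s`.
#' @param connectivity 6 or 26.
#' @return a `vs_mask` segmentation.
#' @export
region_grow <- function(prob, s, t, connectivity = 6L) {
  if (t > s) stop("growth threshold t must not exceed seed threshold s")
  x <- bare(unclass(prob))
  as_mask(region_grow_cpp(x, dim(x), s, t, as.integer(connectivity)))
}

#' Apply post-processing to predictions
#'
#' Under `full_volume` scope the probability patches are tiled back into the
#' padded ROI frame and the binarization runs once over the whole frame
#' (growth can cross patch seams), after which the result is mapped into the
#' original stack frame; under `per_patch` scope each patch is binarized
#' independently (growth cannot cross patch seams) before reassembly. The
#' full-volume result is always a superset of the per-patch result for
#' identical parameters.
#'
#' @param prob_patches a `vs_patchset` of probability patches, or (for
#'   `full_volume` only) an already reassembled probability `vs_volume`.
#' @param config a [postprocess_config()].
#' @return a `vs_mask` segmentation in the original stack frame.
#' @export
apply_postprocess <- function(prob_patches, config) {
  binarize <- function(p) switch(config$mode,
    threshold = threshold_mask(p, config$t),
    region_growing = region_grow(p, config$s, config$t, config$connectivity))
  if (inherits(prob_patches, "vs_volume"))
    return(binarize(prob_patches))
  geom <- prob_patches$geometry
  if (config$scope == "full_volume") {
    padded <- tile_patches(prob_patches)
    seg <- bare(unclass(binarize(padded)))
    return(as_mask(strip_and_place(seg, geom)))
  }
  out <- prob_patches
  out$patches <- lapply(prob_patches$patches, function(p)
    bare(unclass(binarize(p))) + 0)
  as_mask(strip_and_place(tile_patches(out), geom))
}
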