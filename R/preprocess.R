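#' Pre-processing configuration
#'
#' The pipeline applies, in fixed order: ROI extraction by the brain mask,
#' padding to a block multiple, Gaussian smoothing, per-stack min-max
#' normalisation, and separation into cubic patches.
#'
#' @param blur_sigma Gaussian standard deviation in voxels (default 0.5).
#' @param block patch edge length in voxels (default 32; must be >= 8).
#' @return a `vs_preprocess_config` list.
#' @export
preprocess_config <- function(blur_sigma = 0.5, block = 32L) {
  stopifnot(blur_sigma >= 0, block >= 8, block == as.integer(block))
  structure(list(blur_sigma = blur_sigma, block = as.integer(block)),
            class = "vs_preprocess_config")
}

#' Extract the brain region of interest
#'
#' Crops the axis-aligned bounding box of the mask's nonzero voxels and zeroes
#' voxels inside the box but outside the mask, restricting all later stages to
#' the brain itself. Offsets in the returned geometry are 0-based with
#' half-open intervals, so `bbox_low = c(2,2,2)`, `bbox_high = c(5,5,5)`
#' describes R indices `3:5` on each axis.
#'
#' @param volume a `vs_volume`.
#' @param mask a `vs_mask` of identical shape with at least one nonzero voxel.
#' @return `list(volume = cropped vs_volume, geometry = vs_geometry)`.
#' @export
extract_roi <- function(volume, mask) {
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask shapes differ")
  if (sum(mask) == 0L) stop("empty brain mask")
  m <- bare(unclass(mask))
  sz <- rowSums(m)                      # per-z foreground
  myx <- colSums(m)                     # (y, x) sums over z
  sy <- rowSums(myx)
  sx <- colSums(myx)
  rng <- function(s) range(which(s > 0))
  rz <- rng(sz); ry <- rng(sy); rx <- rng(sx)
  sub <- bare(unclass(volume))[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
  sub <- sub * m[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
  geometry <- structure(list(
    original_shape = dim(volume),
    bbox_low  = c(rz[1], ry[1], rx[1]) - 1L,
    bbox_high = c(rz[2], ry[2], rx[2]),
    pad = c(0L, 0L, 0L),
    block = NA_integer_
  ), class = "vs_geometry")
  list(volume = as_volume(sub, volume_dtype(volume)), geometry = geometry)
}

#' Pad a cropped ROI to the next block multiple
#'
#' Each axis is zero-padded at the high-index end to the smallest multiple of
#' `block` that is >= the current length (a no-op for axes already divisible,
#' e.g. 320 with block 32; 400 becomes 416). Idempotent.
#'
#' @param roi cropped `vs_volume` from [extract_roi()].
#' @param geometry the matching `vs_geometry`; its `pad` field is updated.
#' @param block patch edge length.
#' @return `list(volume, geometry)`.
#' @export
pad_to_block <- function(roi, geometry, block = 32L) {
  stopifnot(block >= 1)
  d <- dim(roi)
  target <- ceiling(d / block) * block
  pad <- as.integer(target - d)
  out <- array(0, target)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- bare(unclass(roi))
  geometry$pad <- geometry$pad + pad
  geometry$block <- as.integer(block)
  list(volume = as_volume(out, volume_dtype(roi)), geometry = geometry)
}

#' Isotropic Gaussian smoothing
#'
#' Separable Gaussian filtering along the three axes with reflected (edge
#' repeating) boundary handling; `sigma = 0` returns the input unchanged. The
#' discrete kernel is sampled at integer offsets within `4*sigma` and
#' normalised to unit sum.
#'
#' @param volume a `vs_volume`.
#' @param sigma standard deviation in voxels, `>= 0`.
#' @return a float `vs_volume`.
#' @export
gaussian_smooth <- function(volume, sigma = 0.5) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(volume)
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  x <- bare(unclass(volume))
  for (axis in 1:3) x <- smooth_axis(x, axis, k, off)
  as_volume(x, "float")
}

smooth_axis <- function(x, axis, k, off) {
  n <- dim(x)[axis]
  out <- array(0, dim(x))
  for (i in seq_along(off)) {
    idx <- seq_len(n) + off[i]
    idx <- ifelse(idx < 1L, 1L - idx, idx)        # reflect at low edge
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx) # reflect at high edge
    out <- out + k[i] * switch(axis,
      x[idx, , , drop = FALSE],
      x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE])
  }
  out
}

#' Per-stack min-max normalisation
#'
#' Maps intensities affinely to `[0, 1]` using the minimum and maximum over
#' the whole (padded) ROI, which neutralises per-stack brightness runaways.
#' A constant volume maps to all zeros.
#'
#' @param volume a `vs_volume`.
#' @return a float `vs_volume` with values in `[0, 1]`.
#' @export
minmax_normalize <- function(volume) {
  x <- bare(unclass(volume))
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(as_volume(array(0, dim(x)), "float"))
  as_volume((x - lo) / (hi - lo), "float")
}

#' Separate a volume into cubic patches
#'
#' Non-overlapping tiling into `block^3` patches, ordered lexicographically in
#' `(z, y, x)` grid coordinates (x fastest). Every axis length must be a
#' multiple of `block`.
#'
#' @param volume padded `vs_volume`.
#' @param geometry matching `vs_geometry` (from [pad_to_block()]).
#' @param block patch edge length.
#' @return a `vs_patchset`: list of patches plus `grid_shape` and `geometry`.
#' @export
patchify <- function(volume, geometry, block = 32L) {
  d <- dim(volume)
  if (any(d %% block != 0))
    stop("axis lengths ", paste(d, collapse = "x"),
         " are not multiples of block ", block)
  grid <- d %/% block
  x <- bare(unclass(volume))
  patches <- vector("list", prod(grid))
  i <- 0L
  for (gz in seq_len(grid[1])) for (gy in seq_len(grid[2])) for (gx in seq_len(grid[3])) {
    i <- i + 1L
    patches[[i]] <- x[(gz - 1L) * block + seq_len(block),
                      (gy - 1L) * block + seq_len(block),
                      (gx - 1L) * block + seq_len(block), drop = FALSE]
  }
  geometry$block <- as.integer(block)
  structure(list(patches = patches, grid_shape = grid,
                 block = as.integer(block), geometry = geometry),
            class = "vs_patchset")
}

#' Reassemble patches into the original stack frame
#'
#' Exact inverse of the pre-processing geometry: patches are tiled back in
#' their grid order, the block padding is stripped, and the ROI is placed at
#' its bounding-box offset inside a zero background of the original shape.
#' `reassemble(patchify(v, g))` restores `v` bit-exactly on its domain.
#'
#' @param patchset a `vs_patchset`.
#' @return a `vs_volume` of the original stack shape.
#' @export
reassemble <- function(patchset) {
  as_volume(strip_and_place(tile_patches(patchset), patchset$geometry),
            "float")
}

# tile patches back into the padded ROI frame
tile_patches <- function(patchset) {
  grid <- patchset$grid_shape
  block <- patchset$block
  if (length(patchset$patches) != prod(grid))
    stop("patch count ", length(patchset$patches),
         " does not match grid ", paste(grid, collapse = "x"))
  padded <- array(0, grid * block)
  i <- 0L
  for (gz in seq_len(grid[1])) for (gy in seq_len(grid[2])) for (gx in seq_len(grid[3])) {
    i <- i + 1L
    p <- patchset$patches[[i]]
    if (length(dim(p)) != 3L || any(dim(p) != block))
      stop("patch ", i, " has wrong shape")
    padded[(gz - 1L) * block + seq_len(block),
           (gy - 1L) * block + seq_len(block),
           (gx - 1L) * block + seq_len(block)] <- p
  }
  padded
}

# strip the block padding and place the ROI at its offset in the original frame
strip_and_place <- function(padded, geom) {
  roi_len <- geom$bbox_high - geom$bbox_low
  roi <- padded[seq_len(roi_len[1]), seq_len(roi_len[2]), seq_len(roi_len[3]),
                drop = FALSE]
  out <- array(0, geom$original_shape)
  out[geom$bbox_low[1] + seq_len(roi_len[1]),
      geom$bbox_low[2] + seq_len(roi_len[2]),
      geom$bbox_low[3] + seq_len(roi_len[3])] <- roi
  out
}

#' Run the full pre-processing chain
#'
#' [extract_roi()] then [pad_to_block()] then [gaussian_smooth()] then
#' [minmax_normalize()] then [patchify()], in that fixed order.
#'
#' @param volume raw `vs_volume`.
#' @param mask brain `vs_mask`.
#' @param config a [preprocess_config()].
#' @return a `vs_patchset` of normalised patches.
#' @export
preprocess_stack <- function(volume, mask, config = preprocess_config()) {
  roi <- extract_roi(volume, mask)
  padded <- pad_to_block(roi$volume, roi$geometry, config$block)
  smoothed <- gaussian_smooth(padded$volume, config$blur_sigma)
  normed <- minmax_normalize(smoothed)
  patchify(normed, padded$geometry, config$block)
}

#' Serialise / read ROI geometry sidecars
#'
#' Geometry is written to a JSON sidecar so predictions can be mapped back to
#' the original stack frame without re-reading the brain mask.
#'
#' @param geometry a `vs_geometry`.
#' @param path JSON file path.
#' @return `read_geometry()` returns a `vs_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(unclass(geometry), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  g$original_shape <- as.integer(g$original_shape)
  g$bbox_low <- as.integer(g$bbox_low)
  g$bbox_high <- as.integer(g$bbox_high)
  g$pad <- as.integer(g$pad)
  g$block <- as.integer(g$block)
  structure(g, class = "vs_geometry")
}
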