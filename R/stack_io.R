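#' Read a 3D image stack or binary mask
#'
#' Supports multi-page TIFF (`.tif`/`.tiff`, uint16 or float32) and NIfTI-1
#' (`.nii`/`.nii.gz`). The in-memory canonical axis order is `(z, y, x)`:
#' TIFF pages map to `z`; NIfTI volumes stored `(x, y, z)` on disk are
#' permuted on load. Axis order and integer payloads round-trip exactly
#' through [save_stack()].
#'
#' @param path file to read.
#' @param expect `"intensity"` for a [as_volume()] volume or `"mask"` for a
#'   binary [as_mask()] mask; mask loading binarizes any nonzero voxel to 1.
#' @return a `vs_volume` or `vs_mask`.
#' @examples
#' p <- tempfile(fileext = ".tif")
#' v <- as_volume(array(sample(0:65535, 64, TRUE), c(4, 4, 4)), "uint16")
#' save_stack(v, p)
#' identical(unclass(load_stack(p))[], unclass(v)[])
#' @export
load_stack <- function(path, expect = c("intensity", "mask")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- stack_format(path)
  if (fmt == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("not a rank-3 grayscale stack: ", path)
    bits <- attr(pages[[1]], "bits.per.sample") %||% 16L
    float <- bits >= 32L
    if (float)  # 32-bit pages hold float samples; take the rescaled [0,1] read
      pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(length(pages), d[1], d[2]))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  } else {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
      stop("not a rank-3 volume: ", path, " (rank ", length(dim(img)), ")")
    arr <- aperm(as.array(img), c(3, 2, 1))   # (x,y,z) on disk -> (z,y,x)
    float <- any(arr %% 1 != 0) || min(arr) < 0
  }
  if (expect == "mask") return(as_mask(arr))
  if (float) as_volume(arr, "float") else as_volume(arr, "uint16")
}

#' Write a 3D volume or mask
#'
#' Integer (`uint16`) volumes and masks are written losslessly; float volumes
#' in `[0, 1]` are written as 32-bit float TIFF or float NIfTI and round-trip
#' within single precision (`1e-6`).
#'
#' @param volume a `vs_volume` or `vs_mask`.
#' @param path destination; format chosen from the extension
#'   (`.tif`/`.tiff` vs `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_stack <- function(volume, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  fmt <- stack_format(path)
  arr <- bare(unclass(volume))
  is_mask <- inherits(volume, "vs_mask")
  dtype <- if (is_mask) "uint8" else volume_dtype(volume)
  if (fmt == "tiff") {
    d <- dim(arr)
    pages <- vector("list", d[1])
    for (i in seq_len(d[1])) {
      page <- matrix(arr[i, , ], d[2], d[3])
      pages[[i]] <- switch(dtype,
        uint8  = page / 255,
        uint16 = page / 65535,
        float  = page)
    }
    bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float = 32L)
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = bits), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write ", path, ": ", ok)
  } else {
    disk <- aperm(arr, c(3, 2, 1))   # (z,y,x) -> (x,y,z) on disk
    datatype <- switch(dtype, uint8 = "uint8", uint16 = "uint16", float = "float")
    ok <- try(RNifti::writeNifti(disk, path, datatype = datatype), silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write ", path, ": ", ok)
  }
  invisible(path)
}

stack_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop("unsupported stack format (use .tif/.tiff or .nii/.nii.gz): ", path)
}
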