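#' 3D volumes and binary masks
#'
#' A `vs_volume` is a rank-3 numeric array in `(z, y, x)` order -- `z` is the
#' slice ("layer") index of the stack -- carrying a dtype tag: `"uint16"` for
#' raw stacks with intensities in `[0, 65535]`, or `"float"` for blurred,
#' normalised or probability volumes. A `vs_mask` is the binary counterpart
#' with values in `{0, 1}`, stored as integers.
#'
#' @param data rank-3 numeric array in `(z, y, x)` order.
#' @param dtype `"uint16"` or `"float"`.
#' @return `as_volume()` returns a `vs_volume`; `as_mask()` a `vs_mask`.
#' @examples
#' v <- as_volume(array(0:7, c(2, 2, 2)), "uint16")
#' m <- as_mask(array(c(0, 1), c(2, 2, 2)))
#' @export
as_volume <- function(data, dtype = c("float", "uint16")) {
  dtype <- match.arg(dtype)
  if (length(dim(data)) != 3L)
    stop("volume must be a rank-3 array, got rank ", length(dim(data)))
  if (dtype == "uint16") {
    if (any(data < 0 | data > 65535))
      stop("uint16 volume values must lie in [0, 65535]")
    storage.mode(data) <- "double"
  }
  structure(data, class = c("vs_volume", "array"), dtype = dtype)
}

#' @rdname as_volume
#' @export
as_mask <- function(data) {
  if (length(dim(data)) != 3L)
    stop("mask must be a rank-3 array, got rank ", length(dim(data)))
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1))) {
    if (length(setdiff(vals, c(0, 1))) > 0 && length(vals) > 2L)
      warning("mask contains values other than {0, 1}; binarizing nonzero voxels")
    data <- (data != 0) * 1L
  }
  storage.mode(data) <- "integer"
  structure(data, class = c("vs_mask", "array"))
}

#' @export
print.vs_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vs_volume %s> %d x %d x %d (z,y,x), range [%g, %g]\n",
              attr(x, "dtype"), d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

#' @export
print.vs_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vs_mask> %d x %d x %d (z,y,x), %d foreground voxels (%.4f%%)\n",
              d[1], d[2], d[3], sum(x), 100 * mean(x)))
  invisible(x)
}

volume_dtype <- function(x) attr(x, "dtype") %||% "float"

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip volume/mask class, keep bare array
bare <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
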