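#' Plot training history
#'
#' Training and validation focal loss per epoch.
#'
#' @param object a trained `vs_unet` (with a `history` tibble).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vs_unet <- function(object, ...) {
  if (is.null(object$history)) stop("model has no training history")
  h <- object$history
  df <- rbind(data.frame(epoch = h$epoch, loss = h$train_loss, set = "train"),
              data.frame(epoch = h$epoch, loss = h$val_loss, set = "validation"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "focal loss", colour = NULL)
}

#' Plot a stack slice with optional overlays
#'
#' Base-graphics viewer for one axial slice (`z` layer) of a volume, with
#' optional mask contours drawn on top, mirroring the usual layer-wise way
#' these stacks are inspected.
#'
#' @param volume a `vs_volume`.
#' @param z slice index (default: middle slice).
#' @param mask optional `vs_mask` drawn as an overlay.
#' @param main plot title.
#' @return invisibly, the slice matrix.
#' @export
plot_slice <- function(volume, z = NULL, mask = NULL, main = NULL) {
  d <- dim(volume)
  if (is.null(z)) z <- ceiling(d[1] / 2)
  sl <- matrix(bare(unclass(volume))[z, , ], d[2], d[3])
  graphics::image(t(sl)[, rev(seq_len(d[2]))], col = grey.colors(256),
                  axes = FALSE, asp = d[2] / d[3],
                  main = main %||% paste0("layer z = ", z))
  if (!is.null(mask)) {
    ms <- matrix(bare(unclass(mask))[z, , ], d[2], d[3])
    if (any(ms > 0))
      graphics::contour(t(ms)[, rev(seq_len(d[2]))], levels = 0.5,
                        add = TRUE, drawlabels = FALSE, col = "red")
  }
  invisible(sl)
}

#' @importFrom grDevices grey.colors
NULL
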