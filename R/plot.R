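# ggplot2 visualization helpers. Volumes are shown as single z-slices
# (axial); detection overlays mark component centroids.

slice_df <- function(volume, z) {
  d <- dim(volume)
  if (is.null(z)) z <- ceiling(d[3] / 2)
  sl <- volume[, , z]
  tibble::tibble(
    x = rep(seq_len(d[1]) - 1L, times = d[2]),
    y = rep(seq_len(d[2]) - 1L, each = d[1]),
    intensity = as.vector(sl),
    z = z - 1L
  )
}

#' Plot one z-slice of a volume
#'
#' @param volume Numeric 3D array.
#' @param z 1-based slice index; defaults to the middle slice.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL) {
  df <- slice_df(volume, z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (voxels)", y = "y (voxels)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.phantom <- function(object, z = NULL, centers = TRUE, ...) {
  p <- plot_slice(object$image, z)
  if (centers) {
    zz <- if (is.null(z)) ceiling(dim(object$image)[3] / 2) else z
    near <- object$blobs[abs(object$blobs$z - (zz - 1)) <= 1.5, , drop = FALSE]
    if (nrow(near) > 0) {
      p <- p + ggplot2::geom_point(
        data = near,
        ggplot2::aes(x = .data$x, y = .data$y),
        inherit.aes = FALSE, color = "red", shape = 3, size = 1
      )
    }
  }
  p + ggplot2::ggtitle(sprintf("phantom slice (%d blobs total)", object$n_blobs))
}

#' @export
autoplot.blob_detection <- function(object, z = NULL, ...) {
  p <- plot_slice(1 - object$mask, z)
  zz <- if (is.null(z)) ceiling(dim(object$mask)[3] / 2) else z
  near <- object$blobs[abs(object$blobs$z - (zz - 1)) <= 1.5, , drop = FALSE]
  if (nrow(near) > 0) {
    p <- p + ggplot2::geom_point(
      data = near, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, color = "red", shape = 1, size = 2
    )
  }
  p + ggplot2::ggtitle(sprintf("identification mask (%d blobs)", object$n_detected))
}

#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- tidy.metrics_report(object)
  df <- df[!is.na(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, max(1, max(df$value))) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.blob_translator <- function(object, ...) {
  h <- object$history
  long <- tibble::tibble(
    epoch = rep(h$epoch, 6),
    loss = rep(c("gan", "nce_in", "nce_ic", "convex", "kld", "total"),
      each = nrow(h)
    ),
    value = c(h$gan, h$nce_in, h$nce_ic, h$convex, h$kld, h$total)
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value,
    color = .data$loss
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss (epoch mean)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
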