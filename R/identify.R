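#' Threshold a translated volume into a blob mask
#'
#' Dark-object convention: a voxel is foreground when its intensity is below
#' the threshold.
#'
#' @param volume Numeric 3D array in `[0, 1]` (typically a translated,
#'   denoised volume).
#' @param threshold Intensity threshold in `(0, 1)`; default 0.5.
#' @param dark Foreground is darker than the threshold (default); set
#'   `FALSE` for bright objects.
#' @return Integer 0/1 array.
#' @export
blob_mask <- function(volume, threshold = 0.5, dark = TRUE) {
  assert_volume(volume)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  out <- array(0L, dim(volume))
  if (dark) out[volume < threshold] <- 1L else out[volume > threshold] <- 1L
  out
}

#' Intersect the convexity mask with the blob mask
#'
#' The final identification mask is the Hadamard (voxelwise) product of the
#' Hessian convexity mask and the translated blob mask, so a voxel survives
#' only if it is both locally peak-like and dark in the translation.
#'
#' @param convexity Integer/logical 0/1 array (see [convexity_mask()]).
#' @param blobs Integer/logical 0/1 array (see [blob_mask()]).
#' @return Integer 0/1 array.
#' @export
joint_mask <- function(convexity, blobs) {
  assert_same_shape(convexity, blobs)
  out <- array(0L, dim(convexity))
  out[convexity != 0 & blobs != 0] <- 1L
  out
}

#' Label connected components of a binary mask
#'
#' Maximal connected foreground components under 26-connectivity (voxels
#' sharing a face, edge or corner; the default) or 6-connectivity (faces
#' only). Labels are deterministic: components are numbered by the raster
#' order of their first voxel.
#'
#' @param mask Integer/logical 3D array.
#' @param connectivity 26 or 6.
#' @return Integer label array (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  assert_volume(mask * 1)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26", call. = FALSE)
  m <- array(as.integer(mask != 0), dim(mask))
  .label3d(m, as.integer(connectivity))
}

#' Extract blobs from a binary identification mask
#'
#' Labels 26-connected components, computes per-component voxel counts and
#' centroids (arithmetic mean of 0-based voxel coordinates), optionally
#' attaches a per-blob blobness score, and filters out components smaller
#' than `min_size` voxels (single-voxel components are treated as residual
#' noise by default).
#'
#' @param mask Integer/logical 3D array (the final identification mask).
#' @param connectivity 26 (default) or 6.
#' @param volume Optional source volume used for per-blob blobness (scored on
#'   the inverted image, see [blobness_volume()]).
#' @param min_size Minimum component size in voxels kept (default 2).
#' @return An object of class `"blob_detection"`: list with `mask` (the mask
#'   after size filtering), `labels` (integer label array), `blobs` (tibble:
#'   `label, n_voxels, x, y, z, blobness`) and `n_detected`.
#' @export
connected_components <- function(mask, connectivity = 26, volume = NULL,
                                 min_size = 2L) {
  labels <- label_components(mask, connectivity)
  fg <- which(labels > 0L)
  bl <- if (!is.null(volume)) blobness_volume(volume, invert = TRUE) else NULL
  if (length(fg) == 0) {
    blobs <- tibble::tibble(
      label = integer(), n_voxels = integer(),
      x = numeric(), y = numeric(), z = numeric(), blobness = numeric()
    )
    return(structure(
      list(
        mask = array(0L, dim(labels)), labels = labels, blobs = blobs,
        n_detected = 0L, connectivity = connectivity, min_size = min_size
      ),
      class = "blob_detection"
    ))
  }
  lab <- labels[fg]
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_size)
  coords <- linear_to_coords(fg, dim(labels))
  cx <- rowsum(coords[, "x"], lab)[, 1] / sizes[sort(unique(lab))]
  cy <- rowsum(coords[, "y"], lab)[, 1] / sizes[sort(unique(lab))]
  cz <- rowsum(coords[, "z"], lab)[, 1] / sizes[sort(unique(lab))]
  present <- sort(unique(lab))
  blobness <- rep(NA_real_, length(present))
  if (!is.null(bl)) {
    blobness <- vapply(present, function(lb) {
      v <- fg[lab == lb]
      vals <- bl$blobness[v]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, 0)
  }
  tab <- tibble::tibble(
    label = present, n_voxels = sizes[present],
    x = cx, y = cy, z = cz, blobness = blobness
  )
  tab <- tab[tab$n_voxels >= min_size, , drop = FALSE]
  # relabel kept components consecutively, preserving raster order
  out_labels <- array(0L, dim(labels))
  new_mask <- array(0L, dim(labels))
  if (nrow(tab) > 0) {
    remap <- integer(max(present))
    remap[tab$label] <- seq_len(nrow(tab))
    sel <- fg[lab %in% tab$label]
    out_labels[sel] <- remap[labels[sel]]
    new_mask[sel] <- 1L
    tab$label <- seq_len(nrow(tab))
  }
  structure(
    list(
      mask = new_mask, labels = out_labels, blobs = tab,
      n_detected = nrow(tab), connectivity = connectivity, min_size = min_size
    ),
    class = "blob_detection"
  )
}

#' @export
print.blob_detection <- function(x, ...) {
  cat(sprintf(
    "<blob_detection> %d blobs (%d-connectivity, min size %d voxels)\n",
    x$n_detected, x$connectivity, x$min_size
  ))
  invisible(x)
}

#' @export
tidy.blob_detection <- function(x, ...) x$blobs

#' @export
glance.blob_detection <- function(x, ...) {
  tibble::tibble(
    n_detected = x$n_detected,
    n_foreground = sum(x$mask),
    mean_blobness = mean(x$blobs$blobness, na.rm = TRUE),
    connectivity = x$connectivity,
    min_size = x$min_size
  )
}

#' End-to-end blob detection on a noisy volume
#'
#' Composes the full identification pipeline: Hessian convexity mask of the
#' (inverted) input, translation to the clean domain, blob mask of the
#' translation, Hadamard intersection, and 26-connected component extraction.
#'
#' @param volume Noisy input volume, intensities in `[0, 1]`.
#' @param model A trained translation model ([train_translator()]), or `NULL` to
#'   use `translate_fn`.
#' @param translate_fn Translation function `volume -> volume`; defaults to
#'   [translate()] with `model`, or the identity when `model` is `NULL`
#'   (Hessian + raw-intensity baseline).
#' @param threshold Blob-mask threshold on the translated volume.
#' @param invert Convexity factor uses the inverted input `1 - volume`
#'   (dark-blob convention, default).
#' @param connectivity 26 (default) or 6.
#' @param min_size Minimum component size in voxels.
#' @return A `"blob_detection"` object; the translated volume is attached as
#'   attribute `translated`.
#' @export
detect <- function(volume, model = NULL, translate_fn = NULL,
                   threshold = 0.5, invert = TRUE, connectivity = 26,
                   min_size = 2L) {
  assert_volume(volume)
  if (is.null(translate_fn)) {
    translate_fn <- if (is.null(model)) identity else function(v) translate(model, v)
  }
  conv <- convexity_mask(volume, invert = invert)
  translated <- translate_fn(volume)
  assert_same_shape(volume, translated)
  bm <- blob_mask(translated, threshold = threshold, dark = TRUE)
  final <- joint_mask(conv, bm)
  det <- connected_components(final,
    connectivity = connectivity,
    volume = volume, min_size = min_size
  )
  attr(det, "translated") <- translated
  attr(det, "convexity_mask") <- conv
  attr(det, "blob_mask") <- bm
  det
}
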