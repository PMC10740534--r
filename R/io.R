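# Volume and table I/O. NIfTI is the canonical interchange format; multi-page
# TIFF is supported for microscopy-style fixtures. Arrays are (nx, ny, nz);
# TIFF pages are z-slices with rows = y and columns = x.

#' Read a 3D volume from NIfTI or TIFF
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.tif` or `.tiff` file.
#' @return Numeric 3D array `(nx, ny, nz)`; intensities as stored, no
#'   implicit normalization.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- RNifti::readNifti(path)
    arr <- array(as.numeric(vol), dim(vol))
    if (length(dim(arr)) != 3) stop("not a 3D volume: ", path, call. = FALSE)
    return(arr)
  }
  if (grepl("\\.tiff?$", lower)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    first <- pages[[1]]
    if (length(dim(first)) != 2) stop("expected single-channel TIFF pages: ", path, call. = FALSE)
    arr <- array(0, c(ncol(first), nrow(first), nz))
    for (k in seq_len(nz)) arr[, , k] <- t(pages[[k]])
    return(arr)
  }
  stop("unrecognized volume format: ", path, call. = FALSE)
}

#' Write a 3D volume to NIfTI or TIFF
#'
#' @param volume Numeric 3D array.
#' @param path Output path; format chosen by extension.
#' @param dtype Storage type: `"float"` (32-bit float, images), `"uint8"`
#'   (masks) or `"int32"` (label volumes; NIfTI only).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, dtype = c("float", "uint8", "int32")) {
  dtype <- match.arg(dtype)
  assert_volume(volume)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    datatype <- switch(dtype, float = "float", uint8 = "uint8", int32 = "int")
    RNifti::writeNifti(RNifti::asNifti(volume, datatype = datatype), path)
    return(invisible(path))
  }
  if (grepl("\\.tiff?$", lower)) {
    if (dtype == "int32") {
      stop("int32 label volumes are only supported in NIfTI", call. = FALSE)
    }
    bps <- if (dtype == "uint8") 8L else 32L
    pages <- lapply(seq_len(dim(volume)[3]), function(k) t(volume[, , k]))
    tiff::writeTIFF(pages, path,
      bits.per.sample = bps,
      reduce = FALSE
    )
    return(invisible(path))
  }
  stop("unrecognized volume format: ", path, call. = FALSE)
}

#' Write a blob-center table as CSV
#'
#' One row per blob with columns `id, z, y, x, theta, phi, sigma_x, sigma_y,
#' sigma_z` (coordinates 0-based, voxel frame).
#'
#' @param blobs Tibble as in `phantom$blobs`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_blob_table <- function(blobs, path) {
  out <- data.frame(
    id = blobs$id, z = blobs$z, y = blobs$y, x = blobs$x,
    theta = blobs$theta, phi = blobs$phi,
    sigma_x = blobs$sigma_x, sigma_y = blobs$sigma_y, sigma_z = blobs$sigma_z
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a blob-center table written by [write_blob_table()]
#'
#' @param path CSV path.
#' @return A tibble with the stored columns.
#' @export
read_blob_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(read.csv(path))
}
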