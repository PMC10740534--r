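#' Quadratic-form coefficients of a 3D elliptical Gaussian blob
#'
#' A 3D blob is modeled as \eqn{F(x,y,z) = A e^{-(a x^2 + b y^2 + c z^2 +
#' d xy + e yz + f xz)}}. The six coefficients are controlled by two
#' orientation angles \eqn{\theta, \varphi} (radians, spherical convention)
#' and the three axis scales \eqn{\sigma_x, \sigma_y, \sigma_z} (voxels):
#' \deqn{a = \sin^2\theta\cos^2\varphi/\sigma_x^2 +
#'           \sin^2\theta\sin^2\varphi/\sigma_y^2 + \cos^2\theta/\sigma_z^2}
#' \deqn{b = \cos^2\theta\cos^2\varphi/\sigma_x^2 +
#'           \cos^2\theta\sin^2\varphi/\sigma_y^2 + \sin^2\theta/\sigma_z^2}
#' \deqn{c = \sin^2\varphi/\sigma_x^2 + \cos^2\varphi/\sigma_y^2}
#' \deqn{d = \sin 2\theta\cos^2\varphi/\sigma_x^2 +
#'           \sin 2\theta\sin^2\varphi/\sigma_y^2 - \sin 2\theta/\sigma_z^2}
#' \deqn{e = -\cos\theta\sin 2\varphi/\sigma_x^2 +
#'            \cos\theta\sin 2\varphi/\sigma_y^2}
#' \deqn{f = -\sin\theta\sin 2\varphi/\sigma_x^2 +
#'            \sin\theta\sin 2\varphi/\sigma_y^2}
#' For equal scales \eqn{\sigma} all angular terms cancel and the form reduces
#' to the isotropic \eqn{a=b=c=1/\sigma^2}, \eqn{d=e=f=0}.
#'
#' Not every parameter combination yields a positive-definite quadratic form;
#' use [is_positive_definite()] (as [compose_phantom()] does) to reject
#' degenerate draws.
#'
#' @param theta,phi Orientation angles in radians.
#' @param sigma_x,sigma_y,sigma_z Axis scales in voxels; must be positive.
#' @return A named list with elements `a`..`f` of class `"quad_coefficients"`.
#' @seealso [coefficient_matrix()], [render_blob()]
#' @export
#' @examples
#' gaussian_coefficients(0, 0, 1, 1, 1)
gaussian_coefficients <- function(theta, phi, sigma_x, sigma_y, sigma_z) {
  if (any(c(sigma_x, sigma_y, sigma_z) <= 0)) {
    stop("all sigma values must be positive", call. = FALSE)
  }
  sx2 <- sigma_x^2
  sy2 <- sigma_y^2
  sz2 <- sigma_z^2
  st2 <- sin(theta)^2
  ct2 <- cos(theta)^2
  sp2 <- sin(phi)^2
  cp2 <- cos(phi)^2
  s2t <- sin(2 * theta)
  s2p <- sin(2 * phi)
  out <- list(
    a = st2 * cp2 / sx2 + st2 * sp2 / sy2 + ct2 / sz2,
    b = ct2 * cp2 / sx2 + ct2 * sp2 / sy2 + st2 / sz2,
    c = sp2 / sx2 + cp2 / sy2,
    d = s2t * cp2 / sx2 + s2t * sp2 / sy2 - s2t / sz2,
    e = -cos(theta) * s2p / sx2 + cos(theta) * s2p / sy2,
    f = -sin(theta) * s2p / sx2 + sin(theta) * s2p / sy2
  )
  class(out) <- "quad_coefficients"
  out
}

#' Symmetric matrix of a blob quadratic form
#'
#' @param coefs A `"quad_coefficients"` object (or named list with `a`..`f`).
#' @return The symmetric 3x3 matrix
#'   `[[a, d/2, f/2], [d/2, b, e/2], [f/2, e/2, c]]`.
#' @export
coefficient_matrix <- function(coefs) {
  with(coefs, matrix(
    c(
      a, d / 2, f / 2,
      d / 2, b, e / 2,
      f / 2, e / 2, c
    ),
    nrow = 3, byrow = TRUE
  ))
}

#' Test positive definiteness of a blob quadratic form
#'
#' @param coefs A `"quad_coefficients"` object.
#' @param tol Smallest admissible eigenvalue.
#' @return `TRUE` if all eigenvalues of [coefficient_matrix()] exceed `tol`.
#' @export
is_positive_definite <- function(coefs, tol = 1e-10) {
  ev <- eigen(coefficient_matrix(coefs), symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

#' Construct a blob specification
#'
#' Bundles the parameters of one synthetic blob: continuous center
#' coordinates (0-based, `(x, y, z)` voxel frame), orientation angles, axis
#' scales and peak amplitude.
#'
#' @param center Numeric length-3 vector `(x, y, z)`, 0-based voxel frame.
#' @param theta,phi Orientation angles in radians.
#' @param sigma Numeric length-3 vector of axis scales (voxels), all positive.
#' @param amplitude Peak value `A` (> 0); the rendered blob equals `A` at its
#'   center.
#' @param check Reject non-positive-definite quadratic forms (default `TRUE`).
#' @return A list of class `"blob_spec"`.
#' @export
blob_spec <- function(center, theta = 0, phi = 0, sigma = c(1, 1, 1),
                      amplitude = 1, check = TRUE) {
  stopifnot(length(center) == 3, length(sigma) == 3)
  if (any(sigma <= 0)) stop("all sigma values must be positive", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  coefs <- gaussian_coefficients(theta, phi, sigma[1], sigma[2], sigma[3])
  if (check && !is_positive_definite(coefs)) {
    stop("blob quadratic form is not positive definite", call. = FALSE)
  }
  structure(
    list(
      center = as.numeric(center), theta = theta, phi = phi,
      sigma = as.numeric(sigma), amplitude = amplitude, coefs = coefs
    ),
    class = "blob_spec"
  )
}

# Evaluate a blob over explicit 0-based coordinate grids (vectors per axis).
eval_blob_grid <- function(spec, xs, ys, zs) {
  co <- spec$coefs
  dx <- xs - spec$center[1]
  dy <- ys - spec$center[2]
  dz <- zs - spec$center[3]
  nx <- length(dx)
  ny <- length(dy)
  nz <- length(dz)
  ii <- rep.int(dx, ny * nz)
  jj <- rep.int(rep(dy, each = nx), nz)
  kk <- rep(dz, each = nx * ny)
  expo <- co$a * ii^2 + co$b * jj^2 + co$c * kk^2 +
    co$d * ii * jj + co$e * jj * kk + co$f * ii * kk
  array(spec$amplitude * exp(-expo), dim = c(nx, ny, nz))
}

#' Render a single blob into a volume
#'
#' Evaluates the blob's elliptical Gaussian at every voxel of a volume of the
#' given shape. Voxel `[i, j, k]` (1-based R indexing) sits at 0-based
#' coordinate `(i-1, j-1, k-1)`.
#'
#' @param spec A [blob_spec()].
#' @param shape Integer length-3 `(nx, ny, nz)`.
#' @return A numeric 3D array with the blob's intensity field (peak `A` at the
#'   center when the center is on-grid).
#' @export
render_blob <- function(spec, shape) {
  stopifnot(inherits(spec, "blob_spec"), length(shape) == 3, all(shape >= 1))
  if (!is_positive_definite(spec$coefs)) {
    stop("blob quadratic form is not positive definite", call. = FALSE)
  }
  eval_blob_grid(spec, seq_len(shape[1]) - 1, seq_len(shape[2]) - 1, seq_len(shape[3]) - 1)
}

# Support radius such that the blob value drops below A * exp(-r_cut) outside.
blob_support_radius <- function(spec, exponent_cut = 16) {
  lam_min <- min(eigen(coefficient_matrix(spec$coefs),
    symmetric = TRUE, only.values = TRUE
  )$values)
  ceiling(sqrt(exponent_cut / lam_min))
}

#' Synthesize a clean 3D blob phantom
#'
#' Draws a random number of blobs, places them uniformly in the volume (with a
#' margin), draws orientations uniformly in `[0, 2*pi)` and per-axis scales
#' uniformly in `sigma_range`, rejects draws whose quadratic form is not
#' positive definite, and composes the blob field. The image is inverted so
#' blobs are dark on a bright background (`image = 1 - field`, intensities in
#' `[0, 1]`). Each blob's ground-truth mask is the set of voxels where its own
#' Gaussian is at least `amplitude * exp(-1)` (the unit-quadratic-form
#' ellipsoid), plus the grid voxel nearest its center so every recorded blob
#' owns at least one voxel.
#'
#' @param shape Volume shape `(nx, ny, nz)`; default `c(64, 64, 32)`.
#' @param n_blobs_range Inclusive integer range for the blob count; default
#'   `c(500, 800)`.
#' @param sigma_range Range for per-axis scale draws (voxels); default
#'   `c(0.5, 1.5)`.
#' @param amplitude Peak amplitude of every blob on the normalized scale.
#' @param seed Integer seed; the phantom is a pure function of its arguments.
#' @param composite `"max"` (voxelwise maximum, default) or `"sum"`
#'   (sum then clip at 1) for overlapping blobs.
#' @param mask_cutoff Relative intensity cutoff defining each blob's mask.
#' @param margin Margin (voxels) kept between blob centers and the volume
#'   faces.
#' @param max_retries Bound on positive-definiteness redraws per blob.
#' @return An object of class `"phantom"`: list with `image` (clean volume),
#'   `mask` (0/1 integer array, union of per-blob masks), `blobs` (tibble of
#'   blob parameters), `blob_voxels` (list of linear voxel indices per blob),
#'   and the generation settings.
#' @export
compose_phantom <- function(shape = c(64, 64, 32),
                            n_blobs_range = c(500, 800),
                            sigma_range = c(0.5, 1.5),
                            amplitude = 1,
                            seed = NULL,
                            composite = c("max", "sum"),
                            mask_cutoff = exp(-1),
                            margin = 1,
                            max_retries = 100L) {
  composite <- match.arg(composite)
  stopifnot(
    length(shape) == 3, all(shape >= 3),
    n_blobs_range[1] >= 1, n_blobs_range[1] <= n_blobs_range[2],
    sigma_range[1] > 0, sigma_range[1] <= sigma_range[2]
  )
  if (any(shape - 2 * margin <= 1)) {
    stop("volume too small for the requested margin", call. = FALSE)
  }
  with_seed(seed, {
    n_choices <- seq.int(n_blobs_range[1], n_blobs_range[2])
    n_blobs <- if (length(n_choices) == 1L) n_choices else sample(n_choices, 1L)
    field <- array(0, shape)
    mask <- array(0L, shape)
    blob_voxels <- vector("list", n_blobs)
    specs <- vector("list", n_blobs)
    for (b in seq_len(n_blobs)) {
      spec <- NULL
      for (try in seq_len(max_retries)) {
        center <- c(
          runif(1, margin, shape[1] - 1 - margin),
          runif(1, margin, shape[2] - 1 - margin),
          runif(1, margin, shape[3] - 1 - margin)
        )
        cand <- blob_spec(
          center = center,
          theta = runif(1, 0, 2 * pi), phi = runif(1, 0, 2 * pi),
          sigma = runif(3, sigma_range[1], sigma_range[2]),
          amplitude = amplitude, check = FALSE
        )
        if (is_positive_definite(cand$coefs)) {
          spec <- cand
          break
        }
      }
      if (is.null(spec)) {
        stop("failed to draw a positive-definite blob after bounded retries",
          call. = FALSE
        )
      }
      specs[[b]] <- spec
      r <- blob_support_radius(spec)
      xs <- max(1L, floor(spec$center[1] + 1 - r)):min(shape[1], ceiling(spec$center[1] + 1 + r))
      ys <- max(1L, floor(spec$center[2] + 1 - r)):min(shape[2], ceiling(spec$center[2] + 1 + r))
      zs <- max(1L, floor(spec$center[3] + 1 - r)):min(shape[3], ceiling(spec$center[3] + 1 + r))
      vals <- eval_blob_grid(spec, xs - 1, ys - 1, zs - 1)
      if (composite == "max") {
        field[xs, ys, zs] <- pmax(field[xs, ys, zs], vals)
      } else {
        field[xs, ys, zs] <- field[xs, ys, zs] + vals
      }
      # per-blob ground-truth mask: own-Gaussian cutoff + nearest grid voxel
      sel <- which(vals >= amplitude * mask_cutoff)
      grid_idx <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
      lin <- grid_idx[sel, 1] + shape[1] * (grid_idx[sel, 2] - 1) +
        shape[1] * shape[2] * (grid_idx[sel, 3] - 1)
      nearest <- pmin(pmax(round(spec$center) + 1, 1), shape)
      lin <- unique(c(
        lin,
        nearest[1] + shape[1] * (nearest[2] - 1) + shape[1] * shape[2] * (nearest[3] - 1)
      ))
      blob_voxels[[b]] <- as.integer(sort(lin))
      mask[blob_voxels[[b]]] <- 1L
    }
    if (composite == "sum") field <- pmin(field, 1)
    image <- 1 - pmin(field, 1)
    blobs <- tibble::tibble(
      id = seq_len(n_blobs),
      x = vapply(specs, function(s) s$center[1], 0),
      y = vapply(specs, function(s) s$center[2], 0),
      z = vapply(specs, function(s) s$center[3], 0),
      theta = vapply(specs, function(s) s$theta, 0),
      phi = vapply(specs, function(s) s$phi, 0),
      sigma_x = vapply(specs, function(s) s$sigma[1], 0),
      sigma_y = vapply(specs, function(s) s$sigma[2], 0),
      sigma_z = vapply(specs, function(s) s$sigma[3], 0),
      amplitude = amplitude
    )
    structure(
      list(
        image = image, mask = mask, blobs = blobs, blob_voxels = blob_voxels,
        seed = seed, composite = composite, mask_cutoff = mask_cutoff,
        sigma_range = sigma_range, n_blobs = n_blobs
      ),
      class = "phantom"
    )
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s voxels, %d blobs (composite = %s, seed = %s)\n",
    paste(dim(x$image), collapse = "x"), x$n_blobs, x$composite,
    if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}

#' @export
tidy.phantom <- function(x, ...) x$blobs

#' @export
glance.phantom <- function(x, ...) {
  tibble::tibble(
    n_blobs = x$n_blobs,
    n_mask_voxels = sum(x$mask),
    mean_sigma = mean(unlist(x$blobs[, c("sigma_x", "sigma_y", "sigma_z")])),
    composite = x$composite
  )
}

#' Add calibrated Gaussian noise to a clean volume
#'
#' Draws a signal-to-noise ratio uniformly in `snr_db` (decibels) and adds
#' zero-mean Gaussian noise with variance
#' \eqn{\sigma^2_{noise} = \sigma^2_{image} / 10^{SNR/10}}, where
#' \eqn{\sigma^2_{image}} is the sample variance of the clean volume. The
#' result is clipped to `[0, 1]` (disable with `clip = FALSE`); the pre-clip
#' volume and drawn parameters are attached as attributes for calibration
#' checks.
#'
#' @param image Clean numeric 3D array.
#' @param snr_db Length-2 range (dB), `0 < min <= max`; default
#'   `c(0.01, 1)`. A length-1 value fixes the SNR.
#' @param seed Integer seed for reproducible noise.
#' @param clip Clip the noisy volume to `[0, 1]`.
#' @return The noisy volume with attributes `snr_db`, `sigma_noise` and
#'   `preclip` (the unclipped noisy volume).
#' @export
add_noise <- function(image, snr_db = c(0.01, 1), seed = NULL, clip = TRUE) {
  assert_volume(image)
  if (length(snr_db) == 1) snr_db <- c(snr_db, snr_db)
  stopifnot(snr_db[1] > 0, snr_db[1] <= snr_db[2])
  s2 <- var(as.vector(image))
  if (s2 == 0) {
    stop("constant image: noise variance is undefined (sigma_image = 0)",
      call. = FALSE
    )
  }
  with_seed(seed, {
    snr <- runif(1, snr_db[1], snr_db[2])
    sigma_noise <- sqrt(s2 / 10^(snr / 10))
    noisy <- image + array(rnorm(length(image), 0, sigma_noise), dim(image))
    out <- if (clip) pmin(pmax(noisy, 0), 1) else noisy
    attr(out, "snr_db") <- snr
    attr(out, "sigma_noise") <- sigma_noise
    attr(out, "preclip") <- noisy
    out
  })
}

#' Generate a dataset of clean/noisy phantoms on disk
#'
#' Writes `n_images` phantoms (clean volume, ground-truth mask, blob-center
#' table and, optionally, a noisy counterpart) plus a JSON manifest holding
#' every per-image seed, blob count and drawn SNR, so the dataset can be
#' regenerated bit-identically from the manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_images Number of phantoms.
#' @param shape,n_blobs_range,sigma_range,amplitude Passed to
#'   [compose_phantom()].
#' @param snr_db Noise SNR range in dB, or `NULL` to skip noisy volumes.
#' @param seed Master seed; per-image seeds are derived from it.
#' @param format `"nifti"` or `"tiff"` for the volume files.
#' @return A tibble manifest (one row per image) with file paths, seeds, blob
#'   counts and drawn SNRs; also written as `manifest.json`.
#' @export
generate_dataset <- function(out_dir, n_images,
                             shape = c(64, 64, 32),
                             n_blobs_range = c(500, 800),
                             sigma_range = c(0.5, 1.5),
                             amplitude = 1,
                             snr_db = c(0.01, 1),
                             seed = 1L,
                             format = c("nifti", "tiff")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir, call. = FALSE)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  seeds <- derive_seeds(seed, 2L * n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ph <- compose_phantom(
      shape = shape, n_blobs_range = n_blobs_range,
      sigma_range = sigma_range, amplitude = amplitude, seed = seeds[i]
    )
    clean_path <- file.path(out_dir, sprintf("clean_%03d%s", i, ext))
    mask_path <- file.path(out_dir, sprintf("mask_%03d%s", i, ext))
    centers_path <- file.path(out_dir, sprintf("centers_%03d.csv", i))
    write_volume(ph$image, clean_path, dtype = "float")
    write_volume(ph$mask, mask_path, dtype = "uint8")
    write_blob_table(ph$blobs, centers_path)
    snr_drawn <- NA_real_
    noisy_path <- NA_character_
    if (!is.null(snr_db)) {
      noisy <- add_noise(ph$image, snr_db = snr_db, seed = seeds[n_images + i])
      snr_drawn <- attr(noisy, "snr_db")
      noisy_path <- file.path(out_dir, sprintf("noisy_%03d%s", i, ext))
      write_volume(noisy, noisy_path, dtype = "float")
    }
    rows[[i]] <- tibble::tibble(
      image = i, seed = seeds[i], noise_seed = seeds[n_images + i],
      n_blobs = ph$n_blobs, snr_db = snr_drawn,
      clean = basename(clean_path), mask = basename(mask_path),
      centers = basename(centers_path),
      noisy = if (is.na(noisy_path)) NA_character_ else basename(noisy_path)
    )
  }
  manifest <- do.call(rbind, rows)
  meta <- list(
    n_images = n_images, shape = shape, n_blobs_range = n_blobs_range,
    sigma_range = sigma_range, amplitude = amplitude,
    snr_db = snr_db, seed = seed, format = format,
    images = manifest
  )
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest
}
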