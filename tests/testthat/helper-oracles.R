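# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations: flood fill by breadth-first search, the
# direct min-construction for matched true positives, eigenvalue tests for
# definiteness, and brute-force finite differences.

# BFS flood-fill component labeling on a 3D binary mask.
bfs_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6) {
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1, ]
  }
  labels <- array(0L, d)
  nl <- 0L
  for (start in which(mask != 0)) {
    if (labels[start] != 0L) next
    nl <- nl + 1L
    queue <- start
    labels[start] <- nl
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      i0 <- (cur - 1) %% d[1]
      j0 <- ((cur - 1) %/% d[1]) %% d[2]
      k0 <- (cur - 1) %/% (d[1] * d[2])
      for (o in seq_len(nrow(offs))) {
        i <- i0 + offs$dx[o]
        j <- j0 + offs$dy[o]
        k <- k0 + offs$dz[o]
        if (i < 0 || i >= d[1] || j < 0 || j >= d[2] || k < 0 || k >= d[3]) next
        lin <- 1 + i + d[1] * (j + d[2] * k)
        if (mask[lin] != 0 && labels[lin] == 0L) {
          labels[lin] <- nl
          queue <- c(queue, lin)
        }
      }
    }
  }
  labels
}

# Direct evaluation of the matched-true-positive min construction:
# min(#candidates whose nearest ground truth is within d,
#     #ground truths whose nearest candidate is within d).
tp_direct <- function(gt, det, d) {
  if (nrow(gt) == 0 || nrow(det) == 0) {
    return(0L)
  }
  dm <- as.matrix(stats::dist(rbind(det, gt)))
  dm <- dm[seq_len(nrow(det)), nrow(det) + seq_len(nrow(gt)), drop = FALSE]
  min(sum(apply(dm, 1, min) <= d), sum(apply(dm, 2, min) <= d))
}

# Negative definiteness by eigenvalues.
neg_def_eigen <- function(m) {
  all(eigen(m, symmetric = TRUE, only.values = TRUE)$values < 0)
}

# Wrap per-voxel symmetric matrices into a hessian_field (all voxels valid)
# so the indicator can be tested against the eigenvalue oracle directly.
field_from_matrices <- function(mats) {
  n <- length(mats)
  d <- c(n, 1L, 1L)
  arr <- function(f) array(vapply(mats, f, 0), d)
  structure(
    list(
      h11 = arr(function(m) m[1, 1]), h22 = arr(function(m) m[2, 2]),
      h33 = arr(function(m) m[3, 3]), h12 = arr(function(m) m[1, 2]),
      h13 = arr(function(m) m[1, 3]), h23 = arr(function(m) m[2, 3]),
      valid = array(TRUE, d), dim = d
    ),
    class = "hessian_field"
  )
}

random_symmetric <- function(scale = 1) {
  a <- matrix(rnorm(9, sd = scale), 3, 3)
  (a + t(a)) / 2
}

# Quadratic polynomial volume on the 0-based grid; central differences are
# exact on these.
quadratic_volume <- function(shape, coef) {
  # coef: c(xx, yy, zz, xy, xz, yz, x, y, z, const)
  xs <- seq_len(shape[1]) - 1
  ys <- seq_len(shape[2]) - 1
  zs <- seq_len(shape[3]) - 1
  ii <- rep.int(xs, shape[2] * shape[3])
  jj <- rep.int(rep(ys, each = shape[1]), shape[3])
  kk <- rep(zs, each = shape[1] * shape[2])
  array(
    coef[1] * ii^2 + coef[2] * jj^2 + coef[3] * kk^2 +
      coef[4] * ii * jj + coef[5] * ii * kk + coef[6] * jj * kk +
      coef[7] * ii + coef[8] * jj + coef[9] * kk + coef[10],
    shape
  )
}

# Small clean/noisy phantom pair fixture.
tiny_pair <- function(seed, shape = c(16, 16, 8), n_blobs = c(3, 5)) {
  ph <- compose_phantom(shape = shape, n_blobs_range = n_blobs, seed = seed)
  noisy <- add_noise(ph$image, snr_db = c(0.01, 1), seed = seed + 9999)
  list(phantom = ph, noisy = array(as.numeric(noisy), shape))
}

# 0-based (x, y, z) coordinates of linear indices, independent of package
# internals.
linear_to_coords_test <- function(idx, d) {
  idx0 <- idx - 1L
  cbind(idx0 %% d[1], (idx0 %/% d[1]) %% d[2], idx0 %/% (d[1] * d[2]))
}
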