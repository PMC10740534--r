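test_that("blob masks threshold dark objects monotonically", {
  v <- array(0.9, c(8, 8, 4))
  expect_equal(sum(blob_mask(v)), 0)
  v[3, 3, 2] <- 0.1
  v[6, 6, 3] <- 0.45
  expect_equal(sum(blob_mask(v, threshold = 0.5)), 2)
  expect_equal(sum(blob_mask(v, threshold = 0.3)), 1)
  # raising the threshold never shrinks the dark-object mask
  m_lo <- blob_mask(v, threshold = 0.2)
  m_hi <- blob_mask(v, threshold = 0.7)
  expect_true(all(m_hi[m_lo == 1L] == 1L))
  expect_error(blob_mask(v, threshold = 1.2), "threshold")
})

test_that("the joint mask is the Hadamard product of its factors", {
  d <- c(6, 6, 3)
  set.seed(3)
  a <- array(rbinom(prod(d), 1, 0.4), d)
  b <- array(rbinom(prod(d), 1, 0.4), d)
  expect_equal(joint_mask(array(1L, d), b), b)
  expect_equal(sum(joint_mask(a, 1L - a)), 0)
  expect_equal(joint_mask(a, b), a * b)
  expect_error(joint_mask(a, array(1L, c(5, 6, 3))), "shape")
})

test_that("overlapping blobs merged in the intensity mask stay separated by convexity", {
  # four blobs, three of them overlapping: the thresholded intensity mask
  # fuses the trio into one component, the convexity factor splits them
  shape <- c(24, 24, 10)
  centers <- list(c(8, 8, 4), c(11, 8, 4), c(8, 11, 4), c(18, 18, 5))
  field <- array(0, shape)
  for (ce in centers) {
    field <- pmax(field, render_blob(blob_spec(ce, sigma = c(1.6, 1.6, 1.3)), shape))
  }
  img <- 1 - field
  bm <- blob_mask(img, threshold = 0.7)
  expect_equal(max(label_components(bm, 26)), 2) # trio merged + singleton
  final <- joint_mask(convexity_mask(img), bm)
  det <- connected_components(final, volume = img, min_size = 1)
  expect_equal(det$n_detected, 4)
})

test_that("component labeling matches the BFS flood-fill oracle", {
  # corner-touching voxels: one 26-connected component, two 6-connected
  m <- array(0L, c(4, 4, 4))
  m[1, 1, 1] <- 1L
  m[2, 2, 2] <- 1L
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)

  set.seed(42)
  for (i in 1:100) {
    mask <- array(rbinom(16 * 16 * 8, 1, runif(1, 0.05, 0.5)), c(16, 16, 8))
    for (conn in c(26, 6)) {
      got <- label_components(mask, conn)
      want <- bfs_label(mask, conn)
      expect_equal(max(got), max(want))
      # identical partitions: co-membership must agree
      expect_true(all(tapply(want[mask == 1], got[mask == 1],
        function(v) length(unique(v))) == 1))
    }
    # 26-connected count never exceeds the 6-connected count
    expect_lte(max(label_components(mask, 26)), max(label_components(mask, 6)))
  }
})

test_that("component records carry counts, centroids and blobness consistently", {
  p <- tiny_pair(4, shape = c(20, 20, 10), n_blobs = c(4, 6))
  mask <- convexity_mask(p$phantom$image)
  det <- connected_components(mask, volume = p$phantom$image, min_size = 1)
  expect_equal(det$n_detected, nrow(det$blobs))
  expect_equal(det$n_detected, max(det$labels))
  expect_equal(sum(det$mask), sum(det$blobs$n_voxels))
  # centroids lie inside the bounding box of their component
  for (lb in det$blobs$label) {
    vox <- which(det$labels == lb)
    co <- linear_to_coords_test(vox, dim(det$labels))
    row <- det$blobs[det$blobs$label == lb, ]
    expect_true(row$x >= min(co[, 1]) && row$x <= max(co[, 1]))
    expect_true(row$y >= min(co[, 2]) && row$y <= max(co[, 2]))
    expect_true(row$z >= min(co[, 3]) && row$z <= max(co[, 3]))
  }
  # min_size filters single-voxel components
  single <- array(0L, c(6, 6, 3))
  single[2, 2, 2] <- 1L
  single[5, 5, 2] <- 1L
  single[5, 4, 2] <- 1L
  det2 <- connected_components(single, min_size = 2)
  expect_equal(det2$n_detected, 1)
  expect_equal(det2$blobs$n_voxels, 2)
})

test_that("end-to-end detection obeys the subset law and finds clean blobs", {
  # single-blob phantom with the identity translator
  one <- compose_phantom(
    shape = c(16, 16, 8), n_blobs_range = c(1, 1),
    sigma_range = c(1.2, 1.4), seed = 2
  )
  det <- detect(one$image, model = NULL, min_size = 1)
  expect_equal(det$n_detected, 1)
  d_centroid <- sqrt(sum((unlist(det$blobs[1, c("x", "y", "z")]) -
    unlist(one$blobs[1, c("x", "y", "z")]))^2))
  expect_lt(d_centroid, 2)

  # subset law
  conv <- attr(det, "convexity_mask")
  bm <- attr(det, "blob_mask")
  expect_true(all(det$mask[conv == 0L] == 0L))
  expect_true(all(det$mask[bm == 0L] == 0L))

  # empty volume: zero detections
  det0 <- detect(array(1, c(10, 10, 6)), model = NULL)
  expect_equal(det0$n_detected, 0)
})
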