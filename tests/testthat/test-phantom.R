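test_that("quadratic coefficients match direct evaluation and collapse under isotropy", {
  co <- gaussian_coefficients(0, 0, 1, 1, 1)
  expect_equal(unlist(co)[c("a", "b", "c", "d", "e", "f")],
    c(a = 1, b = 1, c = 1, d = 0, e = 0, f = 0))

  co <- gaussian_coefficients(0, 0, 2, 1, 0.5)
  expect_equal(unlist(co)[c("a", "b", "c", "d", "e", "f")],
    c(a = 4, b = 0.25, c = 1, d = 0, e = 0, f = 0))

  # isotropy cancellation for many random orientations
  set.seed(11)
  for (i in 1:1000) {
    s <- runif(1, 0.3, 3)
    co <- gaussian_coefficients(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi), s, s, s)
    expect_equal(co$a, 1 / s^2, tolerance = 1e-12)
    expect_equal(co$b, 1 / s^2, tolerance = 1e-12)
    expect_equal(co$c, 1 / s^2, tolerance = 1e-12)
    expect_true(max(abs(c(co$d, co$e, co$f))) < 1e-12)
  }

  expect_error(gaussian_coefficients(0, 0, -1, 1, 1), "positive")
})

test_that("rendered blobs peak at the center with the stated amplitude and decay", {
  sp <- blob_spec(c(4, 4, 4), sigma = c(1, 1, 1), amplitude = 0.8)
  v <- render_blob(sp, c(9, 9, 9))
  expect_equal(v[5, 5, 5], 0.8)
  expect_equal(which.max(v), 5 + 9 * 4 + 81 * 4)
  # value at unit offset along x equals A * exp(-a)
  expect_equal(v[6, 5, 5], 0.8 * exp(-1))
  # radial symmetry for the isotropic case
  expect_equal(v[6, 5, 5], v[5, 6, 5])
  expect_equal(v[3, 5, 5], v[5, 5, 3])
  # monotone decay along a ray from the center
  ray <- v[5:9, 5, 5]
  expect_true(all(diff(ray) < 0))

  # off-grid center: maximum at the nearest grid voxel
  sp2 <- blob_spec(c(4.3, 3.8, 4.1), sigma = c(1, 1.2, 0.8))
  v2 <- render_blob(sp2, c(9, 9, 9))
  expect_equal(arrayInd(which.max(v2), dim(v2))[1, ], c(5, 5, 5),
    ignore_attr = TRUE)

  # the definiteness guard: a hand-built indefinite form is rejected while
  # every angle/sigma draw tested empirically yields a positive-definite form
  bad <- structure(list(a = 1, b = 1, c = 1, d = 4, e = 0, f = 0),
    class = "quad_coefficients")
  expect_false(is_positive_definite(bad))
  expect_true(is_positive_definite(gaussian_coefficients(0.4, 2.1, 0.2, 3, 0.2)))
  expect_error(blob_spec(c(1, 1, 1), sigma = c(-1, 1, 1)), "positive")
})

test_that("phantom composition is deterministic, records consistent masks, and respects counts", {
  ph <- compose_phantom(shape = c(24, 24, 12), n_blobs_range = c(10, 20), seed = 5)
  ph2 <- compose_phantom(shape = c(24, 24, 12), n_blobs_range = c(10, 20), seed = 5)
  expect_identical(ph$image, ph2$image)
  expect_identical(ph$mask, ph2$mask)
  expect_identical(ph$blobs, ph2$blobs)

  expect_true(all(ph$image >= 0 & ph$image <= 1))
  expect_true(ph$n_blobs >= 10 && ph$n_blobs <= 20)
  expect_identical(dim(ph$image), dim(ph$mask))

  # every recorded blob owns at least one mask voxel
  expect_true(all(lengths(ph$blob_voxels) >= 1))
  # the union mask equals the union of per-blob voxel sets
  expect_setequal(which(ph$mask == 1L), unique(unlist(ph$blob_voxels)))

  # mask voxels away from the forced nearest-center voxel carry field >=
  # cutoff in the composed bright field
  field <- 1 - ph$image
  for (b in seq_len(ph$n_blobs)) {
    vx <- ph$blob_voxels[[b]]
    expect_true(any(field[vx] >= ph$mask_cutoff - 1e-12))
  }

  # single isotropic blob: mask is one 26-connected component (BFS oracle)
  one <- compose_phantom(
    shape = c(16, 16, 8), n_blobs_range = c(1, 1),
    sigma_range = c(1.2, 1.2), seed = 3
  )
  expect_equal(max(bfs_label(one$mask, 26)), 1)
})

test_that("noise calibration matches the SNR model before clipping", {
  ph <- compose_phantom(shape = c(48, 48, 48), n_blobs_range = c(100, 100), seed = 8)
  s2 <- var(as.vector(ph$image))
  for (snr in c(0.01, 0.5, 1)) {
    noisy <- add_noise(ph$image, snr_db = snr, seed = 21)
    expect_equal(attr(noisy, "snr_db"), snr)
    resid <- attr(noisy, "preclip") - ph$image
    expect_equal(var(as.vector(resid)), s2 / 10^(snr / 10), tolerance = 0.05)
    expect_true(all(noisy >= 0 & noisy <= 1))
  }
  # determinism and degenerate input
  n1 <- add_noise(ph$image, seed = 4)
  n2 <- add_noise(ph$image, seed = 4)
  expect_identical(as.numeric(n1), as.numeric(n2))
  expect_error(add_noise(array(0.5, c(8, 8, 8))), "constant")
})

test_that("dataset generation writes a reproducible manifest", {
  out <- file.path(tempdir(), "blob3d-ds")
  on.exit(unlink(out, recursive = TRUE))
  manifest <- generate_dataset(out, 3,
    shape = c(16, 16, 8),
    n_blobs_range = c(3, 6), seed = 99
  )
  expect_equal(nrow(manifest), 3)
  expect_true(all(file.exists(file.path(out, manifest$clean))))
  expect_true(all(file.exists(file.path(out, manifest$noisy))))
  expect_true(all(file.exists(file.path(out, manifest$mask))))
  expect_true(file.exists(file.path(out, "manifest.json")))

  # regenerating from the recorded per-image seed is bit-identical
  ph <- compose_phantom(
    shape = c(16, 16, 8), n_blobs_range = c(3, 6),
    seed = manifest$seed[2]
  )
  stored <- read_volume(file.path(out, manifest$clean[2]))
  expect_equal(stored, ph$image, tolerance = 1e-6) # float32 round trip
  expect_equal(ph$n_blobs, manifest$n_blobs[2])
  centers <- read_blob_table(file.path(out, manifest$centers[2]))
  expect_equal(centers$x, ph$blobs$x)
})
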