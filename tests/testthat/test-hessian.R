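test_that("central-difference Hessian is exact on quadratic volumes", {
  set.seed(2)
  for (i in 1:5) {
    coef <- c(rnorm(6), rnorm(3), rnorm(1))
    v <- quadratic_volume(c(7, 6, 5), coef)
    hf <- hessian_field(v)
    interior <- hf$valid
    expect_equal(max(abs(hf$h11[interior] - 2 * coef[1])), 0, tolerance = 1e-9)
    expect_equal(max(abs(hf$h22[interior] - 2 * coef[2])), 0, tolerance = 1e-9)
    expect_equal(max(abs(hf$h33[interior] - 2 * coef[3])), 0, tolerance = 1e-9)
    expect_equal(max(abs(hf$h12[interior] - coef[4])), 0, tolerance = 1e-9)
    expect_equal(max(abs(hf$h13[interior] - coef[5])), 0, tolerance = 1e-9)
    expect_equal(max(abs(hf$h23[interior] - coef[6])), 0, tolerance = 1e-9)
  }
  expect_error(hessian_field(array(0, c(2, 5, 5))), "at least 3")
})

test_that("a bright Gaussian peak has a negative-definite Hessian at its center", {
  sp <- blob_spec(c(4, 4, 4), sigma = c(1.5, 1, 1.2))
  v <- render_blob(sp, c(9, 9, 9))
  hf <- hessian_field(v)
  m <- matrix(
    c(
      hf$h11[5, 5, 5], hf$h12[5, 5, 5], hf$h13[5, 5, 5],
      hf$h12[5, 5, 5], hf$h22[5, 5, 5], hf$h23[5, 5, 5],
      hf$h13[5, 5, 5], hf$h23[5, 5, 5], hf$h33[5, 5, 5]
    ), 3, 3
  )
  expect_true(neg_def_eigen(m))
  expect_equal(convexity_indicator(hf)[5, 5, 5], 1L)
})

test_that("convexity indicator agrees with the eigenvalue oracle", {
  # constructed cases
  f <- field_from_matrices(list(diag(c(-1, -1, -1)), diag(c(-1, -1, 1)), diag(c(0, 0, 0))))
  expect_equal(as.vector(convexity_indicator(f)), c(1L, 0L, 0L))

  set.seed(31)
  mats <- c(
    lapply(1:8000, function(i) random_symmetric(scale = runif(1, 0.1, 5))),
    # near-singular cases: shrink one eigenvalue toward zero
    lapply(1:2000, function(i) {
      m <- random_symmetric()
      e <- eigen(m, symmetric = TRUE)
      e$values[1] <- e$values[1] * 1e-9
      e$vectors %*% diag(e$values) %*% t(e$vectors)
    })
  )
  got <- as.vector(convexity_indicator(field_from_matrices(mats)))
  want <- as.integer(vapply(mats, neg_def_eigen, TRUE))
  expect_identical(got, want)
})

test_that("image convexity masks follow the inversion convention", {
  # constant volume: empty mask
  expect_equal(convexity_count(convexity_mask(array(0.4, c(6, 6, 6)))), 0)

  # H(J - f) = -H(f) voxelwise
  set.seed(7)
  v <- array(runif(6 * 6 * 6), c(6, 6, 6))
  hf <- hessian_field(v)
  hi <- hessian_field(1 - v)
  for (nm in c("h11", "h22", "h33", "h12", "h13", "h23")) {
    expect_equal(hi[[nm]], -hf[[nm]], tolerance = 1e-12)
  }
  # where Hessians are definite, inverted and non-inverted masks are disjoint
  m1 <- convexity_mask(v, invert = TRUE)
  m2 <- convexity_mask(v, invert = FALSE)
  expect_equal(sum(m1 * m2), 0)

  # clean phantom: the inverted-image mask covers at least one convex voxel
  # per blob neighborhood, and counting matches the foreground sum
  ph <- compose_phantom(shape = c(20, 20, 10), n_blobs_range = c(5, 5),
    sigma_range = c(1, 1.4), seed = 12)
  mask <- convexity_mask(ph$image, invert = TRUE)
  expect_gte(max(bfs_label(mask, 26)), ph$n_blobs)
  expect_equal(convexity_count(mask), sum(mask))

  # all-ones interior of a 5^3 volume has 27 interior voxels
  f <- hessian_field(quadratic_volume(c(5, 5, 5), c(-1, -1, -1, 0, 0, 0, 5, 5, 5, 0)))
  expect_equal(convexity_count(convexity_indicator(f)), 27)
})

test_that("noise typically increases the convexity count and extra blobs never decrease it", {
  up <- 0
  for (s in 1:5) {
    p <- tiny_pair(s, shape = c(24, 24, 12), n_blobs = c(6, 10))
    cin <- convexity_count(convexity_mask(p$phantom$image))
    cns <- convexity_count(convexity_mask(p$noisy))
    if (cns >= cin) up <- up + 1
  }
  expect_gte(up, 4)

  # monotonicity under added blobs (same seed prefix: first blobs identical)
  base <- compose_phantom(shape = c(24, 24, 12), n_blobs_range = c(4, 4), seed = 77)
  field1 <- 1 - base$image
  extra <- compose_phantom(shape = c(24, 24, 12), n_blobs_range = c(4, 4), seed = 78)
  field2 <- pmax(field1, 1 - extra$image)
  c1 <- convexity_count(convexity_mask(1 - field1))
  c2 <- convexity_count(convexity_mask(1 - field2))
  expect_gte(c2, c1)
})

test_that("per-voxel blobness follows the determinant/principal-minor formula", {
  # construct volumes whose inverted image 1 - vol is a quadratic with a
  # prescribed Hessian diag(h) at every interior voxel
  mk_vol <- function(h) {
    1 - quadratic_volume(c(7, 7, 7), c(h[1] / 2, h[2] / 2, h[3] / 2, 0, 0, 0, 0, 0, 0, 0))
  }
  bl <- blobness_volume(mk_vol(c(-2, -2, -2)), invert = TRUE)
  expect_equal(bl$blobness[4, 4, 4], 1) # isotropic curvature scores exactly 1

  bl <- blobness_volume(mk_vol(c(-4, -1, -1)), invert = TRUE)
  expect_equal(bl$blobness[4, 4, 4], 3 * 4^(2 / 3) / 9, tolerance = 1e-12)

  # bound and equality condition on random negative-definite diagonals
  set.seed(5)
  for (i in 1:200) {
    lam <- -rexp(3) - 0.01
    b <- 3 * abs(prod(lam))^(2 / 3) /
      (lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3])
    expect_true(b > 0 && b <= 1 + 1e-12)
    if (abs(b - 1) < 1e-12) expect_equal(lam[1], lam[2], tolerance = 1e-9)
  }
})

test_that("blob scores aggregate over negative-definite voxels with a sentinel", {
  ph <- compose_phantom(shape = c(20, 20, 10), n_blobs_range = c(6, 6),
    sigma_range = c(0.8, 1.4), seed = 15)
  bl <- blobness_volume(ph$image)
  scores <- vapply(ph$blob_voxels, function(v) {
    blob_blobness(bl, v, dim = dim(ph$image))
  }, 0)
  defined <- scores[!is.na(scores)]
  expect_true(length(defined) > 0)
  expect_true(all(defined > 0 & defined <= 1))
  # flat-region blob set -> sentinel
  expect_true(is.na(blob_blobness(bl, which(array(
    c(TRUE, rep(FALSE, length(ph$image) - 1)), dim(ph$image)
  )))))
  expect_error(blob_blobness(bl, integer(0)), "empty")

  mb <- mean_blobness(ph)
  expect_equal(as.numeric(mb), mean(defined))
  expect_equal(attr(mb, "n_blobs"), 6)
})
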