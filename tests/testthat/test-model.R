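smoke_cfg <- function() {
  generator_config(
    base_channels = 4L, n_downsample = 1L, n_residual = 1L,
    stem_kernel = 3L, resize_factor = 1L,
    nce_locations = 16L, nce_hidden = 8L, nce_dim = 8L
  )
}

test_that("preprocessing resizes and normalizes with a recorded inverse", {
  v <- array(0.5, c(8, 8, 4))
  pp <- preprocess(v, resize_factor = 2L)
  expect_identical(dim(pp$volume), c(16L, 16L, 8L)) # interpolation preserves constants
  expect_true(all(pp$volume == 0.5))

  # published shape contract
  pp2 <- preprocess(array(runif(64 * 64 * 32), c(64, 64, 32)), resize_factor = 2L)
  expect_identical(dim(pp2$volume), c(128L, 128L, 64L))
  expect_equal(range(pp2$volume), c(0, 1))

  # round trip error bounded by interpolation tolerance on smooth content
  ph <- compose_phantom(shape = c(16, 16, 8), n_blobs_range = c(3, 5),
    sigma_range = c(2, 2.5), seed = 6)
  pp3 <- preprocess(ph$image, resize_factor = 2L)
  back <- postprocess(pp3$volume, pp3)
  expect_identical(dim(back), dim(ph$image))
  expect_lt(max(abs(back - (ph$image - pp3$range[1]) / diff(pp3$range))), 0.2)
})

test_that("the adversarial objective matches direct substitution", {
  half <- array(0.5, c(2, 2, 2, 1))
  expect_equal(adversarial_loss(half, half), log(0.5) + (1 - log(0.5)))
  # a perfect discriminator on reals drives the first term to 0
  expect_equal(adversarial_loss(array(1, c(2, 2, 2, 1)), half),
    adversarial_loss(array(1 - 1e-7, c(2, 2, 2, 1)), half))
  expect_gt(
    adversarial_loss(array(0.99, dim(half)), half),
    adversarial_loss(half, half)
  )
})

test_that("the contrastive loss saturates and bounds as a categorical cross-entropy", {
  set.seed(8)
  s_n <- 12
  # uniform similarities: loss = log(N + 1) with N negatives
  z <- matrix(rep(rnorm(6), each = s_n), s_n, 6)
  expect_equal(patch_nce(z, z, temperature = 0.07), log(s_n))

  # a dominant positive drives the loss toward 0
  q <- diag(s_n)[, 1:s_n]
  expect_lt(patch_nce(q * 50, q * 50, temperature = 0.01), 1e-6)

  # non-negativity for arbitrary inputs
  for (i in 1:20) {
    q <- matrix(rnorm(s_n * 6), s_n, 6)
    k <- matrix(rnorm(s_n * 6), s_n, 6)
    expect_gte(patch_nce(q, k), 0)
  }
})

test_that("the convexity loss vanishes at identity and counts lost convexity", {
  p <- tiny_pair(21, shape = c(16, 16, 8))
  expect_equal(as.numeric(convexity_loss(p$noisy, p$noisy)), 0)

  # constant translation loses every input-convex voxel within the mask
  const <- array(0.5, dim(p$noisy))
  hi_in <- convexity_mask(p$noisy)
  l <- convexity_loss(p$noisy, const)
  expect_equal(as.numeric(l), sum(hi_in) / length(hi_in))
  expect_equal(unname(attr(l, "counts")["translated"]), 0)

  # non-negativity with arbitrary region masks
  set.seed(2)
  m <- array(rbinom(length(const), 1, 0.5), dim(const))
  expect_gte(as.numeric(convexity_loss(p$noisy, const, region_mask = m)), 0)
  expect_equal(as.numeric(convexity_loss(p$noisy, p$noisy, region_mask = m)), 0)
})

test_that("the distribution loss is a KL divergence with component pass-through", {
  set.seed(14)
  # KL of identical distributions is 0; non-negative otherwise
  f <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  p <- blob3d:::feature_distribution(f)
  expect_equal(blob3d:::kl_channels(p, p), 0)
  q <- blob3d:::feature_distribution(array(rnorm(length(f)), dim(f)))
  expect_gte(blob3d:::kl_channels(p, q), 0)

  gen <- blob3d:::with_seed(3, blob3d:::build_generator(smoke_cfg()))
  model <- structure(list(gen = gen), class = "blob_translator")
  # clean phantom with k blobs: the reference phantom is built with k blobs
  ph <- compose_phantom(shape = c(16, 16, 8), n_blobs_range = c(4, 4),
    sigma_range = c(1, 1.3), seed = 5)
  l <- kld_loss(model, ph$image, seed = 11)
  expect_gte(as.numeric(l), 0)
  k <- max(label_components(blob_mask(ph$image)))
  expect_equal(attr(l, "n_components"), k)
})

test_that("the combined objective is the stated weighted sum", {
  parts <- list(gan = 2, nce_in = 3, nce_ic = 4, convex = 5, kld = 6)
  expect_equal(total_loss(parts, loss_weights(1, 1, 1, 1)), 20)
  expect_equal(total_loss(parts, loss_weights(0, 0, 0, 0)), 2)
  w1 <- loss_weights(lambda_conv = 1)
  w2 <- loss_weights(lambda_conv = 2)
  expect_equal(
    total_loss(parts, w2) - total_loss(parts, w1),
    parts$convex
  )
  expect_error(loss_weights(lambda_in = -1), "non-negative")
})

test_that("translation preserves shape and intensity range", {
  src <- lapply(1:2, function(s) tiny_pair(s, shape = c(16, 16, 8))$noisy)
  gen <- blob3d:::with_seed(4, blob3d:::build_generator(smoke_cfg()))
  model <- structure(
    list(gen = gen, config = smoke_cfg()),
    class = "blob_translator"
  )
  y <- translate(model, src[[1]])
  expect_identical(dim(y), dim(src[[1]]))
  expect_true(all(y >= 0 & y <= 1))
  # near-identity initialization: the untrained translation changes the
  # convexity count only mildly
  c_in <- convexity_count(convexity_mask(src[[1]]))
  c_tr <- convexity_count(convexity_mask(y))
  expect_lt(abs(c_tr - c_in) / c_in, 0.25)
})

test_that("tiling a large volume is lossless under the identity translator", {
  v <- array(runif(64 * 64 * 64), c(64, 64, 64))
  out <- patch_and_stitch(v, identity, patch_shape = c(16, 16, 8))
  expect_equal(attr(out, "n_patches"), 4 * 4 * 8)
  expect_equal(as.numeric(out), as.numeric(v))

  # boundary voxels map back to their original coordinates under a marker
  marker <- function(p) {
    p[1, 1, 1] <- -1
    p
  }
  out2 <- patch_and_stitch(v, marker, patch_shape = c(16, 16, 8))
  expect_equal(sum(out2 == -1), 128)
  expect_equal(out2[17, 17, 9], -1)

  expect_error(patch_and_stitch(v, identity, patch_shape = c(15, 16, 8)), "divisible")
})

test_that("brief seeded training runs, logs finite losses, and resumes deterministically", {
  src <- lapply(1:3, function(s) tiny_pair(s, shape = c(32, 32, 16), n_blobs = c(5, 8))$noisy)
  tgt <- lapply(4:6, function(s) {
    compose_phantom(shape = c(32, 32, 16), n_blobs_range = c(5, 8), seed = s)$image
  })
  cfg <- smoke_generator_config()
  dcfg <- discriminator_config(4L, 2L)
  m <- train_translator(src, tgt,
    gen_config = cfg, disc_config = dcfg,
    n_epochs = 2, lr = 1e-3, seed = 17
  )
  expect_s3_class(m, "blob_translator")
  expect_equal(m$history$epoch, 0:2)
  expect_true(all(is.finite(unlist(m$history[, c(
    "gan", "nce_in", "nce_ic",
    "convex", "kld", "total"
  )]))))
  # Eq-15 linearity of the logged total against independently summed parts
  h <- m$history
  expect_equal(
    h$total,
    h$gan + h$nce_in + h$nce_ic + h$convex + h$kld
  )

  # checkpoint round trip and resume determinism
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(c(path, sub("\\.rds$", ".json", path))))
  m1 <- train_translator(src, tgt,
    gen_config = cfg, disc_config = dcfg,
    n_epochs = 1, lr = 1e-3, seed = 17
  )
  save_model(m1, path)
  m1b <- load_model(path)
  m2 <- train_translator(src, tgt,
    gen_config = cfg, disc_config = dcfg,
    n_epochs = 1, lr = 1e-3, seed = 17, model_init = m1b
  )
  expect_equal(
    m2$history$total[m2$history$epoch == 2],
    m$history$total[m$history$epoch == 2]
  )
  y1 <- translate(m, src[[1]])
  y2 <- translate(m2, src[[1]])
  expect_equal(y1, y2)
})
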