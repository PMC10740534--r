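#' Adversarial objective value
#'
#' The generator/discriminator objective evaluated on patch-level score maps:
#' `E[log D(real)] + E[1 - log D(fake)]`. Scores are epsilon-clamped into
#' `(0, 1)` before taking logs. This is the reported objective; parameter
#' updates use the standard binary cross-entropy discriminator loss and the
#' non-saturating generator loss (see [train_translator()]).
#'
#' @param real_scores,fake_scores Numeric arrays of discriminator scores in
#'   `(0, 1)`.
#' @param eps Clamping constant.
#' @return Scalar objective value.
#' @export
adversarial_loss <- function(real_scores, fake_scores, eps = 1e-7) {
  r <- pmin(pmax(real_scores, eps), 1 - eps)
  f <- pmin(pmax(fake_scores, eps), 1 - eps)
  mean(log(r)) + mean(1 - log(f))
}

#' Patchwise contrastive (NCE) loss from embeddings
#'
#' Cross-entropy of picking the same-location key for each query among all
#' sampled locations: embeddings are L2-normalized, cosine similarities are
#' scaled by `1 / temperature`, and each query's positive is the key at its
#' own location while the `S - 1` other locations serve as negatives. With
#' all similarities equal the loss is `log(S)` (i.e. `log(N + 1)` with `N`
#' negatives) per query; it is non-negative for any inputs.
#'
#' @param query Numeric matrix (S x E) of query embeddings (translated
#'   volume).
#' @param key Numeric matrix (S x E) of key embeddings (source volume), row
#'   `s` being the positive for query `s`.
#' @param temperature Softmax temperature.
#' @return Scalar loss (mean over queries).
#' @export
patch_nce <- function(query, key, temperature = 0.07) {
  r <- nce_forward(query, key, temperature)
  r$loss
}

l2_normalize_rows <- function(x, eps = 1e-10) {
  nrm <- sqrt(rowSums(x^2)) + eps
  list(out = x / nrm, nrm = nrm)
}

nce_forward <- function(query, key, temperature) {
  stopifnot(nrow(query) == nrow(key), nrow(query) >= 2)
  qn <- l2_normalize_rows(query)
  kn <- l2_normalize_rows(key)
  logits <- qn$out %*% t(kn$out) / temperature # (S, S)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  s_n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(s_n), seq_len(s_n))], 1e-30)))
  list(loss = loss, p = p, qn = qn, kn = kn, temperature = temperature)
}

nce_backward <- function(cache, query, key) {
  s_n <- nrow(cache$p)
  glogits <- cache$p
  glogits[cbind(seq_len(s_n), seq_len(s_n))] <-
    glogits[cbind(seq_len(s_n), seq_len(s_n))] - 1
  glogits <- glogits / (s_n * cache$temperature)
  gqn <- glogits %*% cache$kn$out
  gkn <- t(glogits) %*% cache$qn$out
  # back through row-wise L2 normalization
  unnorm_bw <- function(g, x, norm_cache) {
    xn <- norm_cache$out
    (g - xn * rowSums(g * xn)) / norm_cache$nrm
  }
  list(
    gquery = unnorm_bw(gqn, query, cache$qn),
    gkey = unnorm_bw(gkn, key, cache$kn)
  )
}

# Sample spatial locations (rows of the unfolded feature map) per tap layer.
sample_nce_locations <- function(tap_feats, n_locations) {
  lapply(tap_feats, function(f) {
    nsp <- prod(dim(f)[1:3])
    sample.int(nsp, min(n_locations, nsp))
  })
}

feat_rows <- function(f, locs) {
  d <- dim(f)
  dim(f) <- c(prod(d[1:3]), d[4])
  f[locs, , drop = FALSE]
}

# Scatter row gradients back into a zero feature-map gradient.
feat_rows_adj <- function(g, locs, d) {
  out <- matrix(0, prod(d[1:3]), d[4])
  out[locs, ] <- g
  dim(out) <- d
  out
}

#' Multilayer PatchNCE loss between a source volume and its translation
#'
#' Both volumes are passed through the generator's encoder; at each tap layer
#' a common set of spatial locations is sampled, the per-location channel
#' vectors are projected by that layer's two-layer MLP head, and the
#' contrastive loss ([patch_nce()]) is averaged over layers.
#'
#' @param model A `"blob_translator"` (or the internal trainer state).
#' @param source_volume,translated_volume Volumes of identical shape in
#'   model space.
#' @param seed Optional seed for location sampling.
#' @return Scalar loss.
#' @export
patchnce_loss <- function(model, source_volume, translated_volume, seed = NULL) {
  gen <- model$gen
  cfg <- gen$config
  if (cfg$nce_locations < 2) stop("need at least 2 sampled locations", call. = FALSE)
  ex <- enc_forward(gen, as_vol4(source_volume))
  ey <- enc_forward(gen, as_vol4(translated_volume))
  with_seed(seed, {
    locs <- sample_nce_locations(ex$taps, cfg$nce_locations)
    losses <- vapply(seq_along(ex$taps), function(li) {
      xs <- feat_rows(ex$taps[[li]], locs[[li]])
      ys <- feat_rows(ey$taps[[li]], locs[[li]])
      hx <- mlp_forward(model$nce_heads[[li]], xs)
      hy <- mlp_forward(model$nce_heads[[li]], ys)
      nce_forward(hy$out, hx$out, cfg$nce_temperature)$loss
    }, 0)
    mean(losses)
  })
}

#' Convexity-consistency loss
#'
#' Penalizes changes of the Hessian convexity indicator of the inverted image
#' under translation, restricted to a region mask:
#' `mean(|HI(J - G(In)) - HI(J - In)| * M)` over all voxels. The default
#' region mask is `HI(J - In)` itself (the input's convex voxels), so the
#' loss penalizes losing input convexity while allowing noise removal
#' elsewhere. The convexity-count inequality (translated count <= input
#' count) is attached as attribute `counts`.
#'
#' @param input_volume,translated_volume Same-shape volumes, normalized to
#'   `[0, 1]`.
#' @param region_mask Optional 0/1 array `M`; default
#'   `convexity_mask(input_volume)`.
#' @return Scalar loss (hard indicator value) with attribute `counts`
#'   (`input` and `translated` convexity counts).
#' @export
convexity_loss <- function(input_volume, translated_volume, region_mask = NULL) {
  assert_same_shape(input_volume, translated_volume)
  hi_in <- convexity_mask(input_volume, invert = TRUE)
  hi_tr <- convexity_mask(translated_volume, invert = TRUE)
  m <- if (is.null(region_mask)) hi_in else (region_mask != 0) * 1L
  assert_same_shape(hi_in, m)
  loss <- mean(abs(hi_tr - hi_in) * m)
  attr(loss, "counts") <- c(
    input = convexity_count(hi_in),
    translated = convexity_count(hi_tr)
  )
  loss
}

# Differentiable surrogate of the convexity loss used for backpropagation:
# sigmoid-relaxed Sylvester minors of the inverted-image Hessian. Returns the
# surrogate value and the gradient w.r.t. the translated volume. The hard
# Eq-value remains the reported metric (convexity_loss()).
convexity_loss_soft <- function(input_volume, translated_volume,
                                region_mask = NULL, sharpness = 10) {
  hi_in <- convexity_mask(input_volume, invert = TRUE)
  m <- if (is.null(region_mask)) hi_in else (region_mask != 0) * 1L
  field <- hessian_field(1 - translated_volume)
  mm <- field_minors(field)
  k <- sharpness
  s1 <- 1 / (1 + exp(pmin(pmax(k * mm$m1, -500), 500)))
  s2 <- 1 / (1 + exp(pmin(pmax(-k * mm$m2, -500), 500)))
  s3 <- 1 / (1 + exp(pmin(pmax(k * mm$m3, -500), 500)))
  s <- s1 * s2 * s3
  s[!field$valid] <- 0
  n <- length(s)
  diffv <- s - hi_in
  loss <- sum(abs(diffv) * m) / n
  gs <- sign(diffv) * m / n
  gs[!field$valid] <- 0
  gs1 <- gs * s2 * s3
  gs2 <- gs * s1 * s3
  gs3 <- gs * s1 * s2
  gm1 <- gs1 * s1 * (1 - s1) * (-k)
  gm2 <- gs2 * s2 * (1 - s2) * (k)
  gm3 <- gs3 * s3 * (1 - s3) * (-k)
  # minors -> Hessian entries
  h <- field
  g11 <- gm1 + gm2 * h$h22 + gm3 * (h$h22 * h$h33 - h$h23^2)
  g22 <- gm2 * h$h11 + gm3 * (h$h11 * h$h33 - h$h13^2)
  g33 <- gm3 * (h$h11 * h$h22 - h$h12^2)
  g12 <- gm2 * (-2 * h$h12) + gm3 * (2 * h$h13 * h$h23 - 2 * h$h33 * h$h12)
  g13 <- gm3 * (2 * h$h12 * h$h23 - 2 * h$h22 * h$h13)
  g23 <- gm3 * (2 * h$h12 * h$h13 - 2 * h$h11 * h$h23)
  # Hessian entries -> inverted image (stencil adjoints; border carries no
  # gradient, so plain shifts are the exact adjoints)
  adj_d2 <- function(g, ax) {
    shift_zero(g, -1L, ax) + shift_zero(g, 1L, ax) - 2 * g
  }
  adj_mix <- function(g, ax1, ax2) {
    (shift_zero(shift_zero(g, -1L, ax1), -1L, ax2) +
      shift_zero(shift_zero(g, 1L, ax1), 1L, ax2) -
      shift_zero(shift_zero(g, -1L, ax1), 1L, ax2) -
      shift_zero(shift_zero(g, 1L, ax1), -1L, ax2)) / 4
  }
  g_inv <- adj_d2(g11, 1L) + adj_d2(g22, 2L) + adj_d2(g33, 3L) +
    adj_mix(g12, 1L, 2L) + adj_mix(g13, 1L, 3L) + adj_mix(g23, 2L, 3L)
  list(loss = loss, g_translated = -g_inv)
}

# Per-channel spatial softmax distribution of a feature map.
feature_distribution <- function(f) {
  d <- dim(f)
  dim(f) <- c(prod(d[1:3]), d[4])
  mx <- apply(f, 2, max)
  ex <- exp(sweep(f, 2, mx))
  sweep(ex, 2, colSums(ex), "/")
}

kl_channels <- function(p, q, eps = 1e-12) {
  mean(colSums(p * (log(pmax(p, eps)) - log(pmax(q, eps)))))
}

#' Intensity-distribution (KL divergence) loss
#'
#' Measures how far the translated volume's intensity distribution is from
#' that of a clean synthetic phantom with the same number of blobs:
#' (1) the translated volume is binarized and its 26-connected components
#' counted; (2) a random phantom with that blob count is synthesized;
#' (3) both volumes pass through the generator's encoder; (4) each encoder
#' channel's spatial activations are turned into a probability distribution
#' by a softmax and the Kullback-Leibler divergence KL(translated ||
#' synthetic) is averaged over channels. Zero components fall back to a
#' configured minimum blob count.
#'
#' @param model A `"blob_translator"` (or trainer state).
#' @param translated_volume Translated volume in `[0, 1]` (model space).
#' @param sigma_range Scale range for the synthesized reference phantom.
#' @param threshold Binarization threshold before component counting.
#' @param min_blobs Fallback blob count when no component is found.
#' @param seed Seed for the reference phantom.
#' @return Scalar loss (>= 0) with attribute `n_components`.
#' @export
kld_loss <- function(model, translated_volume, sigma_range = c(0.5, 1.5),
                     threshold = 0.5, min_blobs = 1L, seed = NULL) {
  r <- kld_loss_internal(model$gen, translated_volume, sigma_range,
    threshold, min_blobs, seed,
    want_grad = FALSE
  )
  out <- r$loss
  attr(out, "n_components") <- r$n_components
  out
}

kld_loss_internal <- function(gen, translated_volume, sigma_range,
                              threshold, min_blobs, seed, want_grad = TRUE) {
  bm <- blob_mask(translated_volume, threshold = threshold, dark = TRUE)
  # single-voxel components are residual noise (identify-module convention)
  k <- connected_components(bm, 26, min_size = 2L)$n_detected
  n_components <- max(k, min_blobs)
  ref <- compose_phantom(
    shape = dim(translated_volume),
    n_blobs_range = c(n_components, n_components),
    sigma_range = sigma_range, seed = seed
  )
  ey <- enc_forward(gen, as_vol4(translated_volume))
  es <- enc_forward(gen, as_vol4(ref$image))
  fy <- ey$out
  fs <- es$out
  py <- feature_distribution(fy)
  ps <- feature_distribution(fs)
  loss <- kl_channels(py, ps)
  out <- list(loss = loss, n_components = k, ref = ref)
  if (want_grad) {
    # d KL / d a_y for p = softmax(a): p * (log(p/q) - KL_channel)
    eps <- 1e-12
    lr_ratio <- log(pmax(py, eps)) - log(pmax(ps, eps))
    kl_c <- colSums(py * lr_ratio)
    ga <- py * sweep(lr_ratio, 2, kl_c) / ncol(py)
    d <- dim(fy)
    dim(ga) <- d
    bw <- enc_backward(gen, ey$caches, tap_grads = NULL, gout_top = ga)
    out$g_translated <- array(bw$gx, dim(translated_volume))
    out$enc_grads <- bw$grads
    out$enc_caches <- ey$caches
  }
  out
}

#' Loss weights of the combined objective
#'
#' @param lambda_in,lambda_ic,lambda_conv,lambda_kld Non-negative weights of
#'   the source-side contrastive, target-side (identity) contrastive,
#'   convexity-consistency and distribution losses.
#' @return A list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda_in = 1, lambda_ic = 1, lambda_conv = 1,
                         lambda_kld = 1) {
  w <- list(
    lambda_in = lambda_in, lambda_ic = lambda_ic,
    lambda_conv = lambda_conv, lambda_kld = lambda_kld
  )
  if (any(unlist(w) < 0)) stop("loss weights must be non-negative", call. = FALSE)
  structure(w, class = "loss_weights")
}

#' Combined training objective
#'
#' `total = gan + lambda_in * nce_in + lambda_ic * nce_ic +
#' lambda_conv * convex + lambda_kld * kld`.
#'
#' @param parts Named list/vector with elements `gan`, `nce_in`, `nce_ic`,
#'   `convex`, `kld`.
#' @param weights A [loss_weights()] object.
#' @return Scalar total loss.
#' @export
total_loss <- function(parts, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  parts <- as.list(parts)
  parts$gan + weights$lambda_in * parts$nce_in +
    weights$lambda_ic * parts$nce_ic +
    weights$lambda_conv * parts$convex +
    weights$lambda_kld * parts$kld
}
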