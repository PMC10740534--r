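#' Generator configuration
#'
#' Defaults follow the published architecture: a 7x7x7 stem
#' (Convolution-InstanceNorm-ReLU), 2 strided downsampling layers, 6 residual
#' blocks, 2 fractional-strided upsampling layers and a tanh output, with
#' replicate padding of size 1 in the 3x3x3 convolutions, operating on
#' volumes resized by a factor 2 per axis (64x64x32 to 128x128x64). The
#' generator carries a global residual skip (`pre_tanh = conv(features) +
#' (2x - 1)`), so an untrained model starts near the identity mapping, the
#' usual inductive bias for restoration networks.
#'
#' @param base_channels Stem width (channels).
#' @param n_downsample Number of stride-2 downsampling layers.
#' @param n_residual Number of residual blocks.
#' @param stem_kernel Stem kernel size.
#' @param resize_factor Per-axis preprocessing resize factor.
#' @param nce_layers Which encoder taps feed the contrastive head:
#'   `"default"` uses the stem, every downsampling output and the middle
#'   residual block.
#' @param nce_locations Sampled spatial locations per tap layer.
#' @param nce_hidden,nce_dim Hidden width and embedding width of the
#'   two-layer MLP projection.
#' @param nce_temperature Softmax temperature of the contrastive loss.
#' @param out_gain Initialization standard deviation of the output
#'   convolution; 0 (default) starts the model exactly at the identity
#'   mapping `tanh(2x - 1)` through the global skip.
#' @param conv_sharpness Sharpness of the sigmoid relaxation of the
#'   convexity indicator used for backpropagation (the hard indicator is
#'   always used for reported values); 50 concentrates the gradient on
#'   voxels whose Hessian minors are near the definiteness boundary.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(base_channels = 64L, n_downsample = 2L,
                             n_residual = 6L, stem_kernel = 7L,
                             resize_factor = 2L, nce_layers = "default",
                             nce_locations = 256L, nce_hidden = 256L,
                             nce_dim = 256L, nce_temperature = 0.07,
                             conv_sharpness = 50, out_gain = 0) {
  structure(
    list(
      base_channels = as.integer(base_channels),
      n_downsample = as.integer(n_downsample),
      n_residual = as.integer(n_residual),
      stem_kernel = as.integer(stem_kernel),
      resize_factor = as.integer(resize_factor),
      nce_layers = nce_layers,
      nce_locations = as.integer(nce_locations),
      nce_hidden = as.integer(nce_hidden),
      nce_dim = as.integer(nce_dim),
      nce_temperature = nce_temperature,
      conv_sharpness = conv_sharpness,
      out_gain = out_gain
    ),
    class = "generator_config"
  )
}

#' Reduced configuration for CPU-scale experiments
#'
#' A narrow generator (8 base channels, 2 residual blocks, no resize) and a
#' shallow discriminator for seeded desk-scale runs; the architecture shape
#' (stem + strided downsampling + residual blocks + fractional-strided
#' upsampling + tanh) is unchanged.
#'
#' @return A `"generator_config"`.
#' @export
smoke_generator_config <- function() {
  generator_config(
    base_channels = 8L, n_downsample = 2L, n_residual = 2L,
    stem_kernel = 7L, resize_factor = 1L,
    nce_locations = 64L, nce_hidden = 32L, nce_dim = 32L
  )
}

#' Discriminator configuration
#'
#' A volumetric PatchGAN: `n_strided` 4x4x4 stride-2
#' Convolution-InstanceNorm-LeakyReLU(0.2) blocks, one stride-1 4x4x4 block
#' and a stride-1 4x4x4 output convolution producing a patch-level score map;
#' scores pass through a sigmoid.
#'
#' @param base_channels First-layer width.
#' @param n_strided Number of stride-2 blocks (published: 3).
#' @param leaky_slope LeakyReLU slope.
#' @return A list of class `"discriminator_config"`.
#' @export
discriminator_config <- function(base_channels = 64L, n_strided = 3L,
                                 leaky_slope = 0.2) {
  structure(
    list(
      base_channels = as.integer(base_channels),
      n_strided = as.integer(n_strided),
      leaky_slope = leaky_slope
    ),
    class = "discriminator_config"
  )
}

build_generator <- function(config) {
  cb <- config$base_channels
  layers <- list(
    layer_conv(config$stem_kernel, 1L, cb, stride = 1L, pad_mode = 1L),
    layer_inorm(cb),
    layer_relu()
  )
  taps <- 3L
  ch <- cb
  for (d in seq_len(config$n_downsample)) {
    layers <- c(layers, list(
      layer_conv(3L, ch, ch * 2L, stride = 2L, pad = 1L, pad_mode = 1L),
      layer_inorm(ch * 2L),
      layer_relu()
    ))
    ch <- ch * 2L
    taps <- c(taps, length(layers))
  }
  res_start <- length(layers)
  for (r in seq_len(config$n_residual)) {
    layers <- c(layers, list(layer_resblock(ch)))
  }
  mid_res <- res_start + max(1L, ceiling(config$n_residual / 2))
  taps <- c(taps, mid_res)
  n_enc <- length(layers)
  for (d in seq_len(config$n_downsample)) {
    layers <- c(layers, list(
      layer_convt(3L, ch, ch %/% 2L, stride = 2L, pad = 1L),
      layer_inorm(ch %/% 2L),
      layer_relu()
    ))
    ch <- ch %/% 2L
  }
  layers <- c(layers, list(
    layer_conv(config$stem_kernel, ch, 1L, stride = 1L, pad_mode = 1L,
      init_sd = config$out_gain, zero_init = config$out_gain == 0)
  ))
  list(layers = layers, n_enc = n_enc, taps = sort(unique(taps)), config = config)
}

build_discriminator <- function(config) {
  cb <- config$base_channels
  layers <- list(
    layer_conv(4L, 1L, cb, stride = 2L, pad = 1L, pad_mode = 0L),
    layer_lrelu(config$leaky_slope)
  )
  ch <- cb
  for (d in seq_len(config$n_strided - 1L)) {
    layers <- c(layers, list(
      layer_conv(4L, ch, ch * 2L, stride = 2L, pad = 1L, pad_mode = 0L),
      layer_inorm(ch * 2L),
      layer_lrelu(config$leaky_slope)
    ))
    ch <- ch * 2L
  }
  layers <- c(layers, list(
    layer_conv(4L, ch, ch * 2L, stride = 1L, pad = 1L, pad_mode = 0L),
    layer_inorm(ch * 2L),
    layer_lrelu(config$leaky_slope),
    layer_conv(4L, ch * 2L, 1L, stride = 1L, pad = 1L, pad_mode = 0L)
  ))
  list(layers = layers, config = config)
}

as_vol4 <- function(volume) {
  array(volume, c(dim(volume), 1L))
}

# Full generator pass. Returns the translated volume in [0, 1] plus caches
# for backpropagation and the encoder tap feature maps.
gen_forward <- function(gen, x4) {
  r <- net_forward(gen$layers, x4, taps = gen$taps)
  pre <- r$out + (2 * x4 - 1)
  y_tanh <- tanh(pre)
  list(
    y01 = (y_tanh + 1) / 2, y_tanh = y_tanh,
    caches = r$caches, taps = r$taps, x4 = x4
  )
}

# Backward through the full generator. `g_y01` is the loss gradient w.r.t.
# the [0,1] output; `tap_grads` inject contrastive gradients at encoder taps.
gen_backward <- function(gen, fwd, g_y01, tap_grads = NULL) {
  g_pre <- g_y01 * 0.5 * (1 - fwd$y_tanh^2)
  r <- net_backward(gen$layers, fwd$caches, g_pre, tap_grads = tap_grads)
  list(grads = r$grads, gx = r$gx + 2 * g_pre)
}

# Encoder-only pass (feature extraction for the contrastive and
# distribution losses).
enc_forward <- function(gen, x4) {
  net_forward(gen$layers[seq_len(gen$n_enc)], x4, taps = gen$taps)
}

enc_backward <- function(gen, caches, tap_grads, gout_top = NULL) {
  layers <- gen$layers[seq_len(gen$n_enc)]
  if (is.null(gout_top)) {
    top <- layer_output_zero(caches, layers)
    gout_top <- top
  }
  r <- net_backward(layers, caches, gout_top, tap_grads = tap_grads)
  n_total <- length(gen$layers)
  grads <- c(r$grads, vector("list", n_total - gen$n_enc))
  list(gx = r$gx, grads = grads)
}

# Zero array matching the top encoder output (derived from the last cache).
layer_output_zero <- function(caches, layers) {
  # run a cheap shape inference: the last resblock/conv cache stores x
  last <- caches[[length(caches)]]
  if (!is.null(last$sub)) {
    # resblock: output shape equals input shape of its first conv
    array(0, dim(last$sub[[1]]$x))
  } else if (!is.null(last$d)) {
    array(0, last$d)
  } else if (!is.null(last$x)) {
    array(0, dim(last$x))
  } else {
    stop("cannot infer encoder output shape")
  }
}

#' Resize a volume by trilinear interpolation
#'
#' Separable linear interpolation along each axis; constants are preserved
#' exactly.
#'
#' @param volume Numeric 3D array.
#' @param new_shape Target shape `(nx, ny, nz)`.
#' @return Resized array.
#' @export
resize_trilinear <- function(volume, new_shape) {
  assert_volume(volume)
  stopifnot(length(new_shape) == 3, all(new_shape >= 1))
  out <- volume
  for (ax in 1:3) {
    n <- dim(out)[ax]
    m <- new_shape[ax]
    if (m == n) next
    src <- (seq_len(m) - 0.5) * n / m - 0.5
    src <- pmin(pmax(src, 0), n - 1)
    lo <- floor(src)
    w <- src - lo
    hi <- pmin(lo + 1, n - 1)
    W <- matrix(0, m, n)
    W[cbind(seq_len(m), lo + 1)] <- W[cbind(seq_len(m), lo + 1)] + (1 - w)
    W[cbind(seq_len(m), hi + 1)] <- W[cbind(seq_len(m), hi + 1)] + w
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(out, perm)
    da <- dim(a)
    dim(a) <- c(da[1], prod(da[2:3]))
    a <- W %*% a
    dim(a) <- c(m, da[2], da[3])
    out <- aperm(a, order(perm))
  }
  out
}

#' Preprocess a volume for the translation model
#'
#' Trilinear resize by the configured factor and min-max normalization to
#' `[0, 1]`; the inverse transform (original shape and intensity range) is
#' recorded for postprocessing.
#'
#' @param volume Numeric 3D array.
#' @param resize_factor Integer per-axis factor (published contract: 2,
#'   64x64x32 to 128x128x64).
#' @return List with `volume` (model-ready), `orig_shape`, `range`.
#' @export
preprocess <- function(volume, resize_factor = 2L) {
  assert_volume(volume)
  orig_shape <- dim(volume)
  out <- if (resize_factor != 1L) {
    resize_trilinear(volume, orig_shape * resize_factor)
  } else {
    volume
  }
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  list(volume = out, orig_shape = orig_shape, range = rng)
}

#' Invert [preprocess()]
#'
#' Resizes a model-space volume back to the original shape (intensities are
#' kept on the normalized `[0, 1]` scale).
#'
#' @param volume Model-space volume.
#' @param pp The list returned by [preprocess()].
#' @return Volume with the original shape.
#' @export
postprocess <- function(volume, pp) {
  resize_trilinear(volume, pp$orig_shape)
}

#' Translate (denoise) a volume with a trained model
#'
#' Preprocess, run the generator, map the tanh output to `[0, 1]` and
#' inverse-resize to the input shape.
#'
#' @param model A trained `"blob_translator"` ([train_translator()]).
#' @param volume Input volume, intensities in `[0, 1]`.
#' @return Translated volume, same shape as the input, intensities in
#'   `[0, 1]`.
#' @export
translate <- function(model, volume) {
  if (!inherits(model, "blob_translator")) {
    stop("`model` must be a trained blob_translator", call. = FALSE)
  }
  pp <- preprocess(volume, model$gen$config$resize_factor)
  fwd <- gen_forward(model$gen, as_vol4(pp$volume))
  y <- fwd$y01
  dim(y) <- dim(pp$volume)
  out <- postprocess(y, pp)
  pmin(pmax(out, 0), 1)
}

#' Tile a large volume, translate each patch, and stitch
#'
#' Regular non-overlapping tiling into `patch_shape` patches (a 256x256x256
#' volume yields exactly 128 patches of 64x64x32), per-patch application of
#' `translate_fn`, and lossless reassembly in the original layout. The volume
#' dimensions must be divisible by the patch shape; no implicit padding is
#' performed.
#'
#' @param volume Numeric 3D array.
#' @param translate_fn Function applied to each patch (e.g.
#'   `function(v) translate(model, v)`); defaults to the identity.
#' @param patch_shape Patch dimensions, default `c(64, 64, 32)`.
#' @return Reassembled volume with attribute `n_patches`.
#' @export
patch_and_stitch <- function(volume, translate_fn = identity,
                             patch_shape = c(64, 64, 32)) {
  assert_volume(volume)
  d <- dim(volume)
  if (any(d %% patch_shape != 0)) {
    stop("volume dimensions must be divisible by the patch shape", call. = FALSE)
  }
  steps <- d %/% patch_shape
  out <- array(0, d)
  n_patches <- 0L
  for (k in seq_len(steps[3])) {
    for (j in seq_len(steps[2])) {
      for (i in seq_len(steps[1])) {
        xs <- ((i - 1) * patch_shape[1] + 1):(i * patch_shape[1])
        ys <- ((j - 1) * patch_shape[2] + 1):(j * patch_shape[2])
        zs <- ((k - 1) * patch_shape[3] + 1):(k * patch_shape[3])
        patch <- translate_fn(volume[xs, ys, zs])
        stopifnot(all(dim(patch) == patch_shape))
        out[xs, ys, zs] <- patch
        n_patches <- n_patches + 1L
      }
    }
  }
  attr(out, "n_patches") <- n_patches
  out
}
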