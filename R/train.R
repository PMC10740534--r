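# Training loop for the one-sided contrastive translation model.
#
# Per iteration (batch size 1): the discriminator takes one binary
# cross-entropy step on a real clean phantom vs. the current translation;
# the generator (plus the contrastive projection heads) then takes one Adam
# step on the combined objective: non-saturating adversarial term,
# source-side and identity PatchNCE terms, the differentiable surrogate of
# the convexity-consistency loss, and the encoder-feature KL-divergence
# term. Logged values use the hard convexity indicator and the printed
# adversarial objective, independent of the surrogates used for gradients.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# One multilayer PatchNCE evaluation with gradients. `taps_x`/`ey` are the
# encoder tap features of the source and translated branches.
nce_with_grads <- function(heads, taps_x, taps_y, locs, tau) {
  n_l <- length(taps_x)
  tapg_x <- list()
  tapg_y <- list()
  head_grads <- vector("list", n_l)
  losses <- numeric(n_l)
  for (li in seq_len(n_l)) {
    lid <- names(taps_x)[li]
    xs <- feat_rows(taps_x[[li]], locs[[li]])
    ys <- feat_rows(taps_y[[li]], locs[[li]])
    hx <- mlp_forward(heads[[li]], xs)
    hy <- mlp_forward(heads[[li]], ys)
    fw <- nce_forward(hy$out, hx$out, tau)
    losses[li] <- fw$loss
    bw <- nce_backward(fw, hy$out, hx$out)
    by <- mlp_backward(heads[[li]], hy$cache, bw$gquery / n_l)
    bx <- mlp_backward(heads[[li]], hx$cache, bw$gkey / n_l)
    head_grads[[li]] <- grads_add(by$grads, bx$grads)
    tapg_x[[lid]] <- feat_rows_adj(bx$gx, locs[[li]], dim(taps_x[[li]]))
    tapg_y[[lid]] <- feat_rows_adj(by$gx, locs[[li]], dim(taps_y[[li]]))
  }
  list(
    loss = mean(losses), tapg_x = tapg_x, tapg_y = tapg_y,
    head_grads = head_grads
  )
}

adam_step_heads <- function(heads, grads, state, prefix = "nce") {
  for (i in seq_along(heads)) {
    if (is.null(grads[[i]])) next
    for (nm in names(heads[[i]]$params)) {
      key <- paste0(prefix, i, ".", nm)
      heads[[i]]$params[[nm]] <- adam_update_param(
        state, key, heads[[i]]$params[[nm]], grads[[i]][[nm]]
      )
    }
  }
  heads
}

scale_taps <- function(tg, s) lapply(tg, function(g) g * s)

#' Train the contrastive translation model
#'
#' Unpaired training of the denoising generator: the source domain holds
#' noisy blob volumes, the target domain clean synthetic phantoms.
#' Optimization uses Adam (batch size 1) with alternating
#' discriminator/generator updates; all randomness (weight initialization,
#' data order, location sampling, reference phantoms) fans out from `seed`.
#'
#' @param source List of noisy volumes (numeric 3D arrays in `[0, 1]`), all
#'   of one shape.
#' @param target List of clean synthetic volumes of the same shape
#'   (unpaired).
#' @param gen_config A [generator_config()].
#' @param disc_config A [discriminator_config()].
#' @param weights A [loss_weights()].
#' @param n_epochs Number of training epochs.
#' @param lr Generator-side Adam learning rate (published setting: 2e-4).
#' @param d_lr Discriminator learning rate; defaults to `lr`.
#' @param betas Adam moment decay rates.
#' @param sigma_range Blob-scale range used for the KL-divergence reference
#'   phantoms.
#' @param kld_threshold Binarization threshold for component counting inside
#'   the distribution loss.
#' @param region_mask Region mask of the convexity loss:
#'   `"input_convexity"` (default; penalizes losing input-convex voxels) or
#'   `"ones"` (penalizes any indicator change, enforcing the convexity-count
#'   inequality globally).
#' @param conv_sharpness Overrides the config's convexity-surrogate
#'   sharpness if non-`NULL`.
#' @param seed Master seed.
#' @param validation Optional list of volumes; per-epoch inverted-image
#'   convexity counts of inputs vs. translations are logged.
#' @param model_init Optional `"blob_translator"` to continue training from
#'   (its optimizer state and epoch counter are reused).
#' @param verbose Print per-epoch loss lines.
#' @return A `"blob_translator"`: generator, discriminator, projection heads,
#'   configs, optimizer states and a `history` tibble (epoch 0 is the
#'   pre-training evaluation pass; losses are per-epoch means).
#' @export
train_translator <- function(source, target,
                          gen_config = generator_config(),
                          disc_config = discriminator_config(),
                          weights = loss_weights(),
                          n_epochs = 25L, lr = 2e-4, d_lr = lr,
                          betas = c(0.5, 0.999),
                          sigma_range = c(0.5, 1.5),
                          kld_threshold = 0.5,
                          region_mask = c("input_convexity", "ones"),
                          conv_sharpness = NULL,
                          seed = 1L,
                          validation = NULL,
                          model_init = NULL,
                          verbose = FALSE) {
  stopifnot(length(source) >= 1, length(target) >= 1)
  rf <- gen_config$resize_factor
  prep <- function(v) preprocess(v, rf)$volume
  src <- lapply(source, prep)
  tgt <- lapply(target, prep)
  val <- if (!is.null(validation)) lapply(validation, prep) else NULL
  sharp <- if (is.null(conv_sharpness)) gen_config$conv_sharpness else conv_sharpness
  region_mask <- match.arg(region_mask)
  conv_mask_of <- function(v) {
    if (region_mask == "ones") array(1L, dim(v)) else NULL
  }

  seeds <- derive_seeds(seed, 2L + 1000L)
  if (is.null(model_init)) {
    gen <- with_seed(seeds[1], build_generator(gen_config))
    disc <- with_seed(seeds[1], build_discriminator(disc_config))
    e0 <- enc_forward(gen, as_vol4(src[[1]]))
    tap_dims <- vapply(e0$taps, function(f) dim(f)[4], 0L)
    heads <- with_seed(seeds[2], lapply(tap_dims, function(dc) {
      mlp_head(dc, gen_config$nce_hidden, gen_config$nce_dim)
    }))
    state_g <- adam_state(lr, betas[1], betas[2])
    state_d <- adam_state(d_lr, betas[1], betas[2])
    epoch_offset <- 0L
    history <- NULL
  } else {
    stopifnot(inherits(model_init, "blob_translator"))
    gen <- model_init$gen
    disc <- model_init$disc
    heads <- model_init$nce_heads
    state_g <- model_init$state_g
    state_d <- model_init$state_d
    epoch_offset <- model_init$epochs_trained
    history <- model_init$history
  }

  n_src <- length(src)
  run_epoch <- function(epoch_seed, update) {
    parts_sum <- c(gan = 0, nce_in = 0, nce_ic = 0, convex = 0, kld = 0, total = 0)
    it_seeds <- derive_seeds(epoch_seed, 3L * n_src + 1L)
    order_idx <- with_seed(it_seeds[1], sample.int(n_src))
    for (ii in seq_len(n_src)) {
      i <- order_idx[ii]
      In <- src[[i]]
      Ic <- tgt[[with_seed(it_seeds[1 + ii], sample.int(length(tgt), 1))]]
      x4 <- as_vol4(In)
      ic4 <- as_vol4(Ic)
      fwdG <- gen_forward(gen, x4)
      y4 <- fwdG$y01
      y3 <- array(y4, dim(In))

      # ---- discriminator step (translated volume treated as constant) ----
      dr <- net_forward(disc$layers, ic4)
      df <- net_forward(disc$layers, y4)
      gan_printed <- adversarial_loss(stats::plogis(dr$out), stats::plogis(df$out))
      if (update) {
        gl_r <- -stats::plogis(-dr$out) / length(dr$out)
        gl_f <- stats::plogis(df$out) / length(df$out)
        br <- net_backward(disc$layers, dr$caches, gl_r)
        bf <- net_backward(disc$layers, df$caches, gl_f)
        state_d$t <- state_d$t + 1L
        disc$layers <<- adam_step_layers(
          disc$layers, grads_add(br$grads, bf$grads), state_d
        )
      }

      # ---- generator-side losses ----
      g_y <- array(0, dim(y4))
      df2 <- net_forward(disc$layers, y4)
      if (update) {
        gl2 <- -stats::plogis(-df2$out) / length(df2$out)
        badv <- net_backward(disc$layers, df2$caches, gl2)
        g_y <- g_y + badv$gx
      }

      # PatchNCE, source side: encoder taps of the translation pass vs. a
      # fresh encoder pass on the translated volume
      ey <- enc_forward(gen, y4)
      locs <- with_seed(it_seeds[1 + n_src + ii], {
        sample_nce_locations(fwdG$taps, gen$config$nce_locations)
      })
      nce1 <- nce_with_grads(heads, fwdG$taps, ey$taps, locs, gen$config$nce_temperature)
      gen_extra <- NULL
      head_total <- NULL
      if (update && weights$lambda_in > 0) {
        eyb <- enc_backward(gen, ey$caches, tap_grads = nce1$tapg_y)
        g_y <- g_y + weights$lambda_in * array(eyb$gx, dim(g_y))
        gen_extra <- grads_add(gen_extra, grads_scale(eyb$grads, weights$lambda_in))
        head_total <- grads_add(head_total, grads_scale(nce1$head_grads, weights$lambda_in))
      }

      # PatchNCE, identity (target-domain) side
      fwdI <- gen_forward(gen, ic4)
      eyI <- enc_forward(gen, fwdI$y01)
      nce2 <- nce_with_grads(heads, fwdI$taps, eyI$taps, locs, gen$config$nce_temperature)
      if (update && weights$lambda_ic > 0) {
        eyIb <- enc_backward(gen, eyI$caches, tap_grads = nce2$tapg_y)
        mbI <- gen_backward(
          gen, fwdI, weights$lambda_ic * array(eyIb$gx, dim(ic4)),
          tap_grads = scale_taps(nce2$tapg_x, weights$lambda_ic)
        )
        gen_extra <- grads_add(gen_extra, mbI$grads)
        gen_extra <- grads_add(gen_extra, grads_scale(eyIb$grads, weights$lambda_ic))
        head_total <- grads_add(head_total, grads_scale(nce2$head_grads, weights$lambda_ic))
      }

      # convexity consistency (hard value logged, soft surrogate for grads)
      m_reg <- conv_mask_of(In)
      conv_hard <- convexity_loss(In, y3, region_mask = m_reg)
      if (update && weights$lambda_conv > 0) {
        soft <- convexity_loss_soft(In, y3, region_mask = m_reg, sharpness = sharp)
        g_y <- g_y + weights$lambda_conv * as_vol4(soft$g_translated)
      }

      # intensity-distribution consistency
      kr <- kld_loss_internal(
        gen, y3, sigma_range, kld_threshold,
        min_blobs = 1L, seed = it_seeds[1 + 2L * n_src + ii],
        want_grad = update && weights$lambda_kld > 0
      )
      if (update && weights$lambda_kld > 0) {
        g_y <- g_y + weights$lambda_kld * as_vol4(kr$g_translated)
        gen_extra <- grads_add(gen_extra, grads_scale(kr$enc_grads, weights$lambda_kld))
      }

      # main generator backward + Adam step
      if (update) {
        mb <- gen_backward(
          gen, fwdG, g_y,
          tap_grads = scale_taps(nce1$tapg_x, weights$lambda_in)
        )
        g_total <- grads_add(mb$grads, gen_extra)
        state_g$t <- state_g$t + 1L
        gen$layers <<- adam_step_layers(gen$layers, g_total, state_g)
        heads <<- adam_step_heads(heads, head_total, state_g)
      }

      parts <- list(
        gan = gan_printed, nce_in = nce1$loss, nce_ic = nce2$loss,
        convex = as.numeric(conv_hard), kld = kr$loss
      )
      tot <- total_loss(parts, weights)
      if (!is.finite(tot)) {
        stop("training diverged: non-finite loss at iteration ", ii, call. = FALSE)
      }
      parts_sum <- parts_sum + c(unlist(parts), total = tot)
    }
    parts_sum / n_src
  }

  val_counts <- function() {
    if (is.null(val)) {
      return(c(val_conv_in = NA_real_, val_conv_tr = NA_real_))
    }
    cin <- vapply(val, function(v) convexity_count(convexity_mask(v)), 0)
    ctr <- vapply(val, function(v) {
      fw <- gen_forward(gen, as_vol4(v))
      convexity_count(convexity_mask(array(fw$y01, dim(v))))
    }, 0)
    c(val_conv_in = stats::median(cin), val_conv_tr = stats::median(ctr))
  }

  epoch_seeds <- derive_seeds(seeds[3], epoch_offset + n_epochs + 1L)
  hist_row <- function(epoch, m) {
    vc <- val_counts()
    tibble::tibble(
      epoch = epoch,
      gan = unname(m["gan"]), nce_in = unname(m["nce_in"]),
      nce_ic = unname(m["nce_ic"]), convex = unname(m["convex"]),
      kld = unname(m["kld"]), total = unname(m["total"]),
      val_conv_in = unname(vc[["val_conv_in"]]),
      val_conv_tr = unname(vc[["val_conv_tr"]])
    )
  }
  rows <- list()
  if (is.null(history)) {
    m0 <- run_epoch(epoch_seeds[1], update = FALSE)
    rows[[1]] <- hist_row(0L, m0)
    if (verbose) message(sprintf("epoch 0 (init): total %.4f", m0["total"]))
  }
  for (ep in seq_len(n_epochs)) {
    epoch <- epoch_offset + ep
    m <- run_epoch(epoch_seeds[1L + epoch], update = TRUE)
    rows[[length(rows) + 1L]] <- hist_row(epoch, m)
    if (verbose) message(sprintf("epoch %d: total %.4f", epoch, m["total"]))
  }
  new_hist <- do.call(rbind, rows)
  history <- if (is.null(history)) new_hist else rbind(history, new_hist)

  structure(
    list(
      gen = gen, disc = disc, nce_heads = heads,
      config = gen_config, disc_config = disc_config, weights = weights,
      state_g = state_g, state_d = state_d,
      history = tibble::as_tibble(history),
      seed = seed, epochs_trained = epoch_offset + n_epochs
    ),
    class = "blob_translator"
  )
}

#' @export
print.blob_translator <- function(x, ...) {
  cat(sprintf(
    "<blob_translator> %d epochs trained (base %d channels, %d residual blocks)\n",
    x$epochs_trained, x$config$base_channels, x$config$n_residual
  ))
  invisible(x)
}

#' @export
tidy.blob_translator <- function(x, ...) x$history

#' @export
glance.blob_translator <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    epochs_trained = x$epochs_trained,
    total = last$total, gan = last$gan,
    nce_in = last$nce_in, nce_ic = last$nce_ic,
    convex = last$convex, kld = last$kld
  )
}

#' Save / load a trained model
#'
#' Serializes the model (weights, optimizer state, history) plus a JSON
#' sidecar with the architecture settings and seed.
#'
#' @param model A `"blob_translator"`.
#' @param path Output path (`.rds`).
#' @return `path` invisibly ([save_model()]); the model ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "blob_translator"))
  saveRDS(model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(
    list(
      generator = unclass(model$config),
      discriminator = unclass(model$disc_config),
      weights = unclass(model$weights),
      seed = model$seed, epochs_trained = model$epochs_trained
    ),
    sidecar,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  readRDS(path)
}
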