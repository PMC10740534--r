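# Minimal layer-wise neural-network engine for volumetric models.
#
# Volumes flow through layers as 4D arrays (nx, ny, nz, channels). Every
# layer implements an explicit forward (returning output + cache) and
# backward (returning input gradient + parameter gradients), so no general
# autograd is needed; the 3D convolution kernels live in src/conv3d.cpp.

nn_init_conv_w <- function(k, cin, cout, sd = 0.02, zero = FALSE) {
  w <- if (zero) {
    array(0, c(k, k, k, cin, cout))
  } else {
    array(rnorm(k^3 * cin * cout, 0, sd), c(k, k, k, cin, cout))
  }
  w
}

layer_conv <- function(k, cin, cout, stride = 1L, pad = NULL, pad_mode = 1L,
                       init_sd = 0.02, zero_init = FALSE) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(
    type = "conv", stride = as.integer(stride), pad = as.integer(pad),
    pad_mode = as.integer(pad_mode),
    params = list(w = nn_init_conv_w(k, cin, cout, init_sd, zero_init), b = numeric(cout))
  )
}

layer_convt <- function(k, cin, cout, stride = 2L, pad = NULL,
                        out_pad = stride - 1L, init_sd = 0.02) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  list(
    type = "convt", stride = as.integer(stride), pad = as.integer(pad),
    out_pad = as.integer(out_pad),
    params = list(w = nn_init_conv_w(k, cin, cout, init_sd), b = numeric(cout))
  )
}

layer_inorm <- function(c_n, eps = 1e-5) {
  list(type = "inorm", eps = eps, params = list(gamma = rep(1, c_n), beta = rep(0, c_n)))
}

layer_relu <- function() list(type = "relu", params = NULL)
layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope, params = NULL)
layer_tanh <- function() list(type = "tanh", params = NULL)

layer_resblock <- function(c_n, k = 3L, init_sd = 0.02) {
  list(
    type = "resblock", params = NULL,
    layers = list(
      layer_conv(k, c_n, c_n, init_sd = init_sd),
      layer_inorm(c_n),
      layer_relu(),
      layer_conv(k, c_n, c_n, init_sd = init_sd),
      layer_inorm(c_n)
    )
  )
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      out <- .conv3d_fw(x, layer$params$w, layer$params$b, layer$stride, layer$pad, layer$pad_mode)
      list(out = out, cache = list(x = x))
    },
    convt = {
      out <- .convt3d_fw(x, layer$params$w, layer$params$b, layer$stride,
        layer$pad, layer$out_pad)
      list(out = out, cache = list(x = x))
    },
    inorm = {
      d <- dim(x)
      nsp <- prod(d[1:3])
      xm <- x
      dim(xm) <- c(nsp, d[4])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(xc, 2, istd, "*")
      out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2, layer$params$beta, "+")
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, istd = istd, d = d))
    },
    relu = {
      mask <- x > 0
      out <- x * mask
      list(out = out, cache = list(mask = mask))
    },
    lrelu = {
      mask <- x > 0
      out <- ifelse(mask, x, layer$slope * x)
      dim(out) <- dim(x)
      list(out = out, cache = list(mask = mask))
    },
    tanh = {
      out <- tanh(x)
      list(out = out, cache = list(out = out))
    },
    resblock = {
      r <- net_forward(layer$layers, x)
      list(out = x + r$out, cache = list(sub = r$caches))
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, gout) {
  switch(layer$type,
    conv = {
      r <- .conv3d_bw(cache$x, layer$params$w, gout, layer$stride, layer$pad, layer$pad_mode)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    convt = {
      r <- .convt3d_bw(cache$x, layer$params$w, gout, layer$stride, layer$pad)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    inorm = {
      d <- cache$d
      nsp <- prod(d[1:3])
      g <- gout
      dim(g) <- c(nsp, d[4])
      ggamma <- colSums(g * cache$xhat)
      gbeta <- colSums(g)
      dxhat <- sweep(g, 2, layer$params$gamma, "*")
      # dx = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * cache$xhat)
      gx <- sweep(
        sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, "*"),
        2, cache$istd, "*"
      )
      dim(gx) <- d
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = {
      gx <- gout * cache$mask
      list(gx = gx, grads = NULL)
    },
    lrelu = {
      gx <- ifelse(cache$mask, gout, layer$slope * gout)
      dim(gx) <- dim(gout)
      list(gx = gx, grads = NULL)
    },
    tanh = {
      list(gx = gout * (1 - cache$out^2), grads = NULL)
    },
    resblock = {
      r <- net_backward(layer$layers, cache$sub, gout)
      list(gx = gout + r$gx, grads = list(layers = r$grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Forward through a list of layers; optionally record outputs at `taps`.
net_forward <- function(layers, x, taps = integer(0)) {
  caches <- vector("list", length(layers))
  tap_out <- list()
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
    if (i %in% taps) tap_out[[as.character(i)]] <- x
  }
  list(out = x, caches = caches, taps = tap_out)
}

# Backward through a list of layers. `tap_grads` (named by layer index)
# inject extra gradients at those layers' outputs.
net_backward <- function(layers, caches, gout, tap_grads = NULL) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (!is.null(tap_grads)) {
      tg <- tap_grads[[as.character(i)]]
      if (!is.null(tg)) gout <- gout + tg
    }
    r <- layer_backward(layers[[i]], caches[[i]], gout)
    grads[i] <- list(r$grads) # keep NULL slots (parameter-free layers)
    gout <- r$gx
  }
  list(gx = gout, grads = grads)
}

# Elementwise sum of two nested gradient structures (NULL-tolerant).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- grads_add(a[[nm]], b[[nm]])
    return(out)
  }
  a + b
}

grads_scale <- function(g, s) {
  if (is.null(g)) return(NULL)
  if (is.list(g)) return(lapply(g, grads_scale, s = s))
  g * s
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(lr = 2e-4, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$t <- 0L
  e$m <- list()
  e$v <- list()
  e
}

adam_update_param <- function(state, key, param, grad) {
  if (is.null(state$m[[key]])) {
    state$m[[key]] <- grad * 0
    state$v[[key]] <- grad * 0
  }
  state$m[[key]] <- state$beta1 * state$m[[key]] + (1 - state$beta1) * grad
  state$v[[key]] <- state$beta2 * state$v[[key]] + (1 - state$beta2) * grad^2
  mhat <- state$m[[key]] / (1 - state$beta1^state$t)
  vhat <- state$v[[key]] / (1 - state$beta2^state$t)
  param - state$lr * mhat / (sqrt(vhat) + state$eps)
}

# Apply one Adam step to a layer list given matching nested gradients.
adam_step_layers <- function(layers, grads, state, prefix = "") {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (layers[[i]]$type == "resblock") {
      layers[[i]]$layers <- adam_step_layers(
        layers[[i]]$layers, g$layers, state,
        prefix = paste0(prefix, i, ".")
      )
    } else {
      for (nm in names(layers[[i]]$params)) {
        if (is.null(g[[nm]])) next
        key <- paste0(prefix, i, ".", nm)
        layers[[i]]$params[[nm]] <- adam_update_param(
          state, key, layers[[i]]$params[[nm]], g[[nm]]
        )
      }
    }
  }
  layers
}

# ---- Two-layer MLP head (PatchNCE projection) ------------------------------

mlp_head <- function(dim_in, hidden = 64L, dim_out = 64L) {
  sd1 <- sqrt(2 / dim_in)
  sd2 <- sqrt(2 / hidden)
  list(
    params = list(
      w1 = matrix(rnorm(dim_in * hidden, 0, sd1), dim_in, hidden),
      b1 = numeric(hidden),
      w2 = matrix(rnorm(hidden * dim_out, 0, sd2), hidden, dim_out),
      b2 = numeric(dim_out)
    )
  )
}

mlp_forward <- function(head, x) {
  # x: (S, dim_in)
  h_pre <- sweep(x %*% head$params$w1, 2, head$params$b1, "+")
  h <- pmax(h_pre, 0)
  z <- sweep(h %*% head$params$w2, 2, head$params$b2, "+")
  list(out = z, cache = list(x = x, h = h))
}

mlp_backward <- function(head, cache, gz) {
  gw2 <- t(cache$h) %*% gz
  gb2 <- colSums(gz)
  gh <- gz %*% t(head$params$w2)
  gh[cache$h <= 0] <- 0
  gw1 <- t(cache$x) %*% gh
  gb1 <- colSums(gh)
  gx <- gh %*% t(head$params$w1)
  list(gx = gx, grads = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}
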