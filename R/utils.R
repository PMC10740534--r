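# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_volume <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric 3D array", name), call. = FALSE)
  }
  invisible(x)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf(
      "shape mismatch: %s vs %s",
      paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")
    ), call. = FALSE)
  }
  invisible(NULL)
}

# Shift a 3D array by `s` voxels along `axis` with replicate (clamped) padding:
# out[i] = a[clamp(i + s)].
shift_rep <- function(a, s, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + s, 1L), n)
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

# Plain (zero-extending) shift used for stencil adjoints where the border
# carries no gradient: out[i] = a[i + s] inside, 0 outside.
shift_zero <- function(a, s, axis) {
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  src <- seq_len(n) + s
  keep <- src >= 1L & src <= n
  dst <- seq_len(n)[keep]
  src <- src[keep]
  switch(axis,
    out[dst, , ] <- a[src, , , drop = FALSE],
    out[, dst, ] <- a[, src, , drop = FALSE],
    out[, , dst] <- a[, , src, drop = FALSE]
  )
  out
}

# 0-based voxel coordinates (x, y, z) of linear indices in an array of dim `d`.
linear_to_coords <- function(idx, d) {
  idx0 <- idx - 1L
  x <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  z <- idx0 %/% (d[1] * d[2])
  cbind(x = x, y = y, z = z)
}
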