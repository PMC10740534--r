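#' Seeded desk-scale end-to-end experiment
#'
#' A complete, CPU-scale instance of the detection study: synthesize small
#' clean/noisy phantom sets, train the translation model briefly, run
#' detection on held-out noisy volumes, and evaluate against ground truth
#' alongside a Hessian-mask-only baseline (connected components of the
#' convexity mask without the translated-mask intersection).
#'
#' Defaults are deliberately small (8 training + 4 validation volumes of
#' 32x32x16 voxels with 5-10 blobs each, training epochs 0-2 in zero-based
#' numbering, narrow networks) so the whole experiment runs in minutes on
#' one CPU. The learning rate is raised
#' to 2e-3 for this scale: with batch size 1 and only 16 parameter updates,
#' the full-scale rate of 2e-4 would leave the model at its initialization.
#' The convexity loss uses the all-ones region mask so that newly created
#' convex voxels are penalized as well, aligning the optimized penalty with
#' the convexity-count inequality that a short run is expected to respect.
#'
#' @param seed Master seed for data generation and training.
#' @param n_train,n_val Number of training / validation source volumes.
#' @param shape Volume shape.
#' @param n_blobs_range Blob-count range per phantom.
#' @param sigma_range Per-axis blob scale range (voxels).
#' @param snr_db Noise SNR range (dB).
#' @param n_epochs Training epochs.
#' @param lr Learning rate for this scale.
#' @param weights Loss weights (defaults: all 1).
#' @param min_size Minimum detected component size (voxels).
#' @return List with `model` (trained `"blob_translator"`), `phantoms`
#'   (validation ground truth), `detections`, `reports` (per-volume
#'   [evaluate_run()] rows for the full pipeline), `baseline_reports`
#'   (Hessian-mask-only) and `noisy_val` (the validation inputs).
#' @export
smoke_experiment <- function(seed = 7L, n_train = 8L, n_val = 4L,
                             shape = c(32L, 32L, 16L),
                             n_blobs_range = c(5L, 10L),
                             sigma_range = c(0.5, 1.5),
                             snr_db = c(0.01, 1),
                             n_epochs = 3L, lr = 2e-3,
                             weights = loss_weights(),
                             min_size = 2L) {
  seeds <- derive_seeds(seed, 3L * (n_train + n_val) + 1L)
  make_pair <- function(s1, s2) {
    ph <- compose_phantom(
      shape = shape, n_blobs_range = n_blobs_range,
      sigma_range = sigma_range, seed = s1
    )
    list(phantom = ph, noisy = add_noise(ph$image, snr_db = snr_db, seed = s2))
  }
  train_pairs <- lapply(seq_len(n_train), function(i) {
    make_pair(seeds[i], seeds[n_train + n_val + i])
  })
  val_pairs <- lapply(seq_len(n_val), function(i) {
    make_pair(seeds[n_train + i], seeds[2L * n_train + n_val + i])
  })
  # unpaired clean target domain: fresh phantoms, not the sources' clean twins
  target <- lapply(seq_len(n_train), function(i) {
    compose_phantom(
      shape = shape, n_blobs_range = n_blobs_range,
      sigma_range = sigma_range, seed = seeds[2L * (n_train + n_val) + i]
    )$image
  })
  source <- lapply(train_pairs, function(p) strip_attrs(p$noisy))
  noisy_val <- lapply(val_pairs, function(p) strip_attrs(p$noisy))

  model <- train_translator(
    source, target,
    gen_config = smoke_generator_config(),
    disc_config = discriminator_config(base_channels = 8L, n_strided = 2L),
    weights = weights,
    n_epochs = n_epochs, lr = lr,
    sigma_range = sigma_range,
    region_mask = "ones",
    seed = seeds[length(seeds)],
    validation = noisy_val
  )

  detections <- lapply(noisy_val, function(v) detect(v, model, min_size = min_size))
  reports <- lapply(seq_len(n_val), function(i) {
    evaluate_run(detections[[i]], val_pairs[[i]]$phantom)
  })
  baseline <- lapply(seq_len(n_val), function(i) {
    v <- noisy_val[[i]]
    det <- connected_components(convexity_mask(v), volume = v, min_size = min_size)
    evaluate_run(det, val_pairs[[i]]$phantom)
  })
  list(
    model = model,
    phantoms = lapply(val_pairs, function(p) p$phantom),
    noisy_val = noisy_val,
    detections = detections,
    reports = reports,
    baseline_reports = baseline
  )
}

strip_attrs <- function(v) {
  out <- array(as.numeric(v), dim(v))
  out
}
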