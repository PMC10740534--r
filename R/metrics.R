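#' Detection error rate
#'
#' Absolute relative difference between the ground-truth and detected object
#' counts, `|N_GT - N_det| / N_GT`.
#'
#' @param n_ground_truth Ground-truth count (> 0).
#' @param n_detected Detected count (>= 0).
#' @return Non-negative scalar.
#' @export
der <- function(n_ground_truth, n_detected) {
  if (n_ground_truth <= 0) {
    stop("DER is undefined for zero ground-truth objects", call. = FALSE)
  }
  abs(n_ground_truth - n_detected) / n_ground_truth
}

#' Match detected centroids to ground-truth centers
#'
#' Greedy nearest-first association without reuse: candidate-ground-truth
#' pairs are sorted by ascending Euclidean distance (ties broken by candidate
#' index, then ground-truth index, which makes the matching invariant to row
#' permutations), and a pair is accepted when both points are still unmatched
#' and their distance is at most `d`. The accepted pair count is the number
#' of true positives; double counting is impossible because neither side is
#' reused.
#'
#' @param gt_centers Numeric matrix (m x 3) of ground-truth centers.
#' @param det_centroids Numeric matrix (n x 3) of detected centroids.
#' @param d Distance threshold in voxels (> 0); by convention the average
#'   blob diameter of the ground truth.
#' @return List with `tp` (count) and `pairs` (tibble: `det`, `gt`,
#'   `distance`).
#' @export
match_detections <- function(gt_centers, det_centroids, d) {
  stopifnot(d > 0)
  gt_centers <- as.matrix(gt_centers)
  det_centroids <- as.matrix(det_centroids)
  m <- nrow(gt_centers)
  n <- nrow(det_centroids)
  if (m == 0 || n == 0) {
    return(list(tp = 0L, pairs = tibble::tibble(
      det = integer(), gt = integer(), distance = numeric()
    )))
  }
  dist2 <- outer(rowSums(det_centroids^2), rowSums(gt_centers^2), "+") -
    2 * det_centroids %*% t(gt_centers)
  dist2[dist2 < 0] <- 0
  dmat <- sqrt(dist2) # n x m
  cand <- which(dmat <= d, arr.ind = TRUE)
  dimnames(cand) <- NULL
  if (nrow(cand) == 0) {
    return(list(tp = 0L, pairs = tibble::tibble(
      det = integer(), gt = integer(), distance = numeric()
    )))
  }
  dd <- dmat[cand]
  ord <- order(dd, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  dd <- dd[ord]
  det_used <- logical(n)
  gt_used <- logical(m)
  det_sel <- integer(0)
  gt_sel <- integer(0)
  dist_sel <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    di <- cand[i, 1]
    gi <- cand[i, 2]
    if (!det_used[di] && !gt_used[gi]) {
      det_used[di] <- TRUE
      gt_used[gi] <- TRUE
      det_sel <- c(det_sel, di)
      gt_sel <- c(gt_sel, gi)
      dist_sel <- c(dist_sel, dd[i])
    }
  }
  list(
    tp = length(det_sel),
    pairs = tibble::tibble(det = det_sel, gt = gt_sel, distance = dist_sel)
  )
}

#' Precision, recall and F-score from matched counts
#'
#' `Precision = TP / n`, `Recall = TP / m`,
#' `F = 2 * Precision * Recall / (Precision + Recall)` (0 when both are 0).
#'
#' @param tp True-positive count.
#' @param m Ground-truth count (> 0).
#' @param n Detected-candidate count (>= 0).
#' @return Named list `precision`, `recall`, `f_score` with attribute
#'   `flags$precision_undefined` when `n = 0` (precision reported as 0).
#' @export
precision_recall_fscore <- function(tp, m, n) {
  stopifnot(m > 0, n >= 0, tp <= min(m, n) || n == 0)
  precision_undefined <- n == 0
  precision <- if (n == 0) 0 else tp / n
  recall <- tp / m
  f_score <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  out <- list(precision = precision, recall = recall, f_score = f_score)
  attr(out, "flags") <- list(precision_undefined = precision_undefined)
  out
}

#' Dice coefficient and intersection-over-union of two masks
#'
#' `Dice = 2|A & B| / (|A| + |B|)`, `IoU = |A & B| / |A | B|`. Two empty
#' masks are reported as perfectly overlapping (both 1) with a flag.
#'
#' @param mask_a,mask_b Integer/logical 3D arrays of identical shape.
#' @return Named list `dice`, `iou`, with attribute `flags$both_empty`.
#' @export
dice_iou <- function(mask_a, mask_b) {
  assert_same_shape(mask_a, mask_b)
  a <- mask_a != 0
  b <- mask_b != 0
  na <- sum(a)
  nb <- sum(b)
  inter <- sum(a & b)
  union <- sum(a | b)
  both_empty <- na + nb == 0
  out <- if (both_empty) {
    list(dice = 1, iou = 1)
  } else {
    list(dice = 2 * inter / (na + nb), iou = inter / union)
  }
  attr(out, "flags") <- list(both_empty = both_empty)
  out
}

#' Average ground-truth blob diameter
#'
#' The default matching threshold `d`: twice the mean of all per-blob sigma
#' values (the ellipsoid semi-axes at the `exp(-1)` level are approximately
#' the sigmas).
#'
#' @param blobs Phantom blob tibble with `sigma_x`, `sigma_y`, `sigma_z`.
#' @return Scalar diameter in voxels.
#' @export
average_blob_diameter <- function(blobs) {
  2 * mean(c(blobs$sigma_x, blobs$sigma_y, blobs$sigma_z))
}

#' Evaluate one detection run against a phantom's ground truth
#'
#' Assembles the full metric set: detection error rate, greedily matched
#' precision/recall/F-score (threshold `d` defaulting to the ground-truth
#' average blob diameter), Dice and IoU between the identification mask and
#' the ground-truth mask, and the mean blobness of detected blobs.
#'
#' @param detection A `"blob_detection"` (from [detect()] or
#'   [connected_components()]).
#' @param phantom The ground-truth [compose_phantom()] result in the same
#'   volume frame.
#' @param d Matching threshold in voxels; default
#'   [average_blob_diameter()] of the phantom.
#' @return A one-row tibble of class `"metrics_report"` with columns `der,
#'   tp, m, n, precision, recall, f_score, dice, iou, mean_blobness, d`.
#' @export
evaluate_run <- function(detection, phantom, d = NULL) {
  stopifnot(inherits(detection, "blob_detection"), inherits(phantom, "phantom"))
  assert_same_shape(detection$mask, phantom$mask)
  if (is.null(d)) d <- average_blob_diameter(phantom$blobs)
  gt <- as.matrix(phantom$blobs[, c("x", "y", "z")])
  det_c <- as.matrix(detection$blobs[, c("x", "y", "z")])
  matching <- match_detections(gt, det_c, d)
  prf <- precision_recall_fscore(matching$tp, nrow(gt), nrow(det_c))
  overlap <- dice_iou(detection$mask, phantom$mask)
  out <- tibble::tibble(
    der = der(nrow(gt), nrow(det_c)),
    tp = matching$tp, m = nrow(gt), n = nrow(det_c),
    precision = prf$precision, recall = prf$recall, f_score = prf$f_score,
    dice = overlap$dice, iou = overlap$iou,
    mean_blobness = mean(detection$blobs$blobness, na.rm = TRUE),
    d = d
  )
  attr(out, "flags") <- c(attr(prf, "flags"), attr(overlap, "flags"))
  class(out) <- c("metrics_report", class(out))
  out
}

#' Aggregate per-image metric reports
#'
#' Matches the usual mean-plus-or-minus-standard-deviation presentation of
#' per-image evaluation: stacks one-row reports and summarises each metric.
#'
#' @param reports List of `"metrics_report"` rows (or a single stacked
#'   tibble).
#' @return Tibble with columns `metric`, `mean`, `sd`, `n`.
#' @export
summarise_metrics <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports) # single report
  stacked <- do.call(rbind, lapply(reports, as.data.frame))
  cols <- c("der", "precision", "recall", "f_score", "dice", "iou", "mean_blobness")
  tibble::tibble(
    metric = cols,
    mean = unname(vapply(cols, function(cn) mean(stacked[[cn]], na.rm = TRUE), 0)),
    sd = unname(vapply(cols, function(cn) stats::sd(stacked[[cn]], na.rm = TRUE), 0)),
    n = nrow(stacked)
  )
}

#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("der", "precision", "recall", "f_score", "dice", "iou", "mean_blobness"),
    value = c(
      x$der, x$precision, x$recall, x$f_score, x$dice, x$iou, x$mean_blobness
    )
  )
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::as_tibble(x[, c("der", "precision", "recall", "f_score", "dice", "iou")])
}
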