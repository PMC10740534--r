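test_that("detection error rate is the absolute relative count difference", {
  expect_equal(der(100, 100), 0)
  expect_equal(der(100, 85), 0.15)
  expect_equal(der(100, 115), 0.15)
  expect_error(der(0, 10), "undefined")
})

test_that("greedy matching equals the direct min-construction on random instances", {
  # identical point sets: everything matches
  set.seed(9)
  pts <- matrix(runif(30, 0, 20), ncol = 3)
  m <- match_detections(pts, pts, d = 1)
  expect_equal(m$tp, nrow(pts))

  # no-reuse rule: two candidates near one ground truth yield one match
  gt <- matrix(c(0, 0, 0), ncol = 3)
  det <- rbind(c(0.1, 0, 0), c(0.2, 0, 0))
  m <- match_detections(gt, det, d = 1)
  expect_equal(m$tp, 1)
  expect_equal(m$pairs$det, 1) # the nearer candidate wins

  # random instances with small d vs. the direct evaluation
  for (i in 1:50) {
    n_gt <- sample(5:50, 1)
    n_det <- sample(5:50, 1)
    gt <- matrix(runif(3 * n_gt, 0, 30), ncol = 3)
    det <- matrix(runif(3 * n_det, 0, 30), ncol = 3)
    d <- runif(1, 0.5, 2)
    expect_equal(match_detections(gt, det, d)$tp, tp_direct(gt, det, d))
  }

  # permutation invariance
  gt <- matrix(runif(60, 0, 10), ncol = 3)
  det <- matrix(runif(45, 0, 10), ncol = 3)
  m1 <- match_detections(gt, det, d = 3)
  perm <- sample(nrow(det))
  m2 <- match_detections(gt, det[perm, ], d = 3)
  expect_equal(m1$tp, m2$tp)
})

test_that("precision, recall and F-score follow their definitions", {
  expect_equal(unlist(precision_recall_fscore(50, 50, 50), use.names = FALSE), c(1, 1, 1))
  expect_equal(
    unlist(precision_recall_fscore(30, 60, 40), use.names = FALSE),
    c(0.75, 0.5, 0.6)
  )
  expect_equal(unlist(precision_recall_fscore(0, 10, 10), use.names = FALSE), c(0, 0, 0))
  z <- precision_recall_fscore(0, 10, 0)
  expect_equal(z$precision, 0)
  expect_true(attr(z, "flags")$precision_undefined)
})

test_that("Dice and IoU satisfy their algebraic identity", {
  d <- c(8, 8, 4)
  a <- array(0L, d)
  a[1:4, , ] <- 1L
  b <- array(0L, d)
  b[3:6, , ] <- 1L
  r <- dice_iou(a, b)
  expect_equal(r$dice, 0.5)
  expect_equal(r$iou, 1 / 3)
  expect_equal(unlist(dice_iou(a, a), use.names = FALSE), c(1, 1))
  expect_equal(dice_iou(a, 1L - a)$dice, 0)

  both <- dice_iou(array(0L, d), array(0L, d))
  expect_equal(both$dice, 1)
  expect_true(attr(both, "flags")$both_empty)

  set.seed(13)
  for (i in 1:1000) {
    a <- array(rbinom(64, 1, runif(1, 0.1, 0.9)), c(4, 4, 4))
    b <- array(rbinom(64, 1, runif(1, 0.1, 0.9)), c(4, 4, 4))
    r <- dice_iou(a, b)
    expect_equal(r$dice, 2 * r$iou / (1 + r$iou), tolerance = 1e-12)
  }
})

test_that("self-evaluation of a ground-truth detection is perfect", {
  ph <- compose_phantom(shape = c(20, 20, 10), n_blobs_range = c(5, 8),
    sigma_range = c(0.9, 1.3), seed = 31)
  # emulate an exact detector: ground-truth mask and centers as its output
  det <- structure(
    list(
      mask = ph$mask, labels = label_components(ph$mask),
      blobs = tibble::tibble(
        label = seq_len(ph$n_blobs), n_voxels = lengths(ph$blob_voxels),
        x = ph$blobs$x, y = ph$blobs$y, z = ph$blobs$z,
        blobness = NA_real_
      ),
      n_detected = ph$n_blobs, connectivity = 26, min_size = 1L
    ),
    class = "blob_detection"
  )
  rep <- evaluate_run(det, ph)
  expect_equal(rep$der, 0)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$f_score, 1)
  expect_equal(rep$dice, 1)
  expect_equal(rep$iou, 1)
  expect_equal(rep$d, average_blob_diameter(ph$blobs))

  # empty detection: recall 0, DER 1
  empty <- connected_components(array(0L, dim(ph$mask)), min_size = 1)
  rep0 <- evaluate_run(empty, ph)
  expect_equal(rep0$recall, 0)
  expect_equal(rep0$der, 1)

  # aggregation across images
  s <- summarise_metrics(list(rep, rep0))
  expect_equal(s$mean[s$metric == "der"], 0.5)
  expect_equal(s$n[1], 2)
})
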