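square_map <- function(h, w, specs) {
  # specs: list of c(id, r0, c0, size) axis-aligned squares (1-based)
  m <- matrix(0L, h, w)
  for (s in specs) m[s[2]:(s[2] + s[4] - 1), s[3]:(s[3] + s[4] - 1)] <- s[1]
  m
}

test_that("matching is one-to-one with the strict IoU > 0.5 rule", {
  gt <- square_map(32, 32, list(c(1, 2, 2, 8), c(2, 20, 20, 8)))
  rep1 <- match_segments(gt, gt)
  expect_equal(nrow(rep1$matches), 2)
  expect_equal(rep1$matches$iou, c(1, 1))
  expect_length(rep1$unmatched_pred, 0)
  expect_length(rep1$unmatched_gt, 0)

  # constructed IoU exactly 0.5: |A| = 8, |B| = 8, overlap 16/3? use halves:
  # A = 2x4 block, B = shifted so |A&B| = 4, |A|B| = 12 -> IoU = 1/3 (no match);
  # exact 0.5 via |A&B|=8, |A|=12, |B|=8 -> union 12, iou 8/12? Build exact:
  # A: rows 1:2 cols 1:6 (12), B: rows 1:2 cols 1:4 (8), inter 8, union 12
  pred <- square_map(8, 8, list(c(1, 1, 1, 1)))
  pred[1:2, 1:6] <- 1L
  gt2 <- matrix(0L, 8, 8); gt2[1:2, 1:4] <- 1L
  iou <- mask_iou(pred == 1, gt2 == 1)
  expect_equal(iou, 8 / 12)
  # now make a true 0.5 case: A 2x4=8 px, B 2x2=4... simpler: 1x2 vs 1x1:
  a <- matrix(0L, 4, 4); a[1, 1:2] <- 1L
  b <- matrix(0L, 4, 4); b[1, 1:2] <- 1L; b[1, 3] <- 0L
  # IoU(a=2px, gt=1px subset) = 0.5 exactly
  gt3 <- matrix(0L, 4, 4); gt3[1, 1] <- 1L
  expect_equal(mask_iou(a == 1, gt3 == 1), 0.5)
  rep2 <- match_segments(a, gt3)
  expect_equal(nrow(rep2$matches), 0) # 0.5 is NOT a match
  expect_equal(rep2$unmatched_pred, 1L)
  expect_equal(rep2$unmatched_gt, 1L)

  # 2 GT, 1 exact prediction -> 1 TP, 0 FP, 1 FN
  pred3 <- square_map(32, 32, list(c(1, 2, 2, 8)))
  rep3 <- match_segments(pred3, gt)
  expect_equal(nrow(rep3$matches), 1)
  expect_length(rep3$unmatched_pred, 0)
  expect_equal(rep3$unmatched_gt, 2L)

  expect_error(match_segments(matrix(0L, 4, 4), matrix(0L, 5, 5)), "sizes")
})

test_that("matching accepts ellipse detections against a rendered GT", {
  ann <- annotation_set("m", 64, 64, ellipses(
    cx = c(20, 46), cy = c(20, 46), a = c(10, 9), b = c(5, 4),
    phi = c(30, 120), oriented = TRUE, depth = 0:1))
  gt_map <- render_instance_map(ann)
  dets <- ann$ellipses # perfect predictions
  rep <- match_segments(dets, gt_map)
  expect_equal(nrow(rep$matches), 2)
  expect_true(all(rep$matches$iou > 0.95))
})

test_that("panoptic quality follows the TP/FP/FN formula", {
  gt <- square_map(32, 32, list(c(1, 2, 2, 8), c(2, 20, 20, 8)))
  perfect <- match_segments(gt, gt)
  expect_equal(panoptic_quality(perfect), 1)

  none <- match_segments(matrix(0L, 32, 32), gt)
  expect_equal(panoptic_quality(none), 0)

  # 1 exact TP + 1 FP: PQ = 1 / (1 + 0.5) = 2/3
  pred <- square_map(32, 32, list(c(1, 2, 2, 8), c(2, 12, 2, 3)))
  gt1 <- square_map(32, 32, list(c(1, 2, 2, 8)))
  rep <- match_segments(pred, gt1)
  expect_equal(nrow(rep$matches), 1)
  expect_length(rep$unmatched_pred, 1)
  expect_equal(panoptic_quality(rep), 1 / 1.5, tolerance = 1e-12)

  # empty everything: defined as 0
  expect_equal(panoptic_quality(match_segments(matrix(0L, 4, 4),
                                               matrix(0L, 4, 4))), 0)
})

test_that("detection scores derive from the same TP/FP/FN", {
  gt <- square_map(48, 48, list(c(1, 2, 2, 8), c(2, 20, 20, 8), c(3, 36, 2, 8)))
  pred <- square_map(48, 48, list(c(1, 2, 2, 8), c(2, 20, 20, 8),
                                  c(3, 36, 2, 8), c(4, 36, 36, 4)))
  rep <- match_segments(pred, gt) # 3 TP, 1 FP, 0 FN
  sc <- detection_scores(rep)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 1)
  expect_equal(sc$f1, 2 * 0.75 / 1.75, tolerance = 1e-12)

  empty <- match_segments(matrix(0L, 8, 8), matrix(0L, 8, 8))
  expect_equal(unlist(detection_scores(empty)), c(precision = 0, recall = 0, f1 = 0))

  perfect <- match_segments(gt, gt)
  expect_equal(unlist(detection_scores(perfect)),
               c(precision = 1, recall = 1, f1 = 1))
})

test_that("f1 equals 2TP / (2TP + FP + FN) on random reports", {
  set.seed(55)
  for (i in 1:20) {
    tp <- sample(0:5, 1); fp <- sample(0:4, 1); fn <- sample(0:4, 1)
    rep <- structure(list(
      matches = tibble::tibble(pred = seq_len(tp), gt = seq_len(tp),
                               iou = runif(tp, 0.51, 1)),
      unmatched_pred = seq_len(fp) + 100L,
      unmatched_gt = seq_len(fn) + 100L,
      n_pred = tp + fp, n_gt = tp + fn), class = "match_report")
    sc <- detection_scores(rep)
    want <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    expect_equal(sc$f1, want, tolerance = 1e-12)
    expect_true(panoptic_quality(rep) >= 0 && panoptic_quality(rep) <= 1)
  }
})

test_that("Jaccard accuracy works in binary and categorical modes", {
  a <- matrix(0L, 4, 4); a[1:2, 1:4] <- 1L
  b <- matrix(0L, 4, 4); b[2:3, 1:4] <- 1L
  expect_equal(jaccard_accuracy(a, b, "binary"), 4 / 12)
  expect_equal(jaccard_accuracy(a, a, "binary"), 1)
  expect_equal(jaccard_accuracy(a, a, "categorical"), 1)

  # categorical: mean per-class IoU, counting every class present
  p <- matrix(0L, 4, 4); p[1, 1:2] <- 1L; p[2, 1:2] <- 2L
  g <- p; g[2, 1:2] <- 1L # class 2 disagrees entirely, class 1 partially
  iou0 <- mask_iou(p == 0, g == 0)
  iou1 <- mask_iou(p == 1, g == 1)
  iou2 <- mask_iou(p == 2, g == 2)
  expect_equal(jaccard_accuracy(p, g, "categorical"), mean(c(iou0, iou1, iou2)))
  expect_error(jaccard_accuracy(a, matrix(0L, 3, 3)), "sizes")
})

test_that("orientation accuracy counts TPs within 90 degrees", {
  gt_e <- ellipses(c(10, 30, 50, 70), 10, 8, 4, c(0, 90, 180, 270),
                   oriented = TRUE, depth = 0:3)
  dets <- gt_e
  dets$phi <- c(10, 100, 200, 90) # last one off by 180 from 270
  rep <- structure(list(
    matches = tibble::tibble(pred = 1:4, gt = 1:4, iou = rep(0.9, 4)),
    unmatched_pred = integer(), unmatched_gt = integer(),
    n_pred = 4L, n_gt = 4L), class = "match_report")
  expect_equal(orientation_accuracy(rep, dets, gt_e), 0.75)

  flipped <- gt_e; flipped$phi <- (flipped$phi + 180) %% 360
  expect_equal(orientation_accuracy(rep, flipped, gt_e), 0)
  expect_equal(orientation_accuracy(rep, gt_e, gt_e), 1)

  unor <- gt_e; unor$oriented <- FALSE
  expect_equal(orientation_accuracy(rep, unor, gt_e), 0)
})

test_that("greedy matching equals exhaustive optimal matching", {
  set.seed(60)
  for (trial in 1:30) {
    h <- 48; w <- 48
    n_gt <- sample(1:5, 1); n_pred <- sample(1:5, 1)
    gt_ann <- random_annotation(n = n_gt, h = h, w = w)
    gt_map <- render_instance_map(gt_ann)
    pr_ann <- random_annotation(n = n_pred, h = h, w = w)
    # mix: some predictions copy GT ellipses (perturbed), some are random
    pr <- pr_ann$ellipses
    for (i in seq_len(min(n_gt, n_pred))) {
      if (runif(1) < 0.6) {
        pr[i, ] <- gt_ann$ellipses[i, ]
        pr$cx[i] <- pr$cx[i] + runif(1, -2, 2)
        pr$cy[i] <- pr$cy[i] + runif(1, -2, 2)
      }
    }
    rep <- match_segments(pr, gt_map)
    # oracle IoU matrix
    gt_ids <- sort(setdiff(unique(as.vector(gt_map)), 0L))
    iou <- matrix(0, nrow(pr), length(gt_ids))
    for (i in seq_len(nrow(pr))) {
      pm <- rasterize_ellipse(pr[i, ], c(h, w))
      for (j in seq_along(gt_ids)) iou[i, j] <- mask_iou(pm, gt_map == gt_ids[j])
    }
    best <- brute_match(iou)
    expect_equal(nrow(rep$matches), best$tp)
    expect_equal(sum(rep$matches$iou), best$iou_sum, tolerance = 1e-12)
  }
})

test_that("pooled reports aggregate TP/FP/FN across images", {
  gt <- square_map(32, 32, list(c(1, 2, 2, 8), c(2, 20, 20, 8)))
  r1 <- match_segments(gt, gt)
  r2 <- match_segments(matrix(0L, 32, 32), gt)
  pooled <- pool_reports(list(r1, r2))
  expect_equal(nrow(pooled$matches), 2)
  expect_length(pooled$unmatched_gt, 2)
  expect_equal(panoptic_quality(pooled), 2 / (2 + 1), tolerance = 1e-12)
})
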