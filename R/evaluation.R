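#' Match predicted segments against ground-truth segments
#'
#' Predicted ellipses are rasterized to (possibly overlapping) masks and
#' compared pairwise by IoU against the segments of an exclusive
#' ground-truth instance map (as produced by [render_instance_map()] on the
#' adjusted ground truth). Pairs with IoU strictly greater than 0.5 are
#' matched greedily by descending IoU with one-to-one enforcement; because
#' the ground-truth map is exclusive, at most one prediction can exceed 0.5
#' IoU with a given segment, so the greedy matching is optimal. Leftover
#' predictions are false positives and leftover ground-truth segments false
#' negatives.
#'
#' @param pred Detections tibble (ellipse rows), or an integer instance map
#'   of the same size as `gt_map`.
#' @param gt_map Integer ground-truth instance map (0 = background).
#' @param gt_ids Optional ids of the ground-truth segments to score
#'   (default: all ids present in `gt_map`).
#' @return A `match_report`: list with `matches` (tibble `pred`, `gt`,
#'   `iou`), `unmatched_pred`, `unmatched_gt`, `n_pred`, `n_gt`.
#' @export
match_segments <- function(pred, gt_map, gt_ids = NULL) {
  image_size <- dim(gt_map)
  if (is.matrix(pred) && !is.data.frame(pred)) {
    if (!all(dim(pred) == image_size)) {
      stop("match_segments: prediction and ground-truth sizes differ",
           call. = FALSE)
    }
    pids <- sort(setdiff(unique(as.integer(pred)), 0L))
    pred_masks <- lapply(pids, function(i) pred == i)
  } else {
    pids <- seq_len(nrow(pred))
    pred_masks <- lapply(pids, function(i) rasterize_ellipse(pred[i, ], image_size))
  }
  if (is.null(gt_ids)) gt_ids <- sort(setdiff(unique(as.integer(gt_map)), 0L))
  gt_masks <- lapply(gt_ids, function(i) gt_map == i)

  np <- length(pred_masks); ng <- length(gt_masks)
  iou <- matrix(0, np, ng)
  if (np > 0 && ng > 0) {
    for (i in seq_len(np)) {
      for (j in seq_len(ng)) iou[i, j] <- mask_iou(pred_masks[[i]], gt_masks[[j]])
    }
  }
  cand <- which(iou > 0.5, arr.ind = TRUE) # strictly greater than 0.5
  matches <- tibble::tibble(pred = integer(), gt = integer(), iou = double())
  if (nrow(cand) > 0) {
    ord <- order(-iou[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_p <- logical(np); used_g <- logical(ng)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_p[i] || used_g[j]) next
      used_p[i] <- TRUE; used_g[j] <- TRUE
      matches <- dplyr::bind_rows(matches, tibble::tibble(
        pred = as.integer(pids[i]), gt = as.integer(gt_ids[j]),
        iou = iou[i, j]))
    }
  }
  structure(list(
    matches = matches,
    unmatched_pred = setdiff(as.integer(pids), matches$pred),
    unmatched_gt = setdiff(as.integer(gt_ids), matches$gt),
    n_pred = np, n_gt = ng
  ), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> TP=%d FP=%d FN=%d\n", nrow(x$matches),
              length(x$unmatched_pred), length(x$unmatched_gt)))
  invisible(x)
}

#' Panoptic quality of a match report
#'
#' `PQ = sum(IoU over TP) / (|TP| + |FP|/2 + |FN|/2)`, defined as 0 when
#' the denominator is 0.
#'
#' @param report A `match_report` (or a pooled list with the same fields).
#' @return A number in `[0, 1]`.
#' @export
panoptic_quality <- function(report) {
  tp <- nrow(report$matches)
  fp <- length(report$unmatched_pred)
  fn <- length(report$unmatched_gt)
  den <- tp + fp / 2 + fn / 2
  if (den == 0) return(0)
  sum(report$matches$iou) / den
}

#' Precision, recall and F1 of a match report
#'
#' Based on the same TP/FP/FN sets as [panoptic_quality()]; each score is
#' defined as 0 when its denominator vanishes.
#'
#' @inheritParams panoptic_quality
#' @return One-row tibble with `precision`, `recall`, `f1`.
#' @export
detection_scores <- function(report) {
  tp <- nrow(report$matches)
  fp <- length(report$unmatched_pred)
  fn <- length(report$unmatched_gt)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' Jaccard accuracy of segmentation maps
#'
#' Binary mode: IoU of the foreground (values > 0). Categorical mode:
#' unweighted mean of the per-class IoU over all class codes present in
#' either map (classes absent from both are skipped).
#'
#' @param pred_map,gt_map Integer class maps of identical size.
#' @param mode `"binary"` or `"categorical"`.
#' @return A number in `[0, 1]`.
#' @export
jaccard_accuracy <- function(pred_map, gt_map, mode = c("binary", "categorical")) {
  mode <- match.arg(mode)
  if (!all(dim(pred_map) == dim(gt_map))) {
    stop("jaccard_accuracy: map sizes differ", call. = FALSE)
  }
  if (mode == "binary") {
    return(mask_iou(pred_map > 0, gt_map > 0))
  }
  classes <- sort(union(unique(as.integer(pred_map)), unique(as.integer(gt_map))))
  ious <- vapply(classes, function(k) {
    a <- pred_map == k; b <- gt_map == k
    u <- sum(a | b)
    if (u == 0) NA_real_ else sum(a & b) / u
  }, 0)
  mean(ious, na.rm = TRUE)
}

#' Orientation accuracy over true-positive matches
#'
#' Fraction of matched (TP) detections whose predicted head direction lies
#' within 90 degrees (circular) of the ground-truth `phi`. Unoriented
#' predictions count as incorrect. Defined as 0 when there are no TPs.
#'
#' @param report A `match_report` whose `gt` ids index `gt_ellipses`
#'   (via their `id` column if present, else row number).
#' @param pred_dets Detections tibble that was matched (rows = pred ids).
#' @param gt_ellipses Ground-truth ellipse tibble (adjusted ground truth).
#' @return A number in `[0, 1]`.
#' @export
orientation_accuracy <- function(report, pred_dets, gt_ellipses) {
  m <- report$matches
  if (nrow(m) == 0) return(0)
  gt_row <- if ("id" %in% names(gt_ellipses)) {
    match(m$gt, gt_ellipses$id)
  } else {
    m$gt
  }
  ok <- vapply(seq_len(nrow(m)), function(k) {
    i <- m$pred[k]; j <- gt_row[k]
    if (is.na(j) || !isTRUE(pred_dets$oriented[i]) ||
          !isTRUE(gt_ellipses$oriented[j])) return(FALSE)
    d <- abs(((pred_dets$phi[i] - gt_ellipses$phi[j] + 180) %% 360) - 180)
    d < 90
  }, TRUE)
  mean(ok)
}

#' Pool match reports over a dataset
#'
#' TP/FP/FN (and match IoUs) are pooled over images before computing PQ and
#' the detection scores, matching the set formulation of the panoptic
#' quality; Jaccard accuracies are averaged per image.
#'
#' @param reports List of per-image `match_report`s.
#' @return A pooled `match_report`.
#' @export
pool_reports <- function(reports) {
  structure(list(
    matches = dplyr::bind_rows(lapply(reports, function(r) r$matches)),
    unmatched_pred = unlist(lapply(reports, function(r) r$unmatched_pred)),
    unmatched_gt = unlist(lapply(reports, function(r) r$unmatched_gt)),
    n_pred = sum(vapply(reports, function(r) r$n_pred, 0L)),
    n_gt = sum(vapply(reports, function(r) r$n_gt, 0L))
  ), class = "match_report")
}
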