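#' Training targets for a scene
#'
#' Renders all label maps a training sample may need from the scene's
#' annotations.
#'
#' @param scene A `penseg_scene` (or a list with `image` and `annotations`).
#' @param core_scale Core scale for the categorical map.
#' @param head_fraction Head-cap fraction for the body-part map.
#' @return A training sample: list with `image`, `binary`, `categorical`,
#'   `bodypart`, `instance`.
#' @export
scene_targets <- function(scene, core_scale = 0.5, head_fraction = 0.4) {
  ann <- scene$annotations
  im <- render_instance_map(ann)
  bin <- im
  bin[bin > 0L] <- 1L
  list(
    image = scene$image,
    binary = bin,
    categorical = render_categorical(ann, core_scale),
    bodypart = render_bodypart(ann, head_fraction),
    instance = im
  )
}

#' Turn network outputs into oriented ellipse detections
#'
#' Routes the head outputs through the postprocessing chain the model's
#' head set implies:
#' * `categorical` head: core blobs are fitted and scaled up by
#'   `1 / core_scale`.
#' * `embedding` head: the foreground mask is taken from the `binary` head
#'   (thresholded at `tau`) or from the `bodypart` head (body + head
#'   classes by argmax), the masked embeddings are clustered with HDBSCAN,
#'   and one ellipse is fitted per cluster.
#' * `bodypart` head (when present): head-side orientation is resolved for
#'   every detection.
#'
#' @param model A trained `penseg_unet`.
#' @param image Input image array.
#' @param tau Foreground threshold for the binary head.
#' @param cluster_cfg A [clustering_config()].
#' @param core_scale Core scale used when extracting from a categorical head.
#' @param min_pixels Minimum blob/cluster size for ellipse fitting.
#' @return Detections tibble (see [extract_from_instances()]).
#' @export
infer_detections <- function(model, image, tau = 0.5,
                             cluster_cfg = clustering_config(),
                             core_scale = 0.5, min_pixels = 20) {
  heads <- vapply(model$config$heads, function(hh) hh$name, "")
  out <- predict(model, image)
  if ("embedding" %in% heads) {
    if ("binary" %in% heads) {
      fg <- threshold_binary(out$binary[, , 1], tau)
    } else if ("bodypart" %in% heads) {
      cls <- class_map(out$bodypart)
      fg <- cls > 0L
    } else {
      stop("embedding head needs a binary or bodypart head for the foreground mask",
           call. = FALSE)
    }
    imap <- cluster_embeddings(out$embedding, fg, cluster_cfg)
    dets <- extract_from_instances(imap, min_pixels)
  } else if ("categorical" %in% heads) {
    cls <- class_map(out$categorical)
    dets <- extract_from_categorical(cls, core_scale, min_pixels)
  } else if ("binary" %in% heads) {
    fg <- threshold_binary(out$binary[, , 1], tau)
    blobs <- connected_blobs(fg)
    dets <- new_detections()
    for (bl in blobs) {
      if (nrow(bl) < max(min_pixels, 5)) next
      fit <- tryCatch(fit_ellipse(bl), error = function(err) NULL)
      if (is.null(fit)) next
      fit$pixel_count <- nrow(bl)
      fit$source <- "binary"
      dets <- dplyr::bind_rows(dets, fit)
    }
  } else {
    stop("model has no head from which detections can be extracted", call. = FALSE)
  }
  if ("bodypart" %in% heads && nrow(dets) > 0) {
    cls <- class_map(out$bodypart)
    dets <- resolve_orientation(dets, cls)
  }
  dets
}

#' Evaluate detections against annotations over a dataset
#'
#' Ground truth is adjusted per image by [refit_ground_truth()] (ellipses
#' refit to the visible pixels) and rendered to an exclusive instance map.
#' TP/FP/FN and match IoUs are pooled over images for PQ, precision, recall
#' and F1; Jaccard accuracies and orientation accuracy are also reported.
#'
#' @param detections List of per-image detection tibbles.
#' @param annotations List of matching [annotation_set()]s.
#' @param pred_maps Optional list of per-image predicted class maps (for
#'   the Jaccard accuracies): each element a list with any of `binary`,
#'   `categorical`.
#' @param core_scale Core scale used for the ground-truth categorical maps.
#' @return A `penseg_metrics` object; `glance()` returns the headline
#'   one-row tibble, `$per_image` the per-image breakdown.
#' @export
evaluate_detections <- function(detections, annotations, pred_maps = NULL,
                                core_scale = 0.5) {
  stopifnot(length(detections) == length(annotations))
  reports <- vector("list", length(detections))
  per_image <- vector("list", length(detections))
  orient_ok <- 0; orient_n <- 0
  bj <- c(); cj <- c()
  for (i in seq_along(detections)) {
    ann <- annotations[[i]]
    gt <- refit_ground_truth(ann)
    gt_ann <- annotation_set(ann$image_id, ann$height, ann$width,
                             gt$ellipses[setdiff(names(gt$ellipses), "id")])
    gt_map <- render_instance_map(gt_ann)
    # map back: instance j in gt_map corresponds to gt$ellipses row j
    rep_i <- match_segments(detections[[i]], gt_map)
    reports[[i]] <- rep_i
    sc <- detection_scores(rep_i)
    if (nrow(rep_i$matches) > 0) {
      # report gt ids index the rows of the adjusted table, so drop `id`
      ok <- orientation_tp_flags(rep_i, detections[[i]],
                                 gt$ellipses[setdiff(names(gt$ellipses), "id")])
      orient_ok <- orient_ok + sum(ok)
      orient_n <- orient_n + length(ok)
    }
    jb <- jc <- NA_real_
    if (!is.null(pred_maps)) {
      pm <- pred_maps[[i]]
      if (!is.null(pm$binary)) {
        jb <- jaccard_accuracy(pm$binary, render_binary(ann), "binary")
        bj <- c(bj, jb)
      }
      if (!is.null(pm$categorical)) {
        jc <- jaccard_accuracy(pm$categorical,
                               render_categorical(ann, core_scale), "categorical")
        cj <- c(cj, jc)
      }
    }
    per_image[[i]] <- tibble::tibble(
      image_id = ann$image_id, n_gt = rep_i$n_gt, n_pred = rep_i$n_pred,
      tp = nrow(rep_i$matches), fp = length(rep_i$unmatched_pred),
      fn = length(rep_i$unmatched_gt), pq = panoptic_quality(rep_i),
      precision = sc$precision, recall = sc$recall, f1 = sc$f1,
      binary_jaccard = jb, categorical_jaccard = jc
    )
  }
  pooled <- pool_reports(reports)
  sc <- detection_scores(pooled)
  structure(list(
    pq = panoptic_quality(pooled),
    precision = sc$precision, recall = sc$recall, f1 = sc$f1,
    orientation_accuracy = if (orient_n > 0) orient_ok / orient_n else 0,
    orientation_n = orient_n,
    binary_jaccard = if (length(bj) > 0) mean(bj) else NA_real_,
    categorical_jaccard = if (length(cj) > 0) mean(cj) else NA_real_,
    tp = nrow(pooled$matches), fp = length(pooled$unmatched_pred),
    fn = length(pooled$unmatched_gt),
    per_image = dplyr::bind_rows(per_image)
  ), class = "penseg_metrics")
}

orientation_tp_flags <- function(report, dets, gt_ellipses) {
  m <- report$matches
  gt_row <- if ("id" %in% names(gt_ellipses)) match(m$gt, gt_ellipses$id) else m$gt
  vapply(seq_len(nrow(m)), function(k) {
    i <- m$pred[k]; j <- gt_row[k]
    if (is.na(j) || !isTRUE(dets$oriented[i]) || !isTRUE(gt_ellipses$oriented[j])) {
      return(FALSE)
    }
    d <- abs(((dets$phi[i] - gt_ellipses$phi[j] + 180) %% 360) - 180)
    d < 90
  }, TRUE)
}

#' @export
print.penseg_metrics <- function(x, ...) {
  cat(sprintf(
    "<penseg_metrics> PQ=%.4f F1=%.4f precision=%.4f recall=%.4f (TP=%d FP=%d FN=%d)\n",
    x$pq, x$f1, x$precision, x$recall, x$tp, x$fp, x$fn))
  if (x$orientation_n > 0) {
    cat(sprintf("  orientation accuracy: %.4f over %d TPs\n",
                x$orientation_accuracy, x$orientation_n))
  }
  if (!is.na(x$binary_jaccard)) {
    cat(sprintf("  binary Jaccard: %.4f\n", x$binary_jaccard))
  }
  if (!is.na(x$categorical_jaccard)) {
    cat(sprintf("  categorical Jaccard: %.4f\n", x$categorical_jaccard))
  }
  invisible(x)
}

#' @export
glance.penseg_metrics <- function(x, ...) {
  tibble::tibble(
    pq = x$pq, f1 = x$f1, precision = x$precision, recall = x$recall,
    orientation_accuracy = x$orientation_accuracy,
    binary_jaccard = x$binary_jaccard,
    categorical_jaccard = x$categorical_jaccard,
    tp = x$tp, fp = x$fp, fn = x$fn
  )
}

#' @export
tidy.penseg_metrics <- function(x, ...) x$per_image

#' @export
autoplot.penseg_metrics <- function(object, ...) {
  long <- dplyr::bind_rows(lapply(c("pq", "precision", "recall", "f1"),
                                  function(m) tibble::tibble(
                                    metric = m, value = object$per_image[[m]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "per-image value")
}
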