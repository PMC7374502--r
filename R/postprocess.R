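#' Threshold a probability map to a binary mask
#'
#' Pixels with probability greater than or equal to `tau` become foreground
#' (ties count as foreground, for determinism).
#'
#' @param prob_map Numeric matrix of probabilities in `[0, 1]`.
#' @param tau Threshold strictly inside (0, 1); default 0.5.
#' @return Logical matrix.
#' @export
threshold_binary <- function(prob_map, tau = 0.5) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) ||
        tau <= 0 || tau >= 1) {
    stop("tau must lie strictly between 0 and 1", call. = FALSE)
  }
  prob_map >= tau
}

#' 8-connected components of a binary mask
#'
#' Diagonal neighbours belong to the same blob (8-connectivity). Blobs are
#' returned as 0-based pixel coordinate sets, largest first.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return List of data frames with columns `row`, `col` (0-based), ordered
#'   by decreasing pixel count.
#' @export
connected_blobs <- function(mask) {
  storage.mode(mask) <- "logical"
  lab <- .cc_label8(mask)
  k <- max(lab)
  if (k == 0) return(list())
  blobs <- lapply(seq_len(k), function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L)
  })
  blobs[order(vapply(blobs, nrow, 0L), decreasing = TRUE)]
}

#' Clustering configuration for embedding postprocessing
#'
#' `min_cluster_size` is the minimum number of pixels an instance must
#' occupy. The default of 100 was validated at a 640 x 512 working
#' resolution; for smaller images it is scaled by the area ratio
#' `(h * w) / (640 * 512)` (never below 5), since the parameter tracks how
#' many pixels the smallest animal covers. Noise pixels are discarded to
#' background by default, or assigned to the cluster with the nearest mean
#' embedding under `noise_policy = "nearest-cluster"`.
#'
#' @param min_cluster_size Minimum pixels per instance at the 640 x 512
#'   reference resolution (>= 5).
#' @param noise_policy `"discard"` or `"nearest-cluster"`.
#' @param merge_below Clusters whose mean embeddings lie closer than this
#'   L1 distance are fused: under the discriminative training objective the
#'   means of *distinct* instances are pushed at least `2 * delta_d` apart
#'   while pixels of one instance are pulled within `delta_v` of a common
#'   mean, so density modes closer than `delta_d` (default 1.5) are
#'   fragments of a single instance. Set to 0 to disable.
#' @param min_samples HDBSCAN density-smoothing neighbourhood size (the
#'   k-th nearest neighbour defining core distances). `NULL` (default)
#'   couples it to the effective min cluster size as the reference
#'   implementation does, but floors it at 10: when the area scaling pushes
#'   the cluster size to its minimum, a 5-neighbour density estimate is too
#'   noisy and fragments instances.
#' @export
clustering_config <- function(min_cluster_size = 100,
                              noise_policy = c("discard", "nearest-cluster"),
                              merge_below = 1.5, min_samples = NULL) {
  noise_policy <- match.arg(noise_policy)
  min_cluster_size <- as.integer(min_cluster_size)
  if (min_cluster_size < 5) {
    stop("min_cluster_size must be at least 5", call. = FALSE)
  }
  stopifnot(merge_below >= 0, is.null(min_samples) || min_samples >= 1)
  structure(list(min_cluster_size = min_cluster_size,
                 noise_policy = noise_policy, merge_below = merge_below,
                 min_samples = if (is.null(min_samples)) NULL else
                   as.integer(min_samples)),
            class = "clustering_config")
}

#' @rdname clustering_config
#' @param image_size `c(height, width)` of the image being clustered.
#' @return `effective_min_cluster_size()` gives the area-scaled value used
#'   for an image of the given size.
#' @export
effective_min_cluster_size <- function(cfg, image_size) {
  ref <- 640 * 512
  area <- prod(as.double(image_size))
  if (area >= ref) return(cfg$min_cluster_size)
  max(5L, as.integer(round(cfg$min_cluster_size * area / ref)))
}

#' Cluster pixel embeddings into instances with HDBSCAN
#'
#' Runs HDBSCAN (minimum cluster size from `cfg`, scaled to the image area)
#' on the embedding vectors of the foreground pixels only — restricting the
#' clustering to the mask both speeds it up and keeps background pixels out
#' of every instance. Cluster labels are written back to pixel positions;
#' HDBSCAN noise pixels are handled per `cfg$noise_policy`.
#'
#' @param emb `h x w x D` embedding array.
#' @param fg_mask Logical foreground mask of matching spatial size.
#' @param cfg A [clustering_config()].
#' @return Integer `h x w` instance map (0 = background/noise).
#' @export
cluster_embeddings <- function(emb, fg_mask, cfg = clustering_config()) {
  d <- dim(emb)
  if (length(d) != 3 || !all(d[1:2] == dim(fg_mask))) {
    stop("cluster_embeddings: embedding and mask sizes differ", call. = FALSE)
  }
  out <- matrix(0L, d[1], d[2])
  idx <- which(fg_mask != 0)
  if (length(idx) == 0) return(out)
  X <- matrix(emb, d[1] * d[2], d[3])[idx, , drop = FALSE]
  mcs <- effective_min_cluster_size(cfg, d[1:2])
  ms <- if (is.null(cfg$min_samples)) max(mcs, 10L) else cfg$min_samples
  lab <- .hdbscan_labels(X, mcs, ms, FALSE)
  lab <- merge_close_clusters(X, lab, cfg$merge_below)
  if (cfg$noise_policy == "nearest-cluster" && any(lab >= 0) && any(lab < 0)) {
    ids <- sort(unique(lab[lab >= 0]))
    mus <- t(vapply(ids, function(i) colMeans(X[lab == i, , drop = FALSE]),
                    numeric(d[3])))
    noise <- which(lab < 0)
    d2 <- vapply(seq_len(nrow(mus)), function(k) {
      rowSums((X[noise, , drop = FALSE] -
                 matrix(mus[k, ], length(noise), d[3], byrow = TRUE))^2)
    }, numeric(length(noise)))
    d2 <- matrix(d2, nrow = length(noise))
    lab[noise] <- ids[max.col(-d2, ties.method = "first")]
  }
  out[idx] <- lab + 1L
  out[out < 0L] <- 0L
  out
}

# Single-linkage fusion of clusters whose mean embeddings are within
# `threshold` (L1): fragments of one instance under the discriminative
# loss's margins. Labels are re-compacted to 0..k-1.
merge_close_clusters <- function(X, lab, threshold) {
  ids <- sort(unique(lab[lab >= 0]))
  if (threshold <= 0 || length(ids) < 2) return(lab)
  repeat {
    mus <- t(vapply(ids, function(i) colMeans(X[lab == i, , drop = FALSE]),
                    numeric(ncol(X))))
    dm <- as.matrix(dist(mus, method = "manhattan"))
    diag(dm) <- Inf
    mn <- which(dm == min(dm), arr.ind = TRUE)[1, ]
    if (dm[mn[1], mn[2]] >= threshold) break
    lab[lab == ids[mn[2]]] <- ids[mn[1]]
    ids <- ids[-mn[2]]
    if (length(ids) < 2) break
  }
  # compact to 0..k-1; noise (-1, not in ids) maps back to -1
  out <- match(lab, ids) - 1L
  out[is.na(out)] <- -1L
  out
}

new_detections <- function() {
  dplyr::mutate(empty_ellipses(), pixel_count = integer(), source = character())
}

#' Extract ellipse detections from a categorical segmentation
#'
#' Blobs of the inner-core class (code 2) are found by 8-connected blob
#' search, each blob is fitted with the direct least-squares ellipse fit,
#' and the fitted ellipse is scaled back up by `1 / core_scale` to undo the
#' core shrinkage. Blobs smaller than `max(min_pixels, 5)` pixels or with a
#' degenerate fit are skipped (with a message).
#'
#' @param cat_map Integer matrix with codes 0 = background, 1 = outer edge,
#'   2 = inner core.
#' @param core_scale Axis scale that produced the core class (default 0.5).
#' @param min_pixels Minimum blob size in pixels.
#' @return Detections tibble: ellipse columns plus `pixel_count`, `source`.
#' @export
extract_from_categorical <- function(cat_map, core_scale = 0.5, min_pixels = 20) {
  if (core_scale <= 0 || core_scale >= 1) {
    stop("core_scale must lie strictly between 0 and 1", call. = FALSE)
  }
  blobs <- connected_blobs(cat_map == 2L)
  out <- list()
  for (bl in blobs) {
    if (nrow(bl) < max(min_pixels, 5)) next
    fit <- tryCatch(fit_ellipse(bl), error = function(err) {
      message("extract_from_categorical: skipping blob of ", nrow(bl),
              " px (", conditionMessage(err), ")")
      NULL
    })
    if (is.null(fit)) next
    det <- scale_ellipse(fit, 1 / core_scale)
    det$pixel_count <- nrow(bl)
    det$source <- "categorical"
    out[[length(out) + 1]] <- det
  }
  if (length(out) == 0) return(new_detections())
  dplyr::bind_rows(out)
}

#' Extract ellipse detections from an instance map
#'
#' Fits one ellipse per instance id covering at least `max(min_pixels, 5)`
#' pixels; undersized or degenerate instances are skipped (with a message).
#'
#' @param instance_map Integer matrix (0 = background).
#' @param min_pixels Minimum instance size in pixels.
#' @return Detections tibble (see [extract_from_categorical()]), with
#'   `source = "embedding"`.
#' @export
extract_from_instances <- function(instance_map, min_pixels = 20) {
  ids <- sort(setdiff(unique(as.integer(instance_map)), 0L))
  out <- list()
  for (i in ids) {
    idx <- which(instance_map == i, arr.ind = TRUE)
    if (nrow(idx) < max(min_pixels, 5)) next
    fit <- tryCatch(
      fit_ellipse(data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1)),
      error = function(err) {
        message("extract_from_instances: skipping instance ", i,
                " (", conditionMessage(err), ")")
        NULL
      }
    )
    if (is.null(fit)) next
    fit$pixel_count <- nrow(idx)
    fit$source <- "embedding"
    out[[length(out) + 1]] <- fit
  }
  if (length(out) == 0) return(new_detections())
  dplyr::bind_rows(out)
}

#' Resolve head-side orientation of detections from a body-part map
#'
#' For each detection, head-class pixels (code 2) are counted in the front
#' and back halves of the fitted ellipse ([ellipse_halves()]). `phi` is
#' made to point towards the half with the strictly larger count; ties or
#' zero head pixels leave the detection unoriented (`phi` keeps the fitted
#' axis modulo 180).
#'
#' @param dets Detections tibble.
#' @param bodypart_map Integer matrix with codes 0 = background, 1 = body,
#'   2 = head.
#' @return The detections tibble with `phi`/`oriented` updated.
#' @export
resolve_orientation <- function(dets, bodypart_map) {
  if (nrow(dets) == 0) return(dets)
  image_size <- dim(bodypart_map)
  head <- bodypart_map == 2L
  for (i in seq_len(nrow(dets))) {
    halves <- ellipse_halves(dets[i, ], image_size)
    n_front <- sum(head & halves$front)
    n_back <- sum(head & halves$back)
    if (n_front > n_back) {
      dets$oriented[i] <- TRUE
    } else if (n_back > n_front) {
      dets$phi[i] <- (dets$phi[i] + 180) %% 360
      dets$oriented[i] <- TRUE
    } else {
      dets$oriented[i] <- FALSE
    }
  }
  dets
}
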