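test_that("thresholding uses >= with ties to foreground", {
  p <- matrix(0.9, 3, 3)
  expect_true(all(threshold_binary(p, 0.5)))
  expect_true(all(threshold_binary(matrix(0.5, 3, 3), 0.5)))
  cb <- matrix(c(0.2, 0.8), 4, 4)
  expect_identical(threshold_binary(cb, 0.5), cb == 0.8)
  expect_error(threshold_binary(p, 0), "strictly between")
  expect_error(threshold_binary(p, 1), "strictly between")
})

test_that("blob search is 8-connected and size-ordered", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE # diagonal touch -> one blob
  expect_length(connected_blobs(m), 1)

  expect_length(connected_blobs(matrix(FALSE, 4, 4)), 0)

  m2 <- matrix(FALSE, 16, 16)
  m2[2:4, 2:4] <- TRUE; m2[8:10, 8:10] <- TRUE; m2[12:14, 2:4] <- TRUE
  blobs <- connected_blobs(m2)
  expect_length(blobs, 3)
  expect_true(all(vapply(blobs, nrow, 0L) == 9))
  # coordinates are 0-based
  expect_true(all(blobs[[1]]$row >= 0 & blobs[[1]]$row <= 15))

  m3 <- matrix(FALSE, 8, 8)
  m3[1:4, 1:4] <- TRUE; m3[7, 7] <- TRUE
  sizes <- vapply(connected_blobs(m3), nrow, 0L)
  expect_equal(sizes, c(16L, 1L)) # decreasing size
})

test_that("embedding clustering separates well-separated clusters exactly", {
  set.seed(31)
  h <- 40; w <- 40
  fg <- matrix(FALSE, h, w)
  fg[1:15, ] <- TRUE; fg[26:40, ] <- TRUE # 600 px per cluster
  emb <- array(rnorm(h * w * 4, sd = 0.03), c(h, w, 4))
  emb[, , 1][1:15, ] <- emb[, , 1][1:15, ] + 7.5 # 10 * delta_d separation (L1)
  emb[, , 1][26:40, ] <- emb[, , 1][26:40, ] - 7.5
  im <- cluster_embeddings(emb, fg, clustering_config(100))
  ids <- setdiff(unique(as.vector(im)), 0L)
  expect_length(ids, 2)
  # exact partition: each half is one cluster, nothing leaks
  expect_length(unique(as.vector(im[1:15, ])), 1)
  expect_length(unique(as.vector(im[26:40, ])), 1)
  expect_true(all(im[16:25, ] == 0))
})

test_that("undersized clusters and empty masks give no instances", {
  set.seed(32)
  h <- 32; w <- 32 # effective min cluster size floors at 5
  fg <- matrix(FALSE, h, w)
  fg[1, 1:4] <- TRUE # 4 px < 5
  emb <- array(rnorm(h * w * 3, sd = 0.01), c(h, w, 3))
  im <- cluster_embeddings(emb, fg, clustering_config(100))
  expect_equal(sum(im > 0), 0)
  im2 <- cluster_embeddings(emb, matrix(FALSE, h, w), clustering_config(100))
  expect_equal(sum(im2 > 0), 0)
  # background pixels are never assigned
  fg3 <- matrix(FALSE, h, w); fg3[1:20, 1:20] <- TRUE
  im3 <- cluster_embeddings(emb, fg3, clustering_config(100))
  expect_true(all(im3[!fg3] == 0))
})

test_that("min_cluster_size scales with image area from the 640x512 reference", {
  cfg <- clustering_config(100)
  expect_equal(effective_min_cluster_size(cfg, c(512, 640)), 100L)
  expect_equal(effective_min_cluster_size(cfg, c(1024, 1280)), 100L)
  expect_equal(effective_min_cluster_size(cfg, c(256, 320)), 25L)
  expect_equal(effective_min_cluster_size(cfg, c(128, 128)), 5L)
  expect_error(clustering_config(4), "at least 5")
})

test_that("noise policy nearest-cluster reassigns noise pixels", {
  set.seed(33)
  h <- 40; w <- 40
  fg <- matrix(FALSE, h, w)
  fg[1:15, ] <- TRUE; fg[26:40, ] <- TRUE
  fg[20, 1:3] <- TRUE # 3 stray pixels, far outside both clusters
  emb <- array(rnorm(h * w * 4, sd = 0.03), c(h, w, 4))
  emb[, , 1][1:15, ] <- emb[, , 1][1:15, ] + 5
  emb[, , 1][26:40, ] <- emb[, , 1][26:40, ] - 5
  # farther from each cluster than the clusters are from each other, so the
  # strays only attach above the root split and are genuine HDBSCAN noise
  emb[, , 1][20, 1:3] <- -30
  im_d <- cluster_embeddings(emb, fg, clustering_config(100, "discard"))
  im_n <- cluster_embeddings(emb, fg, clustering_config(100, "nearest-cluster"))
  expect_true(all(im_d[20, 1:3] == 0))
  expect_true(all(im_n[20, 1:3] == unique(as.vector(im_n[26:40, ]))))
})

test_that("categorical extraction recovers the annotated ellipse", {
  ann <- annotation_set("x", 64, 64, ellipses(30, 30, 10, 4, 40, TRUE, 0L))
  cm <- render_categorical(ann, 0.5)
  dets <- extract_from_categorical(cm, core_scale = 0.5, min_pixels = 10)
  expect_equal(nrow(dets), 1)
  expect_lt(abs(dets$a - 10) / 10, 0.1)
  expect_lt(abs(dets$b - 4) / 4, 0.1)
  expect_equal(dets$source, "categorical")
  expect_gte(dets$pixel_count, 10)

  empty <- matrix(0L, 32, 32)
  expect_equal(nrow(extract_from_categorical(empty)), 0)
})

test_that("touching edges with disjoint cores still separate", {
  # two animals whose full ellipses overlap but whose cores stay apart
  ann <- annotation_set("t", 64, 96, ellipses(
    cx = c(36, 58), cy = c(32, 32), a = c(13, 13), b = c(6, 6), phi = 0,
    oriented = TRUE, depth = c(0L, 1L)))
  full1 <- rasterize_ellipse(ann$ellipses[1, ], c(64, 96))
  full2 <- rasterize_ellipse(ann$ellipses[2, ], c(64, 96))
  expect_gt(sum(full1 & full2), 0) # edges touch
  cm <- render_categorical(ann, 0.5)
  dets <- extract_from_categorical(cm, 0.5, 10)
  expect_equal(nrow(dets), 2) # cores separate the animals
  expect_equal(sort(round(dets$cx)), c(36, 58), tolerance = 0.05)
})

test_that("instance extraction fits one ellipse per id and skips small ones", {
  ann <- annotation_set("i", 96, 96, ellipses(
    cx = c(20, 50, 78), cy = c(20, 60, 30), a = c(11, 12, 10),
    b = c(5, 6, 4), phi = c(10, 100, 250), oriented = TRUE, depth = 0:2))
  im <- render_instance_map(ann)
  dets <- extract_from_instances(im, min_pixels = 20)
  expect_equal(nrow(dets), 3)
  got <- dets[order(dets$cx), ]
  want <- ann$ellipses[order(ann$ellipses$cx), ]
  expect_equal(got$a, want$a, tolerance = 0.08)
  expect_equal(got$b, want$b, tolerance = 0.08)

  tiny <- matrix(0L, 16, 16); tiny[1:2, 1:2] <- 1L # 4 px
  expect_equal(nrow(extract_from_instances(tiny, 1)), 0)
  expect_equal(nrow(extract_from_instances(matrix(0L, 8, 8))), 0)
})

test_that("extraction is idempotent on its own rendered detections", {
  ann <- annotation_set("r", 96, 96, ellipses(
    cx = c(30, 66), cy = c(30, 60), a = c(12, 10), b = c(6, 5),
    phi = c(15, 120), oriented = TRUE, depth = 0:1))
  im <- render_instance_map(ann)
  d1 <- extract_from_instances(im, 20)
  d1$depth <- 0:1
  ann2 <- annotation_set("r2", 96, 96,
                         d1[c("cx", "cy", "a", "b", "phi", "oriented", "depth")])
  d2 <- extract_from_instances(render_instance_map(ann2), 20)
  expect_equal(d2[order(d2$cx), c("cx", "cy", "a", "b")],
               d1[order(d1$cx), c("cx", "cy", "a", "b")], tolerance = 0.05)
})

test_that("orientation resolution flips phi towards the head side", {
  e <- ellipses(24, 24, 10, 4, 0, TRUE, 0L)
  ann <- annotation_set("o", 48, 64, e)
  bp <- render_bodypart(ann, 0.4)
  # detection with the correct axis but unknown direction
  det <- e; det$oriented <- FALSE
  det$pixel_count <- 100L; det$source <- "embedding"

  ok <- resolve_orientation(det, bp)
  expect_true(ok$oriented)
  expect_equal(ok$phi, 0)

  flipped <- det; flipped$phi <- 180
  r <- resolve_orientation(flipped, bp)
  expect_true(r$oriented)
  expect_equal(r$phi, 0) # flipped back towards the head

  no_head <- bp; no_head[no_head == 2L] <- 1L
  r2 <- resolve_orientation(det, no_head)
  expect_false(r2$oriented)
})

test_that("orientation resolution handles whole synthetic scenes", {
  set.seed(35)
  flips <- 0; total <- 0
  for (s in 1:6) {
    ann <- random_annotation(n = 3)
    bp <- render_bodypart(ann, 0.4)
    im <- render_instance_map(ann)
    dets <- extract_from_instances(im, 10)
    dets <- resolve_orientation(dets, bp)
    occl <- non_occluded_ids(ann)
    for (i in seq_len(nrow(dets))) {
      j <- which.min((ann$ellipses$cx - dets$cx[i])^2 +
                       (ann$ellipses$cy - dets$cy[i])^2)
      if (!(j %in% occl)) next
      total <- total + 1
      expect_true(dets$oriented[i])
      expect_lt(angle_diff(dets$phi[i], ann$ellipses$phi[j]), 90)
    }
  }
  expect_gt(total, 5)
})

test_that("HDBSCAN agrees with the scikit-learn implementation on blobs", {
  set.seed(99)
  X <- rbind(matrix(rnorm(300, 0, 0.3), 150, 2),
             matrix(rnorm(300, 6, 0.3), 150, 2),
             cbind(rnorm(150, 12, 0.3), rnorm(150, 0, 0.3)))
  mine <- penseg:::.hdbscan_labels(X, 30L, 30L, FALSE)
  csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  utils::write.table(X, csv, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from sklearn.cluster import HDBSCAN\n",
    "X = np.loadtxt(%s, delimiter=',')\n",
    "lab = HDBSCAN(min_cluster_size=30, min_samples=30).fit_predict(X)\n",
    "np.savetxt(%s, lab, fmt='%%d')\n"),
    deparse(csv), deparse(out_csv))
  py <- tempfile(fileext = ".py")
  writeLines(code, py)
  status <- system2("python", py, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  theirs <- as.integer(readLines(out_csv))
  # same noise set and identical partition of the clustered points
  expect_equal(mine < 0, theirs < 0)
  keep <- mine >= 0
  expect_equal(length(unique(mine[keep])), length(unique(theirs[keep])))
  tab <- table(mine[keep], theirs[keep])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("clusters closer than the merge margin are fused into one instance", {
  set.seed(34)
  h <- 40; w <- 40
  fg <- matrix(FALSE, h, w)
  fg[1:10, ] <- TRUE; fg[15:24, ] <- TRUE; fg[31:40, ] <- TRUE
  emb <- array(rnorm(h * w * 4, sd = 0.02), c(h, w, 4))
  # two fragments of one instance 0.5 apart in L1, one distinct instance far away
  emb[, , 1][1:10, ] <- emb[, , 1][1:10, ] + 5
  emb[, , 1][15:24, ] <- emb[, , 1][15:24, ] + 5.5
  emb[, , 1][31:40, ] <- emb[, , 1][31:40, ] - 5
  merged <- cluster_embeddings(emb, fg, clustering_config(100, merge_below = 1.5))
  expect_length(setdiff(unique(as.vector(merged)), 0L), 2)
  expect_equal(unique(as.vector(merged[1:10, ])),
               unique(as.vector(merged[15:24, ])))
  raw <- cluster_embeddings(emb, fg, clustering_config(100, merge_below = 0))
  expect_length(setdiff(unique(as.vector(raw)), 0L), 3)
})
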