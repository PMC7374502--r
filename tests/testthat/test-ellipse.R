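test_that("rasterization matches pixel-centre enumeration", {
  # circle of radius 2: exactly the 13 integer points with dx^2+dy^2 <= 4
  e <- ellipses(5, 5, 2, 2, 0)
  m <- rasterize_ellipse(e, c(11, 11))
  expect_equal(sum(m), 13)
  expect_equal(m, brute_mask(5, 5, 2, 2, 0, 11, 11))

  set.seed(41)
  for (i in 1:10) {
    a <- runif(1, 3, 12); b <- runif(1, 2, a); phi <- runif(1, 0, 360)
    cx <- runif(1, 0, 30); cy <- runif(1, 0, 30)
    m1 <- rasterize_ellipse(ellipses(cx, cy, a, b, phi), c(31, 31))
    expect_equal(m1, brute_mask(cx, cy, a, b, phi, 31, 31))
    # central symmetry: phi and phi + 180 rasterize identically
    m2 <- rasterize_ellipse(ellipses(cx, cy, a, b, (phi + 180) %% 360), c(31, 31))
    expect_identical(m1, m2)
  }
})

test_that("rasterization clips to the frame and rejects bad axes", {
  e <- ellipses(cx = -100, cy = -100, a = 2, b = 2)
  expect_equal(sum(rasterize_ellipse(e, c(11, 11))), 0)
  bad <- tibble::tibble(cx = 1, cy = 1, a = -1, b = -2, phi = 0,
                        oriented = FALSE, depth = NA_integer_)
  expect_error(rasterize_ellipse(bad, c(11, 11)), "axes")
  expect_error(rasterize_ellipse(ellipses(1, 1, 2, 2), c(0, 5)), "image_size")
})

test_that("scaling multiplies axes only, and is invertible", {
  e <- ellipses(3, 4, 10, 4, 33, TRUE, 2L)
  half <- scale_ellipse(e, 0.5)
  expect_equal(c(half$a, half$b), c(5, 2))
  expect_equal(half[c("cx", "cy", "phi", "oriented", "depth")],
               e[c("cx", "cy", "phi", "oriented", "depth")])
  expect_equal(scale_ellipse(e, 1), e)
  expect_equal(scale_ellipse(scale_ellipse(e, 0.5), 2), e)
  expect_error(scale_ellipse(e, 0), "positive")
  expect_error(scale_ellipse(e, -2), "positive")
})

test_that("rasterization is monotone under scaling and area-consistent", {
  set.seed(7)
  for (i in 1:5) {
    a <- runif(1, 8, 14); b <- runif(1, 8, a)
    e <- ellipses(24, 24, a, b, runif(1, 0, 360))
    m_small <- rasterize_ellipse(scale_ellipse(e, 0.6), c(48, 48))
    m_big <- rasterize_ellipse(e, c(48, 48))
    expect_true(all(m_big[m_small])) # subset
    expect_lt(abs(sum(m_big) - pi * a * b) / (pi * a * b), 0.05)
  }
})

test_that("fit_ellipse recovers rasterized ellipses", {
  m <- rasterize_ellipse(ellipses(20, 15, 10, 4, 30), c(64, 64))
  idx <- which(m, arr.ind = TRUE)
  f <- fit_ellipse(data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1))
  expect_lt(sqrt((f$cx - 20)^2 + (f$cy - 15)^2), 0.5)
  expect_lt(abs(f$a - 10) / 10, 0.05)
  expect_lt(abs(f$b - 4) / 4, 0.05)
  expect_lt(axis_angle_diff(f$phi, 30), 2)
  expect_false(f$oriented)
})

test_that("fit_ellipse handles degenerate input", {
  expect_error(fit_ellipse(data.frame(row = c(0, 1, 2, 3), col = c(0, 1, 2, 3))),
               "at least 5")
  # collinear points cannot define an ellipse
  expect_error(fit_ellipse(data.frame(row = 0:9, col = 0:9)), "fit failed")
  # perfect circle: near-equal axes, any angle
  m <- rasterize_ellipse(ellipses(16, 16, 9, 9, 0), c(33, 33))
  idx <- which(m, arr.ind = TRUE)
  f <- fit_ellipse(data.frame(row = idx[, 1] - 1, col = idx[, 2] - 1))
  expect_lt(abs(f$a - f$b) / f$a, 0.02)
})

test_that("mask_iou counts intersection over union", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:4] <- TRUE # 8 px
  b <- matrix(FALSE, 4, 4); b[2:3, 1:4] <- TRUE # 8 px, overlap 4
  expect_equal(mask_iou(a, b), 4 / 12)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, matrix(FALSE, 4, 4)), 0)
  expect_equal(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_equal(mask_iou(a, b), mask_iou(b, a))
  expect_error(mask_iou(a, matrix(FALSE, 3, 3)), "identical dimensions")
})

test_that("ellipse_halves partitions the mask with ties to the front", {
  e <- ellipses(5, 5, 2, 2, 0)
  hv <- ellipse_halves(e, c(11, 11))
  full <- rasterize_ellipse(e, c(11, 11))
  # oracle for the axis-aligned circle: front = dx >= 0 (on-line to front)
  front_oracle <- full & matrix(0:10, 11, 11, byrow = TRUE) >= 5
  expect_identical(hv$front, front_oracle)
  expect_identical(hv$front | hv$back, full)
  expect_false(any(hv$front & hv$back))
  expect_equal(sum(hv$front), 9) # 4 with dx > 0 plus 5 on the line
  expect_equal(sum(hv$back), 4)

  # flipping phi by 180 swaps the halves, up to pixels numerically on the
  # dividing line (the tie rule sends those to the front on both sides)
  set.seed(13)
  for (i in 1:5) {
    e1 <- ellipses(24, 24, runif(1, 6, 12), runif(1, 3, 6), runif(1, 0, 360))
    h1 <- ellipse_halves(e1, c(48, 48))
    e2 <- e1; e2$phi <- (e2$phi + 180) %% 360
    h2 <- ellipse_halves(e2, c(48, 48))
    full <- rasterize_ellipse(e1, c(48, 48))
    expect_identical(h1$front | h1$back, full)
    expect_false(any(h1$front & h1$back))
    # back of the flipped ellipse is contained in the front of the original
    expect_true(all(h1$front[h2$back]))
    # pixels front on both sides must sit on the dividing line
    rad <- e1$phi * pi / 180
    proj <- (matrix(0:47, 48, 48, byrow = TRUE) - e1$cx) * cos(rad) +
      (matrix(0:47, 48, 48) - e1$cy) * sin(rad)
    both_front <- h1$front & h2$front
    if (any(both_front)) expect_lt(max(abs(proj[both_front])), 1e-9)
  }
})

test_that("annotation sets validate their invariants", {
  e <- ellipses(c(10, 30), c(10, 30), c(5, 6), c(3, 3), c(0, 90),
                oriented = TRUE, depth = c(0L, 1L))
  ann <- annotation_set("img1", 48, 64, e)
  expect_s3_class(ann, "annotation_set")
  expect_error(annotation_set("img1", 48, 64, ellipses(10, 10, 5, 3, 0, depth = NA)),
               "depth")
  dup <- ellipses(c(10, 30), c(10, 30), c(5, 6), c(3, 3), 0, depth = c(1L, 1L))
  expect_error(annotation_set("img1", 48, 64, dup), "unique")
  far <- ellipses(500, 10, 5, 3, 0, depth = 0L)
  expect_error(annotation_set("img1", 48, 64, far), "outside")
  # centre slightly outside is fine (partially visible animal)
  edge <- ellipses(-3, 10, 5, 3, 0, depth = 0L)
  expect_s3_class(annotation_set("img1", 48, 64, edge), "annotation_set")
})

test_that("annotation files round-trip losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  sets <- list(
    annotation_set("a", 48, 64, ellipses(
      cx = c(10.123456789, 30.5), cy = c(11.987654321, 20.25),
      a = c(8.5, 6.25), b = c(4.125, 3.5), phi = c(359.999, 12.3456789),
      oriented = c(TRUE, FALSE), depth = c(1L, 0L))),
    annotation_set("empty", 32, 32)
  )
  write_annotations(sets, path)
  back <- read_annotations(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$ellipses, sets[[1]]$ellipses, tolerance = 1e-12)
  expect_equal(back[[1]]$image_id, "a")
  expect_equal(back[[2]]$height, 32)
  expect_equal(nrow(back[[2]]$ellipses), 0)

  # empty list round trip
  write_annotations(list(), path)
  expect_length(read_annotations(path), 0)

  # missing field errors name the image and field
  jsonlite::write_json(
    list(list(image_id = "bad", height = 10, width = 10,
              ellipses = list(list(cx = 1, cy = 1, b = 1, phi = 0,
                                   oriented = FALSE, depth = 0)))),
    path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "bad.*'a'")
})

test_that("as_tibble flattens annotation sets", {
  ann <- annotation_set("x", 10, 20, ellipses(5, 5, 3, 2, 0, depth = 0L))
  tb <- as_tibble(ann)
  expect_equal(tb$image_id, "x")
  expect_equal(tb$width, 20)
  expect_equal(nrow(as_tibble(annotation_set("y", 5, 5))), 0)
})
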