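#' Configuration of the synthetic pen-scene generator
#'
#' The generator emulates the statistical structure of overhead pen
#' footage: elliptical animal bodies with a distinguishable (brighter) head
#' end, partial overlaps with known depth order, per-camera background
#' textures, grayscale night-vision frames, occasional blotchy lens-dirt
#' artifacts, and additive sensor noise. It does not attempt photorealism —
#' the algorithms, not the rendering, are under test.
#'
#' Defaults describe the study conditions at a 128 x 128 working size
#' (640 x 512 is supported): 3-8 animals per frame, about 30% of animals
#' partially overlapping a neighbour, roughly half of the frames in
#' night-vision mode, and axis ranges giving animals that cover roughly
#' 1-2% of the frame each, mirroring pen stocking densities.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_animals Inclusive range `c(min, max)` of animals per scene.
#' @param a_range,b_range Ranges for the semi-major and semi-minor axes, in
#'   pixels at `image_size`.
#' @param overlap_fraction Target fraction of animals that partially
#'   overlap another animal.
#' @param night_mode_prob Probability that a scene is a grayscale
#'   night-vision frame.
#' @param dirt_prob Probability of low-contrast lens-dirt blotches.
#' @param noise_sigma Standard deviation of additive Gaussian noise
#'   (intensities in `[0, 1]`).
#' @param head_fraction Major-axis fraction rendered as the bright head cap
#'   (kept consistent with [render_bodypart()]).
#' @param cameras Number of simulated cameras; backgrounds differ per
#'   camera and scenes cycle through them.
#' @param seed Base seed; `(cfg, index)` fully determines each scene.
#' @export
scene_config <- function(image_size = c(128, 128), n_animals = c(3, 8),
                         a_range = c(10, 18), b_range = c(5, 9),
                         overlap_fraction = 0.3, night_mode_prob = 0.5,
                         dirt_prob = 0.15, noise_sigma = 0.02,
                         head_fraction = 0.4, cameras = 5, seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            length(n_animals) == 2, n_animals[1] >= 0,
            n_animals[2] >= n_animals[1],
            all(a_range > 0), all(b_range > 0),
            a_range[2] >= a_range[1], b_range[2] >= b_range[1],
            b_range[1] <= a_range[2],
            overlap_fraction >= 0, overlap_fraction <= 1,
            night_mode_prob >= 0, night_mode_prob <= 1,
            dirt_prob >= 0, dirt_prob <= 1, noise_sigma >= 0,
            head_fraction > 0, head_fraction < 1, cameras >= 1)
  structure(list(
    image_size = as.integer(image_size), n_animals = as.integer(n_animals),
    a_range = a_range, b_range = b_range,
    overlap_fraction = overlap_fraction, night_mode_prob = night_mode_prob,
    dirt_prob = dirt_prob, noise_sigma = noise_sigma,
    head_fraction = head_fraction, cameras = as.integer(cameras),
    seed = as.integer(seed)
  ), class = "scene_config")
}

with_scene_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

scene_seed <- function(cfg, index) {
  (cfg$seed * 48271 + index * 9973) %% 2147483563L + 1L
}

# Smooth low-frequency texture: coarse uniform noise bilinearly upsampled.
smooth_noise <- function(h, w, cells, amplitude) {
  gh <- max(2, cells); gw <- max(2, cells)
  grid <- matrix(runif(gh * gw, -1, 1), gh, gw)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1); x0 <- pmin(floor(rx), gw - 1)
  fy <- ry - y0; fx <- rx - x0
  g00 <- grid[cbind(rep(y0, w), rep(x0, each = h))]
  g10 <- grid[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  g01 <- grid[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  g11 <- grid[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  fy_m <- rep(fy, w); fx_m <- rep(fx, each = h)
  v <- g00 * (1 - fy_m) * (1 - fx_m) + g10 * fy_m * (1 - fx_m) +
    g01 * (1 - fy_m) * fx_m + g11 * fy_m * fx_m
  matrix(v * amplitude, h, w)
}

# Deterministic per-camera appearance.
camera_palette <- function(camera) {
  bases <- list(
    c(0.32, 0.30, 0.26), c(0.38, 0.34, 0.28), c(0.28, 0.30, 0.32),
    c(0.36, 0.32, 0.34), c(0.30, 0.34, 0.26), c(0.34, 0.36, 0.32),
    c(0.26, 0.28, 0.24), c(0.40, 0.36, 0.34)
  )
  list(base = bases[[(camera - 1) %% length(bases) + 1]],
       cells = 4 + (camera - 1) %% 4)
}

#' Generate one synthetic pen scene
#'
#' Animals are placed by rejection sampling under an adaptive overlap
#' controller that steers the realized fraction of overlapping animals
#' towards `cfg$overlap_fraction` (overlapping pairs are constrained to a
#' mask IoU of roughly 0.03-0.35, so covered animals stay mostly visible).
#' Depth ranks are assigned at random, and animals are drawn farthest
#' first, with body shading, a darker rim, and a brighter head cap on the
#' `phi` side. Identical `(cfg, index)` always produce identical output.
#'
#' @param cfg A [scene_config()].
#' @param index 1-based scene index (drives the seed and the camera tag).
#' @return A `penseg_scene`: list with `image` (`h x w x 3` array in
#'   `[0, 1]`), `annotations` (an [annotation_set()]), `camera`, `night`,
#'   `index`.
#' @export
generate_scene <- function(cfg, index) {
  stopifnot(inherits(cfg, "scene_config"))
  h <- cfg$image_size[1]; w <- cfg$image_size[2]
  camera <- (index - 1L) %% cfg$cameras + 1L
  with_scene_seed(scene_seed(cfg, index), {
    n <- if (cfg$n_animals[2] == cfg$n_animals[1]) cfg$n_animals[1] else
      sample(cfg$n_animals[1]:cfg$n_animals[2], 1)
    night <- runif(1) < cfg$night_mode_prob
    dirty <- runif(1) < cfg$dirt_prob

    placed <- empty_ellipses()
    masks <- list()
    overlapped <- logical(0)
    target_overlapped <- round(cfg$overlap_fraction * n)
    for (i in seq_len(n)) {
      want_overlap <- nrow(placed) > 0 && sum(overlapped) < target_overlapped
      done <- FALSE
      for (attempt in seq_len(100)) {
        a <- runif(1, cfg$a_range[1], cfg$a_range[2])
        b <- runif(1, cfg$b_range[1], min(a, cfg$b_range[2]))
        phi <- runif(1, 0, 360)
        if (want_overlap) {
          pool <- which(!overlapped)
          if (length(pool) == 0) pool <- seq_len(nrow(placed))
          j <- pool[sample.int(length(pool), 1)]
          ang <- runif(1, 0, 2 * pi)
          dctr <- runif(1, 0.55, 0.95) * (placed$a[j] + a) / 2 +
            0.3 * (placed$b[j] + b) / 2
          cx <- placed$cx[j] + cos(ang) * dctr
          cy <- placed$cy[j] + sin(ang) * dctr
        } else {
          cx <- runif(1, a, w - 1 - a)
          cy <- runif(1, a, h - 1 - a)
        }
        if (cx < a || cx > w - 1 - a || cy < a || cy > h - 1 - a) next
        cand <- ellipses(cx, cy, a, b, phi, oriented = TRUE, depth = 0L)
        m <- rasterize_ellipse(cand, c(h, w))
        ious <- vapply(masks, function(mm) mask_iou(m, mm), 0)
        if (want_overlap) {
          if (ious[j] < 0.03 || ious[j] > 0.35) next
          if (any(ious[-j] > 0.35)) next
        } else {
          if (length(ious) > 0 && any(ious > 0)) next
        }
        placed <- dplyr::bind_rows(placed, cand)
        masks[[length(masks) + 1]] <- m
        new_overlapped <- ious > 0
        overlapped <- overlapped | new_overlapped
        overlapped <- c(overlapped, any(new_overlapped))
        done <- TRUE
        break
      }
      if (!done) {
        stop(sprintf(paste0("generate_scene: could not place animal %d/%d ",
                            "within 100 attempts (frame %dx%d, overlap target %.2f)"),
                     i, n, h, w, cfg$overlap_fraction), call. = FALSE)
      }
    }
    if (nrow(placed) > 0) placed$depth <- sample(0:(n - 1))
    ann <- annotation_set(sprintf("scene_%05d", index), h, w, placed)

    pal <- camera_palette(camera)
    img <- array(0, c(h, w, 3))
    tex <- smooth_noise(h, w, pal$cells, 0.06) + smooth_noise(h, w, 12, 0.03)
    for (k in 1:3) img[, , k] <- pal$base[k] + tex

    if (n > 0) {
      body_rgb <- c(0.78, 0.62, 0.58) + runif(3, -0.03, 0.03)
      for (i in order(placed$depth, decreasing = TRUE)) {
        e <- placed[i, ]
        fr <- ellipse_frame(e, c(h, w))
        if (is.null(fr)) next
        inside <- (fr$xp / e$a)^2 + (fr$yp / e$b)^2 <= 1
        rr <- (fr$xp / e$a)^2 + (fr$yp / e$b)^2
        shade <- 1 - 0.18 * abs(fr$yp) / e$b # rounded-back shading
        rim <- rr > 0.78
        headcap <- fr$xp > e$a * (1 - 2 * cfg$head_fraction)
        tint <- 1 + runif(1, -0.06, 0.06)
        for (k in 1:3) {
          ch <- img[fr$rows + 1, fr$cols + 1, k]
          val <- body_rgb[k] * tint * shade
          val[rim] <- val[rim] * 0.8
          val[headcap] <- pmin(1, val[headcap] * 1.3)
          ch[inside] <- val[inside]
          img[fr$rows + 1, fr$cols + 1, k] <- ch
        }
      }
    }

    if (dirty) {
      n_blotch <- sample(1:3, 1)
      for (bl in seq_len(n_blotch)) {
        bx <- runif(1, 0, w - 1); by <- runif(1, 0, h - 1)
        br <- runif(1, 0.15, 0.35) * min(h, w)
        dy <- matrix(0:(h - 1), h, w) - by
        dx <- matrix(0:(w - 1), h, w, byrow = TRUE) - bx
        wgt <- exp(-(dx^2 + dy^2) / (2 * br^2)) * 0.45
        for (k in 1:3) img[, , k] <- img[, , k] * (1 - wgt) + 0.5 * wgt
      }
    }

    if (night) {
      lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
      lum <- 0.15 + 0.85 * lum # active IR lifts the black level
      for (k in 1:3) img[, , k] <- lum
    }

    if (cfg$noise_sigma > 0) {
      img <- img + array(rnorm(length(img), 0, cfg$noise_sigma), dim(img))
    }
    img[img < 0] <- 0; img[img > 1] <- 1

    structure(list(image = img, annotations = ann, camera = camera,
                   night = night, index = index),
              class = "penseg_scene")
  })
}

#' @export
print.penseg_scene <- function(x, ...) {
  cat(sprintf("<penseg_scene> %s: %dx%d, %d animal(s), camera %d%s\n",
              x$annotations$image_id, dim(x$image)[1], dim(x$image)[2],
              nrow(x$annotations$ellipses), x$camera,
              if (x$night) ", night vision" else ""))
  invisible(x)
}

#' Plot a synthetic scene with its annotations
#'
#' @param object A `penseg_scene`.
#' @param ... Unused.
#' @return A ggplot object (image raster with ellipse outlines and head
#'   direction arrows).
#' @export
autoplot.penseg_scene <- function(object, ...) {
  img <- object$image
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- tibble::tibble(
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), w),
    fill = grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                          as.vector(img[, , 3]))
  )
  e <- object$annotations$ellipses
  outline <- NULL
  if (nrow(e) > 0) {
    ts <- seq(0, 2 * pi, length.out = 73)
    outline <- purrr::map_dfr(seq_len(nrow(e)), function(i) {
      ang <- e$phi[i] * pi / 180
      tibble::tibble(
        id = i,
        x = e$cx[i] + e$a[i] * cos(ts) * cos(ang) - e$b[i] * sin(ts) * sin(ang),
        y = e$cy[i] + e$a[i] * cos(ts) * sin(ang) + e$b[i] * sin(ts) * cos(ang)
      )
    })
  }
  p <- ggplot2::ggplot(px, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(outline)) {
    p <- p + ggplot2::geom_path(
      data = outline,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id),
      colour = "yellow", linewidth = 0.4, inherit.aes = FALSE)
  }
  p
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` PNG frames, one annotation JSON (schema of
#' [write_annotations()]) and a manifest JSON echoing the configuration and
#' listing per-image camera tags, seeds and split assignment. Scenes cycle
#' over the configured cameras; the last camera is declared the test split
#' (held-out pen protocol), the second-to-last validation, the rest
#' training.
#'
#' @param cfg A [scene_config()].
#' @param n_images Number of scenes.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (one row per image) with the config in
#'   attribute `"config"`; also written to `manifest.json`.
#' @export
generate_dataset <- function(cfg, n_images, out_dir) {
  stopifnot(inherits(cfg, "scene_config"), n_images >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  rows <- vector("list", n_images)
  sets <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sc <- generate_scene(cfg, i)
    file <- file.path("images", sprintf("%s.png", sc$annotations$image_id))
    png::writePNG(sc$image, file.path(out_dir, file))
    split <- camera_split(sc$camera, cfg$cameras)
    rows[[i]] <- tibble::tibble(
      image_id = sc$annotations$image_id, file = file,
      camera = sc$camera, split = split, night = sc$night,
      seed = scene_seed(cfg, i)
    )
    sets[[i]] <- sc$annotations
  }
  write_annotations(sets, file.path(out_dir, "annotations.json"))
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    list(config = unclass(cfg), images = manifest),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  attr(manifest, "config") <- cfg
  manifest
}

camera_split <- function(camera, cameras) {
  if (cameras == 1) return("train")
  if (camera == cameras) return("test")
  if (cameras >= 3 && camera == cameras - 1) return("validation")
  "train"
}
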