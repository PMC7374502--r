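#' Ellipse annotation records
#'
#' Individual animals are annotated as ellipses: centre `(cx, cy)` in
#' continuous 0-based pixel coordinates (x to the right along columns, y down
#' along rows), semi-major/minor axes `a >= b > 0` in pixels, and an
#' orientation `phi` in degrees within `[0, 360)` measured from the +x axis
#' towards +y (i.e. visually clockwise on screen since y points down). When
#' `oriented` is `TRUE`, `phi` points from the centre towards the head end of
#' the animal; otherwise only `phi` modulo 180 (the major-axis line) is
#' meaningful. `depth` is an integer rank along the camera axis, 0 = closest
#' to the camera, used to resolve occlusions when labels are rendered.
#'
#' `ellipses()` builds a validated tibble with one row per ellipse; all
#' geometry functions in the package take and return this representation.
#'
#' @param cx,cy Centre coordinates (0-based pixels).
#' @param a,b Semi-major and semi-minor axis lengths in pixels (`a >= b > 0`).
#' @param phi Orientation in degrees; normalised into `[0, 360)`.
#' @param oriented Logical; is the head direction of `phi` meaningful?
#' @param depth Integer depth rank (0 = topmost). `NA` allowed for detections.
#' @return A tibble with columns `cx, cy, a, b, phi, oriented, depth`.
#' @examples
#' e <- ellipses(cx = 20, cy = 15, a = 10, b = 4, phi = 30, oriented = TRUE)
#' mask <- rasterize_ellipse(e, c(32, 48))
#' sum(mask)
#' @export
ellipses <- function(cx, cy, a, b, phi = 0, oriented = FALSE, depth = NA_integer_) {
  out <- tibble::tibble(
    cx = as.double(cx), cy = as.double(cy),
    a = as.double(a), b = as.double(b),
    phi = as.double(phi) %% 360,
    oriented = as.logical(oriented),
    depth = as.integer(depth)
  )
  validate_ellipses(out)
  out
}

#' @rdname ellipses
#' @param e A tibble of ellipse records.
#' @export
validate_ellipses <- function(e) {
  req <- c("cx", "cy", "a", "b", "phi", "oriented", "depth")
  missing <- setdiff(req, names(e))
  if (length(missing) > 0) {
    stop("invalid ellipse table: missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(e) == 0) return(invisible(e))
  if (any(!is.finite(e$a)) || any(!is.finite(e$b)) || any(e$b <= 0)) {
    stop("invalid ellipse: axes must be finite and positive", call. = FALSE)
  }
  if (any(e$a < e$b)) {
    stop("invalid ellipse: requires a >= b (semi-major first)", call. = FALSE)
  }
  if (any(e$phi < 0 | e$phi >= 360)) {
    stop("invalid ellipse: phi must lie in [0, 360)", call. = FALSE)
  }
  if (any(!is.na(e$depth) & e$depth < 0)) {
    stop("invalid ellipse: depth rank must be >= 0", call. = FALSE)
  }
  invisible(e)
}

# Coordinates of every pixel centre in the ellipse's own frame, restricted to
# the axis-aligned bounding box clipped to the image. Returns NULL when the
# box misses the frame entirely. xp points towards phi (the head end).
ellipse_frame <- function(e, image_size) {
  h <- image_size[1]; w <- image_size[2]
  rad <- e$a
  r0 <- max(0, floor(e$cy - rad)); r1 <- min(h - 1, ceiling(e$cy + rad))
  c0 <- max(0, floor(e$cx - rad)); c1 <- min(w - 1, ceiling(e$cx + rad))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  ang <- e$phi * pi / 180
  dx <- matrix(cols, length(rows), length(cols), byrow = TRUE) - e$cx
  dy <- matrix(rows, length(rows), length(cols)) - e$cy
  list(
    rows = rows, cols = cols,
    xp = dx * cos(ang) + dy * sin(ang),
    yp = -dx * sin(ang) + dy * cos(ang)
  )
}

empty_ellipses <- function() {
  ellipses(cx = double(), cy = double(), a = double(), b = double())
}

check_image_size <- function(image_size) {
  if (length(image_size) != 2 || any(!is.finite(image_size)) || any(image_size < 1)) {
    stop("image_size must be two positive integers (height, width)", call. = FALSE)
  }
  as.integer(image_size)
}

#' Rasterize an ellipse to a binary pixel mask
#'
#' A pixel at (row r, col c), 0-based, is inside iff its centre (x = c, y = r)
#' satisfies the closed interior inequality
#' \eqn{(x'/a)^2 + (y'/b)^2 \le 1} after rotation/translation into the
#' ellipse frame. Pixels outside the image are clipped.
#'
#' @param e One-row ellipse tibble (see [ellipses()]).
#' @param image_size `c(height, width)` in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_ellipse <- function(e, image_size) {
  image_size <- check_image_size(image_size)
  stopifnot(nrow(e) == 1)
  if (!is.finite(e$a) || !is.finite(e$b) || e$a <= 0 || e$b <= 0) {
    stop("invalid ellipse: axes must be positive", call. = FALSE)
  }
  mask <- matrix(FALSE, image_size[1], image_size[2])
  fr <- ellipse_frame(e, image_size)
  if (is.null(fr)) return(mask)
  inside <- (fr$xp / e$a)^2 + (fr$yp / e$b)^2 <= 1
  mask[fr$rows + 1, fr$cols + 1] <- inside
  mask
}

#' Scale an ellipse about its centre
#'
#' Multiplies both semi-axes by `factor`, leaving centre, orientation and
#' depth untouched. Used to derive the inner-core class (axes scaled down,
#' default to 50%) and to scale fitted core ellipses back up by `1/factor`.
#'
#' @param e Ellipse tibble (any number of rows).
#' @param factor Positive scale factor applied to both axes.
#' @return Ellipse tibble of the same shape.
#' @export
scale_ellipse <- function(e, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    stop("scale factor must be a single positive number", call. = FALSE)
  }
  e$a <- e$a * factor
  e$b <- e$b * factor
  e
}

#' Direct least-squares ellipse fit (Fitzgibbon)
#'
#' Fits an ellipse outline to a filled pixel blob (e.g. the pixels of a
#' segmented instance). The conic fit constrained to an ellipse by the
#' direct least-squares method of Fitzgibbon et al. (numerically stable
#' Halir-Flusser formulation) is computed on unbiased boundary samples —
#' the midpoints between 4-adjacent inside/outside pixel pairs of the
#' hole-filled set (an algebraic fit through a solid region would shrink
#' the axes by about \eqn{1/\sqrt 2}, and inner-boundary pixel centres sit
#' half a pixel inside the true outline). By default the parameters are
#' then polished by a local area-matching step (Nelder-Mead on the five
#' parameters, matching a smoothed inside-indicator against the pixel
#' mask), which brings centre and axis errors on rasterize-and-refit round
#' trips well below half a pixel. The result has `a >= b` enforced
#' (swapping axes rotates `phi` by 90 degrees) and `phi` reported modulo
#' 180 with `oriented = FALSE`.
#'
#' @param pixels Matrix or data frame with columns `row`, `col` (0-based
#'   pixel coordinates), at least 5 distinct non-collinear points.
#' @param refine Run the area-matching polish after the direct fit?
#' @return One-row ellipse tibble (`oriented = FALSE`, `depth = NA`).
#' @export
fit_ellipse <- function(pixels, refine = TRUE) {
  pixels <- as.data.frame(pixels)
  if (!all(c("row", "col") %in% names(pixels))) {
    if (ncol(pixels) >= 2) names(pixels)[1:2] <- c("row", "col")
  }
  pts <- unique(pixels[, c("row", "col")])
  if (nrow(pts) < 5) {
    stop("ellipse fit failed: need at least 5 distinct points", call. = FALSE)
  }
  bd <- blob_geometry(pts)
  x <- bd$boundary$col; y <- bd$boundary$row
  mx <- mean(x); my <- mean(y)
  xc <- x - mx; yc <- y - my

  fit <- tryCatch({
    D1 <- cbind(xc^2, xc * yc, yc^2)
    D2 <- cbind(xc, yc, 1)
    S1 <- crossprod(D1)
    S2 <- crossprod(D1, D2)
    S3 <- crossprod(D2)
    Tm <- -solve(S3, t(S2))
    M <- S1 + S2 %*% Tm
    M2 <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
    ev <- eigen(M2)
    vals <- ev$values; vecs <- ev$vectors
    ok <- abs(Im(vals)) < 1e-8
    vecs <- Re(vecs); vals <- Re(vals)
    cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
    pick <- which(ok & cond > 0)
    if (length(pick) == 0) stop("no elliptical solution")
    pick <- pick[1]
    a1 <- vecs[, pick]
    c(a1, as.vector(Tm %*% a1))
  }, error = function(err) {
    stop("ellipse fit failed: degenerate point configuration (",
         conditionMessage(err), ")", call. = FALSE)
  })

  geom <- conic_to_geometric(fit)
  if (is.null(geom)) {
    stop("ellipse fit failed: conic is not a finite ellipse", call. = FALSE)
  }
  geom$cx <- geom$cx + mx
  geom$cy <- geom$cy + my
  if (refine) geom <- refine_ellipse_fit(geom, bd)
  ellipses(
    cx = geom$cx, cy = geom$cy,
    a = geom$a, b = geom$b, phi = geom$phi %% 180,
    oriented = FALSE, depth = NA_integer_
  )
}

# Hole-filled local mask of a pixel set plus unbiased boundary samples:
# midpoints between 4-adjacent inside/outside pixel-centre pairs.
blob_geometry <- function(pts) {
  r0 <- min(pts$row); c0 <- min(pts$col)
  h <- max(pts$row) - r0 + 3L # one-pixel pad on every side
  w <- max(pts$col) - c0 + 3L
  mask <- matrix(FALSE, h, w)
  mask[cbind(pts$row - r0 + 2L, pts$col - c0 + 2L)] <- TRUE
  comp <- .cc_label8(!mask)
  outside <- unique(c(comp[1, ], comp[h, ], comp[, 1], comp[, w]))
  outside <- outside[outside > 0]
  filled <- mask | !(comp %in% outside)
  dim(filled) <- dim(mask)
  ii <- which(filled, arr.ind = TRUE)
  mids <- NULL
  for (s in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- cbind(ii[, 1] + s[1], ii[, 2] + s[2])
    out <- !filled[nb]
    if (any(out)) {
      mids <- rbind(mids, cbind((ii[out, 1] + nb[out, 1]) / 2,
                                (ii[out, 2] + nb[out, 2]) / 2))
    }
  }
  boundary <- if (is.null(mids) || nrow(mids) < 5) {
    data.frame(row = pts$row, col = pts$col)
  } else {
    data.frame(row = mids[, 1] + r0 - 2L, col = mids[, 2] + c0 - 2L)
  }
  list(boundary = boundary, filled = filled, row0 = r0 - 2L, col0 = c0 - 2L)
}

# Local polish: minimise the squared mismatch between a smoothed ellipse
# inside-indicator and the filled pixel mask.
refine_ellipse_fit <- function(geom, bd) {
  tgt <- bd$filled * 1
  h <- nrow(tgt); w <- ncol(tgt)
  X <- matrix(bd$col0 + seq_len(w), h, w, byrow = TRUE) # local index i (1-based)
  Y <- matrix(bd$row0 + seq_len(h), h, w)               # maps to col0/row0 + i
  obj <- function(p) {
    if (p[3] <= 0.5 || p[4] <= 0.5) return(1e10)
    ang <- p[5] * pi / 180
    dx <- X - p[1]; dy <- Y - p[2]
    xp <- dx * cos(ang) + dy * sin(ang)
    yp <- -dx * sin(ang) + dy * cos(ang)
    s <- 1 - ((xp / p[3])^2 + (yp / p[4])^2)
    # slope 4: transition half-width ~ axis/8, sharp enough to resolve the
    # smallest animals without losing the smooth gradient
    cov <- pmin(1, pmax(0, 0.5 + 4 * s))
    sum((cov - tgt)^2)
  }
  start <- c(geom$cx, geom$cy, geom$a, geom$b, geom$phi)
  o <- tryCatch({
    o1 <- stats::optim(start, obj, control = list(maxit = 400, reltol = 1e-10))
    # restart with a fresh simplex: Nelder-Mead collapses occasionally and a
    # second pass costs little while tightening the worst cases
    stats::optim(o1$par, obj, control = list(maxit = 400, reltol = 1e-10))
  }, error = function(err) NULL)
  if (is.null(o) || any(!is.finite(o$par)) || o$par[3] <= 0 || o$par[4] <= 0) {
    return(geom)
  }
  p <- o$par
  if (p[4] > p[3]) { # keep a >= b, rotating by 90 degrees
    p[3:4] <- p[4:3]
    p[5] <- p[5] + 90
  }
  list(cx = p[1], cy = p[2], a = p[3], b = p[4], phi = p[5] %% 180)
}

# Conic coefficients c(A,B,C,D,E,F) for Ax^2+Bxy+Cy^2+Dx+Ey+F=0 -> centre,
# semi-axes and major-axis angle in [0, 180). NULL when not a finite ellipse.
conic_to_geometric <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; F <- k[6]
  den <- 4 * A * C - B^2
  if (!is.finite(den) || den <= 0) return(NULL)
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  val <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  lam <- eg$values
  if (val > 0) { lam <- -lam; val <- -val }
  if (any(lam <= 0) || val >= 0) return(NULL)
  # semi-axis^2 = -val / lambda; the smaller eigenvalue gives the major axis
  imaj <- which.min(lam)
  a_len <- sqrt(-val / lam[imaj])
  b_len <- sqrt(-val / lam[3 - imaj])
  v_major <- eg$vectors[, imaj]
  phi <- (atan2(v_major[2], v_major[1]) * 180 / pi) %% 180
  if (!all(is.finite(c(cx, cy, a_len, b_len, phi)))) return(NULL)
  list(cx = cx, cy = cy, a = a_len, b = b_len, phi = phi)
}

#' Intersection over union of two binary masks
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of identical size.
#' @return `|A and B| / |A or B|`, defined as 0 when the union is empty.
#' @export
mask_iou <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("mask_iou: masks must have identical dimensions", call. = FALSE)
  }
  a <- mask_a != 0
  b <- mask_b != 0
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

#' Split a rasterized ellipse into front and back halves
#'
#' Partitions the rasterization of `e` by the minor-axis line through the
#' centre. The front half lies in the direction of `phi` (towards the head
#' when oriented); pixels exactly on the dividing line are assigned to the
#' front. The two halves are disjoint and their union is the full mask.
#'
#' @inheritParams rasterize_ellipse
#' @return List with logical matrices `front` and `back`.
#' @export
ellipse_halves <- function(e, image_size) {
  image_size <- check_image_size(image_size)
  stopifnot(nrow(e) == 1)
  if (!is.finite(e$a) || !is.finite(e$b) || e$a <= 0 || e$b <= 0) {
    stop("invalid ellipse: axes must be positive", call. = FALSE)
  }
  front <- matrix(FALSE, image_size[1], image_size[2])
  back <- front
  fr <- ellipse_frame(e, image_size)
  if (is.null(fr)) return(list(front = front, back = back))
  inside <- (fr$xp / e$a)^2 + (fr$yp / e$b)^2 <= 1
  front[fr$rows + 1, fr$cols + 1] <- inside & fr$xp >= 0
  back[fr$rows + 1, fr$cols + 1] <- inside & fr$xp < 0
  list(front = front, back = back)
}

#' Per-image annotation sets
#'
#' An annotation set bundles the ellipses of one image with the image
#' identity and size. Depth ranks must be unique within a set, and each
#' centre may lie outside the frame by at most `max(a, b)` so that partially
#' visible animals remain representable.
#'
#' @param image_id Character image identifier.
#' @param height,width Image size in pixels.
#' @param ellipses Ellipse tibble (see [ellipses()]); may have zero rows.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, height, width, ellipses = empty_ellipses()) {
  validate_ellipses(ellipses)
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1 || width < 1) stop("image size must be positive", call. = FALSE)
  if (nrow(ellipses) > 0) {
    if (anyNA(ellipses$depth)) {
      stop("annotation_set: every ellipse needs a depth rank", call. = FALSE)
    }
    if (anyDuplicated(ellipses$depth)) {
      stop("annotation_set: depth ranks must be unique within an image", call. = FALSE)
    }
    slack <- pmax(ellipses$a, ellipses$b)
    if (any(ellipses$cx < -slack | ellipses$cx > width - 1 + slack |
              ellipses$cy < -slack | ellipses$cy > height - 1 + slack)) {
      stop("annotation_set: ellipse centre too far outside the image frame",
           call. = FALSE)
    }
  }
  structure(
    list(image_id = as.character(image_id), height = height, width = width,
         ellipses = ellipses),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s (%d x %d), %d ellipse(s)\n",
              x$image_id, x$height, x$width, nrow(x$ellipses)))
  if (nrow(x$ellipses) > 0) print(x$ellipses)
  invisible(x)
}

#' @export
as_tibble.annotation_set <- function(x, ...) {
  if (nrow(x$ellipses) == 0) {
    return(tibble::tibble(image_id = character(), height = integer(),
                          width = integer(), cx = double(), cy = double(),
                          a = double(), b = double(), phi = double(),
                          oriented = logical(), depth = integer()))
  }
  dplyr::bind_cols(
    tibble::tibble(image_id = x$image_id, height = x$height, width = x$width),
    x$ellipses
  )
}

#' Read and write annotation files
#'
#' Annotations are stored as JSON: a top-level list of objects
#' `{"image_id", "height", "width", "ellipses": [{"cx","cy","a","b","phi",
#' "oriented","depth"}]}` with 0-based depth ranks (0 = topmost). The round
#' trip is lossless to full double precision.
#'
#' @param path File path.
#' @param sets A list of [annotation_set()] objects (a single set is
#'   wrapped automatically).
#' @return `read_annotations()` returns a list of `annotation_set`s;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    id <- if (is.null(rec$image_id)) "<unknown>" else rec$image_id
    for (fld in c("image_id", "height", "width", "ellipses")) {
      if (is.null(rec[[fld]])) {
        stop(sprintf("annotation parse error in image '%s': missing field '%s'",
                     id, fld), call. = FALSE)
      }
    }
    ell <- rec$ellipses
    cols <- c("cx", "cy", "a", "b", "phi", "oriented", "depth")
    parsed <- lapply(ell, function(er) {
      for (fld in cols) {
        if (is.null(er[[fld]])) {
          stop(sprintf("annotation parse error in image '%s': ellipse missing field '%s'",
                       id, fld), call. = FALSE)
        }
      }
      er[cols]
    })
    e <- if (length(parsed) == 0) {
      ellipses(cx = double(), cy = double(), a = double(), b = double())
    } else {
      ellipses(
        cx = vapply(parsed, function(p) as.double(p$cx), 0),
        cy = vapply(parsed, function(p) as.double(p$cy), 0),
        a = vapply(parsed, function(p) as.double(p$a), 0),
        b = vapply(parsed, function(p) as.double(p$b), 0),
        phi = vapply(parsed, function(p) as.double(p$phi), 0),
        oriented = vapply(parsed, function(p) as.logical(p$oriented), TRUE),
        depth = vapply(parsed, function(p) as.integer(p$depth), 1L)
      )
    }
    annotation_set(rec$image_id, rec$height, rec$width, e)
  })
}

#' @rdname read_annotations
#' @export
write_annotations <- function(sets, path) {
  if (inherits(sets, "annotation_set")) sets <- list(sets)
  payload <- lapply(sets, function(s) {
    stopifnot(inherits(s, "annotation_set"))
    ell <- s$ellipses
    list(
      image_id = s$image_id,
      height = s$height,
      width = s$width,
      ellipses = if (nrow(ell) == 0) list() else
        lapply(seq_len(nrow(ell)), function(i) list(
          cx = ell$cx[i], cy = ell$cy[i], a = ell$a[i], b = ell$b[i],
          phi = ell$phi[i], oriented = ell$oriented[i], depth = ell$depth[i]
        ))
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
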