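#' Hinge (positive part)
#'
#' `hinge(x) = max(0, x)`, written elementwise. The discriminative loss
#' hinges its variance and distance terms at the margins `delta_v` and
#' `delta_d` before squaring.
#'
#' @param x Numeric vector or array.
#' @export
hinge <- function(x) pmax(0, x)

LOSS_EPS <- 1e-7

#' Binary cross-entropy over a probability map
#'
#' Mean of `-(y * log p + (1 - y) * log(1 - p))` over all pixels, with
#' probabilities clamped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param p Numeric matrix of foreground probabilities in `[0, 1]`.
#' @param y Binary label matrix (0 = background, 1 = foreground) of the
#'   same dimensions.
#' @return A single non-negative number.
#' @export
binary_cross_entropy <- function(p, y) {
  if (!all(dim(p) == dim(y))) {
    stop("binary_cross_entropy: prediction and label shapes differ", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = FALSE)) {
    stop("binary_cross_entropy: probabilities must lie in [0, 1]", call. = FALSE)
  }
  pc <- pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Categorical cross-entropy over per-pixel class distributions
#'
#' Mean over pixels of `-sum_j t_ij * log(x_ij)` for `C >= 2` classes, with
#' the same probability clamping as [binary_cross_entropy()]. `t` must be
#' one-hot at every pixel.
#'
#' @param x `h x w x C` array of class probabilities (summing to ~1 per pixel).
#' @param t `h x w x C` one-hot target array.
#' @return A single non-negative number.
#' @export
categorical_cross_entropy <- function(x, t) {
  if (length(dim(x)) != 3 || !all(dim(x) == dim(t))) {
    stop("categorical_cross_entropy: x and t must be h x w x C arrays of equal shape",
         call. = FALSE)
  }
  if (dim(x)[3] < 2) {
    stop("categorical_cross_entropy: need at least 2 classes", call. = FALSE)
  }
  if (!all(t %in% c(0, 1)) || !all(abs(apply(t, c(1, 2), sum) - 1) < 1e-12)) {
    stop("categorical_cross_entropy: t must be one-hot at every pixel", call. = FALSE)
  }
  n <- dim(x)[1] * dim(x)[2]
  xc <- pmin(pmax(x, LOSS_EPS), 1 - LOSS_EPS)
  -sum(t * log(xc)) / n
}

#' One-hot encode an integer class map
#'
#' @param map Integer matrix with values in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (channels).
#' @return `h x w x n_classes` 0/1 array.
#' @export
one_hot_map <- function(map, n_classes) {
  stopifnot(all(map >= 0), all(map < n_classes))
  out <- array(0, c(dim(map), n_classes))
  for (k in seq_len(n_classes)) out[, , k] <- (map == (k - 1)) * 1
  out
}

#' Configuration of the discriminative embedding loss
#'
#' Margins and weights of the pull/push/regularisation terms: pixels of one
#' instance are pulled to within `delta_v` (L1) of their mean embedding,
#' instance means are pushed to at least `2 * delta_d` apart, and a small
#' `gamma`-weighted term keeps the means near the origin. Defaults follow
#' the study configuration: `delta_v = 0.1`, `delta_d = 1.5`,
#' `alpha = beta = 1`, `gamma = 0.001`, L1 norm, with the background treated
#' as one of the instances (postprocessing removes it via the foreground
#' mask).
#'
#' @param delta_v,delta_d Positive hinge margins.
#' @param alpha,beta,gamma Non-negative term weights.
#' @param include_background Treat background (id 0) as an instance?
#' @export
discriminative_config <- function(delta_v = 0.1, delta_d = 1.5, alpha = 1,
                                  beta = 1, gamma = 0.001,
                                  include_background = TRUE) {
  stopifnot(delta_v > 0, delta_d > 0, alpha >= 0, beta >= 0, gamma >= 0)
  structure(list(delta_v = delta_v, delta_d = delta_d, alpha = alpha,
                 beta = beta, gamma = gamma,
                 include_background = isTRUE(include_background)),
            class = "discriminative_config")
}

#' Discriminative pixel-embedding loss
#'
#' For `C` instances with pixel embeddings `x_i` and per-instance means
#' `mu_c` (L1 norm throughout, hinge `[z]+ = max(0, z)` squared after
#' clipping):
#' \deqn{L_{reg} = \frac{1}{C}\sum_c \|\mu_c\|_1}
#' \deqn{L_{var} = \frac{1}{C}\sum_c \frac{1}{N_c}\sum_i
#'   [\|\mu_c - x_i\|_1 - \delta_v]_+^2}
#' \deqn{L_{dist} = \frac{1}{C(C-1)}\sum_{c_A \ne c_B}
#'   [2\delta_d - \|\mu_{c_A} - \mu_{c_B}\|_1]_+^2}
#' \deqn{L = \alpha L_{var} + \beta L_{dist} + \gamma L_{reg}}
#' `L_dist` is defined as 0 when `C < 2`. The background counts as an
#' instance when `cfg$include_background` is `TRUE` and background pixels
#' exist; relabelling instance ids never changes the result.
#'
#' @param emb `h x w x D` numeric array of pixel embeddings.
#' @param instance_map Integer `h x w` matrix (0 = background).
#' @param cfg A [discriminative_config()].
#' @return List with `loss`, `var`, `dist`, `reg` and `stats` (tibble of
#'   instance id, pixel count and mean embedding).
#' @export
discriminative_loss <- function(emb, instance_map, cfg = discriminative_config()) {
  comp <- disc_components(emb, instance_map, cfg)
  list(
    loss = cfg$alpha * comp$var + cfg$beta * comp$dist + cfg$gamma * comp$reg,
    var = comp$var, dist = comp$dist, reg = comp$reg,
    stats = tibble::tibble(id = comp$ids, n = comp$counts,
                           mu = lapply(seq_len(nrow(comp$mu)),
                                       function(i) comp$mu[i, ]))
  )
}

# Shared core for loss and gradient: groups pixels, computes means and the
# three raw terms, and keeps intermediates for the backward pass.
disc_components <- function(emb, instance_map, cfg) {
  d <- dim(emb)
  if (length(d) != 3 || !all(d[1:2] == dim(instance_map))) {
    stop("discriminative_loss: embedding must be h x w x D matching the instance map",
         call. = FALSE)
  }
  if (any(!is.finite(emb))) {
    stop("discriminative_loss: embeddings must be finite", call. = FALSE)
  }
  lab <- as.integer(instance_map)
  X <- matrix(emb, d[1] * d[2], d[3])
  keep <- rep(TRUE, length(lab))
  if (!cfg$include_background) keep <- lab > 0L
  lab <- lab[keep]
  X <- X[keep, , drop = FALSE]
  if (length(lab) == 0) {
    stop("discriminative_loss: no pixels to evaluate", call. = FALSE)
  }
  ids <- sort(unique(lab))
  C <- length(ids)
  g <- match(lab, ids)
  counts <- tabulate(g, C)
  if (any(counts < 1)) {
    stop("discriminative_loss: instance with zero pixels", call. = FALSE)
  }
  mu <- rowsum(X, g) / counts

  # variance term
  diff <- mu[g, , drop = FALSE] - X
  d1 <- rowSums(abs(diff))
  hv <- pmax(0, d1 - cfg$delta_v)
  var_term <- sum(hv^2 / counts[g]) / C

  # distance term
  if (C >= 2) {
    dm <- as.matrix(dist(mu, method = "manhattan"))
    hd <- pmax(2 * cfg$delta_d - dm, 0) # matrix first: pmax keeps its dim

    diag(hd) <- 0
    dist_term <- sum(hd^2) / (C * (C - 1))
  } else {
    dm <- NULL
    hd <- NULL
    dist_term <- 0
  }

  reg_term <- sum(abs(mu)) / C

  list(ids = ids, counts = counts, mu = mu, g = g, keep = keep, X = X,
       diff = diff, hv = hv, hd = hd, C = C, dims = d,
       var = var_term, dist = dist_term, reg = reg_term)
}

#' @rdname discriminative_loss
#' @return `discriminative_loss_grad()` additionally returns `grad`, the
#'   `h x w x D` gradient of the weighted loss with respect to the
#'   embeddings (including the dependence of the means on the pixels).
#' @export
discriminative_loss_grad <- function(emb, instance_map,
                                     cfg = discriminative_config()) {
  comp <- disc_components(emb, instance_map, cfg)
  C <- comp$C
  g <- comp$g
  counts <- comp$counts
  D <- ncol(comp$mu)

  sgn <- sign(comp$diff) # sign(mu_c - x_i), per kept pixel
  fac <- 2 * comp$hv / (C * counts[g])
  gX_var <- -fac * sgn # direct dL_var / dx_i
  gmu_var <- rowsum(fac * sgn, g) # dL_var / dmu_c

  gmu_reg <- sign(comp$mu) / C

  gmu_dist <- matrix(0, C, D)
  if (C >= 2) {
    for (cc in seq_len(C)) {
      others <- setdiff(seq_len(C), cc)
      s <- sign(matrix(comp$mu[cc, ], length(others), D, byrow = TRUE) -
                  comp$mu[others, , drop = FALSE])
      coef <- 2 * comp$hd[cc, others] # ordered pairs (cc,.) and (.,cc) combined
      gmu_dist[cc, ] <- colSums(-2 * coef * s) / (C * (C - 1))
    }
  }

  gmu <- cfg$alpha * gmu_var + cfg$beta * gmu_dist + cfg$gamma * gmu_reg
  gX <- cfg$alpha * gX_var + gmu[g, , drop = FALSE] / counts[g]

  grad_full <- matrix(0, prod(comp$dims[1:2]), D)
  grad_full[comp$keep, ] <- gX
  list(
    loss = cfg$alpha * comp$var + cfg$beta * comp$dist + cfg$gamma * comp$reg,
    var = comp$var, dist = comp$dist, reg = comp$reg,
    grad = array(grad_full, comp$dims)
  )
}
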