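# Independent brute-force oracles used across the tests. These deliberately
# re-derive results with naive loops / enumeration so the implementation is
# checked against something it does not share code with.

# Pixel-centre enumeration of the ellipse interior over the whole frame.
brute_mask <- function(cx, cy, a, b, phi, h, w) {
  m <- matrix(FALSE, h, w)
  ang <- phi * pi / 180
  for (r in 0:(h - 1)) {
    for (c in 0:(w - 1)) {
      xp <- (c - cx) * cos(ang) + (r - cy) * sin(ang)
      yp <- -(c - cx) * sin(ang) + (r - cy) * cos(ang)
      m[r + 1, c + 1] <- (xp / a)^2 + (yp / b)^2 <= 1
    }
  }
  m
}

# Naive double-loop reference for the discriminative loss (Eqs. as written,
# no vectorisation shared with the implementation).
naive_discriminative <- function(emb, imap, cfg = discriminative_config()) {
  h <- dim(emb)[1]; w <- dim(emb)[2]
  ids <- sort(unique(as.integer(imap)))
  if (!cfg$include_background) ids <- setdiff(ids, 0L)
  C <- length(ids)
  mus <- list(); Ns <- numeric(C)
  for (k in seq_len(C)) {
    mu <- rep(0, dim(emb)[3]); n <- 0
    for (r in 1:h) for (c in 1:w) if (imap[r, c] == ids[k]) {
      mu <- mu + emb[r, c, ]; n <- n + 1
    }
    mus[[k]] <- mu / n; Ns[k] <- n
  }
  Lreg <- 0
  for (k in seq_len(C)) Lreg <- Lreg + sum(abs(mus[[k]]))
  Lreg <- Lreg / C
  Lvar <- 0
  for (k in seq_len(C)) {
    s <- 0
    for (r in 1:h) for (c in 1:w) if (imap[r, c] == ids[k]) {
      s <- s + max(0, sum(abs(mus[[k]] - emb[r, c, ])) - cfg$delta_v)^2
    }
    Lvar <- Lvar + s / Ns[k]
  }
  Lvar <- Lvar / C
  Ldist <- 0
  if (C >= 2) {
    for (A in seq_len(C)) for (B in seq_len(C)) if (A != B) {
      Ldist <- Ldist + max(0, 2 * cfg$delta_d - sum(abs(mus[[A]] - mus[[B]])))^2
    }
    Ldist <- Ldist / (C * (C - 1))
  }
  list(loss = cfg$alpha * Lvar + cfg$beta * Ldist + cfg$gamma * Lreg,
       var = Lvar, dist = Ldist, reg = Lreg)
}

# Exhaustive optimal one-to-one matching (maximising TP count, then total
# IoU) between predicted and ground-truth masks under the strict IoU > 0.5
# rule. Enumerates every injective assignment; only viable for few segments.
brute_match <- function(iou) {
  np <- nrow(iou); ng <- ncol(iou)
  best <- list(tp = -1, iou_sum = -1, pairs = NULL)
  recurse <- function(p, used_g, pairs) {
    if (p > np) {
      tp <- nrow(pairs)
      tot <- if (tp == 0) 0 else sum(iou[as.matrix(pairs)])
      if (tp > best$tp || (tp == best$tp && tot > best$iou_sum + 1e-15)) {
        best <<- list(tp = tp, iou_sum = tot, pairs = pairs)
      }
      return(invisible())
    }
    recurse(p + 1, used_g, pairs) # leave p unmatched
    for (g in seq_len(ng)) {
      if (!used_g[g] && iou[p, g] > 0.5) {
        recurse(p + 1, replace(used_g, g, TRUE),
                rbind(pairs, data.frame(pred = p, gt = g)))
      }
    }
  }
  recurse(1, rep(FALSE, max(ng, 1)),
          data.frame(pred = integer(), gt = integer()))
  best
}

# A random valid annotation set with controlled overlap, for rendering tests.
random_annotation <- function(n = 3, h = 96, w = 96) {
  a_hi <- min(16, (min(h, w) - 4) / 2)
  e <- NULL
  for (i in seq_len(n)) {
    a <- runif(1, min(8, a_hi - 1), a_hi); b <- runif(1, 4, min(a, 8))
    e <- rbind(e, data.frame(
      cx = runif(1, a, w - 1 - a), cy = runif(1, a, h - 1 - a),
      a = a, b = b, phi = runif(1, 0, 360)
    ))
  }
  annotation_set("rand", h, w, ellipses(e$cx, e$cy, e$a, e$b, e$phi,
                                        oriented = TRUE,
                                        depth = sample(n) - 1L))
}

angle_diff <- function(x, y) abs(((x - y + 180) %% 360) - 180)
axis_angle_diff <- function(x, y) abs(((x - y + 90) %% 180) - 90)
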