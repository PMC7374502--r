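#' Output head specification
#'
#' Each experiment attaches one or more heads to the shared
#' encoder-decoder: `binary` (1 channel, sigmoid), `categorical` and
#' `bodypart` (3 channels, softmax) and `embedding` (D channels, linear;
#' default D = 8). The activation is fixed by the head type and is applied
#' at prediction time (training works on logits with fused loss gradients).
#'
#' @param name One of `"binary"`, `"categorical"`, `"bodypart"`,
#'   `"embedding"`.
#' @param out_channels Number of output channels; defaults per head type
#'   (1 / 3 / 3 / 8).
#' @param weight Loss weight of this head (default 1, equal weighting).
#' @export
head_spec <- function(name = c("binary", "categorical", "bodypart", "embedding"),
                      out_channels = NULL, weight = 1) {
  name <- match.arg(name)
  defaults <- c(binary = 1L, categorical = 3L, bodypart = 3L, embedding = 8L)
  activations <- c(binary = "sigmoid", categorical = "softmax",
                   bodypart = "softmax", embedding = "linear")
  if (is.null(out_channels)) out_channels <- defaults[[name]]
  out_channels <- as.integer(out_channels)
  if (name %in% c("binary") && out_channels != 1L) {
    stop("binary head must have 1 output channel", call. = FALSE)
  }
  if (name %in% c("categorical", "bodypart") && out_channels != 3L) {
    stop(name, " head must have 3 output channels", call. = FALSE)
  }
  if (out_channels < 1L) stop("out_channels must be >= 1", call. = FALSE)
  stopifnot(weight >= 0)
  structure(list(name = name, out_channels = out_channels,
                 activation = activations[[name]], weight = weight),
            class = "head_spec")
}

#' Network configuration
#'
#' A compact U-Net: per encoder stage two 3x3 convolutions (ReLU) followed
#' by 2x2 max pooling, channel width doubling per stage from `base_width`;
#' a two-convolution bottleneck; a mirrored decoder with nearest-neighbour
#' upsampling and skip concatenation; and one 1x1 convolution per head.
#' Input sizes must be divisible by `2^stages`.
#'
#' With `coord_channels = TRUE` (default) two channels holding the
#' normalised x and y pixel coordinates are appended to the input. A
#' desk-scale encoder has a limited receptive field and no pretrained
#' context, and pure convolutions are translation-equivariant — identical
#' looking animals at different positions would otherwise be pushed to the
#' same point in embedding space. The coordinate channels give every head a
#' cheap positional cue.
#'
#' @param input_channels Image channels (3 for RGB).
#' @param stages Number of down/up-sampling stages (>= 2, default 4).
#' @param base_width Channels at the first stage (>= 4, default 16).
#' @param heads List of [head_spec()]s (at least one).
#' @param coord_channels Append normalised coordinate channels?
#' @export
network_config <- function(input_channels = 3, stages = 4, base_width = 16,
                           heads = list(head_spec("binary")),
                           coord_channels = TRUE) {
  stopifnot(stages >= 2, base_width >= 4, input_channels >= 1,
            length(heads) >= 1)
  if (inherits(heads, "head_spec")) heads <- list(heads)
  if (!all(vapply(heads, inherits, TRUE, "head_spec"))) {
    stop("heads must be a list of head_spec() objects", call. = FALSE)
  }
  nm <- vapply(heads, function(hh) hh$name, "")
  if (anyDuplicated(nm)) stop("duplicate head names", call. = FALSE)
  structure(list(input_channels = as.integer(input_channels),
                 stages = as.integer(stages),
                 base_width = as.integer(base_width),
                 heads = heads,
                 coord_channels = isTRUE(coord_channels)),
            class = "network_config")
}

# Shapes of every weight tensor, in the fixed layer order shared with the
# C++ engine: encoder stages (shallow to deep), bottleneck, decoder stages
# (deep to shallow), heads.
unet_layer_shapes <- function(cfg) {
  in_ch <- cfg$input_channels + if (cfg$coord_channels) 2L else 0L
  S <- cfg$stages; base <- cfg$base_width
  shapes <- list()
  add <- function(k, cin, cout) {
    shapes[[length(shapes) + 1]] <<- list(k = k, "in" = cin, out = cout)
  }
  prev <- in_ch
  for (s in 0:(S - 1)) {
    wch <- base * 2^s
    add(3, prev, wch); add(3, wch, wch)
    prev <- wch
  }
  wB <- base * 2^S
  add(3, prev, wB); add(3, wB, wB)
  above <- wB
  for (s in (S - 1):0) {
    wch <- base * 2^s
    add(3, above + wch, wch); add(3, wch, wch)
    above <- wch
  }
  for (hh in cfg$heads) add(1, base, hh$out_channels)
  shapes
}

#' Build a segmentation network
#'
#' Initialises the weights (He initialisation, driven by R's RNG so that a
#' prior `set.seed()` makes the model reproducible) and returns an untrained
#' model object.
#'
#' @param cfg A [network_config()].
#' @return A `penseg_unet` model: configuration, weight list, training
#'   history, and parameter count (`glance()` summarises it).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  shapes <- unet_layer_shapes(cfg)
  weights <- lapply(shapes, function(s) {
    fan_in <- s$`in` * s$k^2
    list(W = matrix(rnorm(fan_in * s$out, 0, sqrt(2 / fan_in)), fan_in, s$out),
         b = rep(0, s$out))
  })
  model <- structure(list(
    config = cfg,
    weights = weights,
    history = tibble::tibble(),
    env = new.env(parent = emptyenv())
  ), class = "penseg_unet")
  model$env$ptr <- NULL
  model
}

#' @export
print.penseg_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<penseg_unet> stages=%d base_width=%d heads=[%s] (%s parameters, %d training steps)\n",
    cfg$stages, cfg$base_width,
    paste(vapply(cfg$heads, function(hh) hh$name, ""), collapse = ", "),
    format(n_parameters(x), big.mark = ","), nrow(x$history)))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$weights, function(wl) length(wl$W) + length(wl$b), 0))
}

# (Re)materialise the C++ engine for this model; external pointers do not
# survive serialisation, so the R weight list is the source of truth.
unet_ptr <- function(model, push_weights = TRUE) {
  ptr <- model$env$ptr
  if (is.null(ptr) ||
        isTRUE(tryCatch({.unet_get_weights(ptr); FALSE}, error = function(e) TRUE))) {
    cfg <- model$config
    in_ch <- cfg$input_channels + if (cfg$coord_channels) 2L else 0L
    ptr <- .unet_create(in_ch, cfg$stages, cfg$base_width,
                        vapply(cfg$heads, function(hh) hh$out_channels, 1L))
    model$env$ptr <- ptr
    push_weights <- TRUE
  }
  if (push_weights) .unet_set_weights(ptr, model$weights)
  ptr
}

# Append normalised x/y coordinate channels when configured.
prepare_input <- function(model, image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1))
  d <- dim(image)
  cfg <- model$config
  if (d[3] != cfg$input_channels) {
    stop(sprintf("network expects %d image channels, got %d",
                 cfg$input_channels, d[3]), call. = FALSE)
  }
  div <- 2^cfg$stages
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop(sprintf("image size %dx%d must be divisible by 2^stages = %d",
                 d[1], d[2], div), call. = FALSE)
  }
  if (!cfg$coord_channels) return(image)
  xs <- matrix(seq(0, 1, length.out = d[2]), d[1], d[2], byrow = TRUE)
  ys <- matrix(seq(0, 1, length.out = d[1]), d[1], d[2])
  out <- array(0, c(d[1], d[2], d[3] + 2))
  out[, , seq_len(d[3])] <- image
  out[, , d[3] + 1] <- xs
  out[, , d[3] + 2] <- ys
  out
}

apply_activation <- function(z, activation) {
  switch(activation,
    sigmoid = 1 / (1 + exp(-z)),
    linear = z,
    softmax = {
      d <- dim(z)
      zm <- matrix(z, d[1] * d[2], d[3])
      mx <- do.call(pmax, lapply(seq_len(d[3]), function(k) zm[, k]))
      ez <- exp(zm - mx)
      array(ez / rowSums(ez), d)
    },
    stop("unknown activation ", activation)
  )
}

#' Argmax class codes of a softmax output
#'
#' Collapses an `h x w x C` class-probability array to the 0-based integer
#' code of the most probable class per pixel (ties to the first class).
#'
#' @param p `h x w x C` probability array.
#' @return Integer `h x w` matrix with values in `0:(C-1)`.
#' @export
class_map <- function(p) {
  d <- dim(p)
  pm <- matrix(p, d[1] * d[2], d[3])
  matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
}

#' Run the network on an image
#'
#' Deterministic inference: returns one `h x w x C` array per head, with
#' the head activation applied (sigmoid probabilities, softmax
#' distributions summing to 1 per pixel, raw embeddings).
#'
#' @param object A `penseg_unet` model.
#' @param image `h x w x channels` array (or matrix for 1-channel input)
#'   with dimensions divisible by `2^stages`.
#' @param logits Return raw logits instead of activations?
#' @param ... Unused.
#' @return Named list of arrays, one per head.
#' @export
predict.penseg_unet <- function(object, image, logits = FALSE, ...) {
  inp <- prepare_input(object, image)
  ptr <- unet_ptr(object)
  raw <- .unet_forward(ptr, inp, FALSE)
  names(raw) <- vapply(object$config$heads, function(hh) hh$name, "")
  if (logits) return(raw)
  out <- raw
  for (i in seq_along(out)) {
    out[[i]] <- apply_activation(out[[i]], object$config$heads[[i]]$activation)
  }
  out
}

#' Training configuration
#'
#' Adam with the study's default initial learning rate of 1e-5. For the
#' compact randomly-initialised network trained here from scratch, larger
#' rates (1e-3) converge far faster and are used by the bundled
#' experiments; the default matches the reference setting for fine-tuning
#' style training.
#'
#' @param learning_rate Adam step size.
#' @param epochs Passes over the dataset.
#' @param seed RNG seed for shuffling/augmentation (and reproducibility).
#' @param augment Random flips, 90-degree rotations (square images) and
#'   grayscale conversion (night-vision analogue)?
#' @param shuffle Reshuffle sample order each epoch?
#' @param decay_after Fraction of the total steps after which the learning
#'   rate is multiplied by `decay_factor` (a simple step schedule that
#'   settles the final phase of single-image stochastic training);
#'   `decay_after = 1` disables it.
#' @param decay_factor Multiplier applied after `decay_after`.
#' @export
train_config <- function(learning_rate = 1e-5, epochs = 1, seed = 1,
                         augment = FALSE, shuffle = TRUE,
                         decay_after = 1, decay_factor = 0.2) {
  stopifnot(learning_rate > 0, epochs >= 0,
            decay_after > 0, decay_after <= 1,
            decay_factor > 0, decay_factor <= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 shuffle = isTRUE(shuffle), decay_after = decay_after,
                 decay_factor = decay_factor),
            class = "train_config")
}

# One training sample: image plus the label maps required by the heads.
# Heads draw their targets as: binary -> $binary, categorical ->
# $categorical, bodypart -> $bodypart, embedding -> $instance.
check_sample <- function(sample, heads) {
  need <- vapply(heads, function(hh) {
    switch(hh$name, embedding = "instance", hh$name)
  }, "")
  missing <- setdiff(need, names(sample))
  if (length(missing) > 0) {
    stop("training sample lacks label map(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  need
}

augment_sample <- function(sample) {
  maps <- setdiff(names(sample), "image")
  sq <- dim(sample$image)[1] == dim(sample$image)[2]
  flip_h <- runif(1) < 0.5
  flip_v <- runif(1) < 0.5
  rot <- if (sq) sample.int(4, 1) - 1 else 0
  gray <- runif(1) < 0.25 && dim(sample$image)[3] == 3
  fl <- function(m, byrow) if (byrow) m[nrow(m):1, , drop = FALSE] else m[, ncol(m):1, drop = FALSE]
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  tx <- function(m) {
    if (flip_h) m <- fl(m, FALSE)
    if (flip_v) m <- fl(m, TRUE)
    if (rot > 0) for (i in seq_len(rot)) m <- rot90(m)
    m
  }
  img <- sample$image
  chs <- lapply(seq_len(dim(img)[3]), function(k) tx(img[, , k]))
  img <- array(unlist(chs), c(dim(chs[[1]]), length(chs)))
  if (gray) {
    lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    for (k in 1:3) img[, , k] <- lum
  }
  out <- list(image = img)
  for (mn in maps) out[[mn]] <- tx(sample[[mn]])
  out
}

# Per-head loss and gradient with respect to the logits.
head_loss_grad <- function(head, z, sample, disc_cfg) {
  n <- dim(z)[1] * dim(z)[2]
  if (head$name == "binary") {
    y <- sample$binary
    p <- 1 / (1 + exp(-z[, , 1]))
    loss <- binary_cross_entropy(p, y)
    grad <- array((p - y) / n, dim(z))
  } else if (head$name %in% c("categorical", "bodypart")) {
    t <- one_hot_map(sample[[head$name]], head$out_channels)
    p <- apply_activation(z, "softmax")
    # internally generated targets are one-hot by construction, so the
    # public categorical_cross_entropy()'s validation pass is skipped here
    pc <- pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)
    loss <- -sum(t * log(pc)) / n
    grad <- (p - t) / n
  } else { # embedding
    res <- discriminative_loss_grad(z, sample$instance, disc_cfg)
    loss <- res$loss
    grad <- res$grad
  }
  list(loss = loss, grad = grad)
}

#' Train a segmentation network
#'
#' Streams single images through the network (stochastic steps), combining
#' the per-head losses with the head weights and feeding the gradients
#' equally into the shared encoder-decoder. The loss history is recorded
#' every step; runs with the same seed and data are identical on one
#' machine.
#'
#' @param model A `penseg_unet`.
#' @param dataset List of samples; each sample is a list with `image`
#'   (`h x w x channels` array) and the label maps required by the model's
#'   heads (`binary`, `categorical`, `bodypart` 0/1/2 codes, `instance`).
#'   See [scene_targets()].
#' @param cfg A [train_config()].
#' @param disc_cfg A [discriminative_config()] for the embedding head.
#' @return The trained model, with `$history` grown by one row per step
#'   (`tidy()` returns it; `glance()` summarises the run).
#' @export
train_network <- function(model, dataset, cfg = train_config(),
                          disc_cfg = discriminative_config()) {
  stopifnot(inherits(model, "penseg_unet"), inherits(cfg, "train_config"))
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  heads <- model$config$heads
  for (s in dataset) check_sample(s, heads)
  if (cfg$epochs == 0) return(model)
  ptr <- unet_ptr(model)
  .unet_reset_optimizer(ptr)
  head_names <- vapply(heads, function(hh) hh$name, "")
  hist <- vector("list", cfg$epochs * length(dataset))
  step <- 0L
  with_scene_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle) sample.int(length(dataset)) else seq_along(dataset)
      for (i in ord) {
        sample_i <- dataset[[i]]
        if (cfg$augment) sample_i <- augment_sample(sample_i)
        inp <- prepare_input(model, sample_i$image)
        zs <- .unet_forward(ptr, inp, TRUE)
        grads <- vector("list", length(heads))
        losses <- numeric(length(heads))
        for (k in seq_along(heads)) {
          lg <- head_loss_grad(heads[[k]], zs[[k]], sample_i, disc_cfg)
          losses[k] <- lg$loss
          grads[[k]] <- lg$grad * heads[[k]]$weight
        }
        .unet_backward(ptr, grads)
        lr <- cfg$learning_rate
        if (step + 1L > cfg$decay_after * cfg$epochs * length(dataset)) {
          lr <- lr * cfg$decay_factor
        }
        .unet_adam_step(ptr, lr, 0.9, 0.999, 1e-8)
        step <- step + 1L
        row <- tibble::tibble(step = step, epoch = ep, sample = i,
                              loss = sum(losses * vapply(heads, function(hh) hh$weight, 0)))
        for (k in seq_along(heads)) row[[paste0("loss_", head_names[k])]] <- losses[k]
        hist[[step]] <- row
      }
    }
  })
  model$weights <- .unet_get_weights(ptr)
  model$history <- dplyr::bind_rows(model$history, dplyr::bind_rows(hist))
  model
}

#' @export
tidy.penseg_unet <- function(x, ...) x$history

#' @export
glance.penseg_unet <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = n_parameters(x),
    stages = x$config$stages,
    base_width = x$config$base_width,
    heads = paste(vapply(x$config$heads, function(hh) hh$name, ""),
                  collapse = "+"),
    steps = nrow(h),
    initial_loss = if (nrow(h) > 0) h$loss[1] else NA_real_,
    final_loss = if (nrow(h) > 0) h$loss[nrow(h)] else NA_real_
  )
}

#' @export
autoplot.penseg_unet <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) stop("model has no training history", call. = FALSE)
  long <- tidyr_pivot(h)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "training step", y = "loss", colour = NULL)
}

# minimal long-format reshape of the history (avoids a tidyr dependency)
tidyr_pivot <- function(h) {
  cols <- grep("^loss", names(h), value = TRUE)
  dplyr::bind_rows(lapply(cols, function(cn) {
    tibble::tibble(step = h$step, term = cn, value = h[[cn]])
  }))
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold the configuration, weights and history in RDS format.
#'
#' @param model A `penseg_unet`.
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, weights = model$weights,
               history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  raw <- readRDS(path)
  model <- structure(list(config = raw$config, weights = raw$weights,
                          history = raw$history,
                          env = new.env(parent = emptyenv())),
                     class = "penseg_unet")
  model$env$ptr <- NULL
  model
}
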