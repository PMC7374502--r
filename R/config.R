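#' Run configuration
#'
#' A single structured configuration drives the command-line pipeline:
#' sections `scene` (see [scene_config()]), `labels` (`core_scale`,
#' `head_fraction`), `loss` (see [discriminative_config()], plus
#' `embedding_dim`), `network` (`stages`, `base_width`, `coord_channels`),
#' `train` (see [train_config()]), `postprocess` (`tau`,
#' `min_cluster_size`, `noise_policy`, `min_pixels`). Unknown keys are
#' rejected so that typos cannot silently fall back to defaults, and the
#' full configuration is echoed into run logs and manifests.
#'
#' @param path YAML file; missing keys take the defaults of
#'   `default_run_config()`.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    scene = list(
      image_size = c(128L, 128L), n_animals = c(3L, 8L),
      a_range = c(10, 18), b_range = c(5, 9), overlap_fraction = 0.3,
      night_mode_prob = 0.5, dirt_prob = 0.15, noise_sigma = 0.02,
      head_fraction = 0.4, cameras = 5L, seed = 1L
    ),
    labels = list(core_scale = 0.5, head_fraction = 0.4),
    loss = list(delta_v = 0.1, delta_d = 1.5, alpha = 1, beta = 1,
                gamma = 0.001, include_background = TRUE, embedding_dim = 8L),
    network = list(stages = 4L, base_width = 16L, coord_channels = TRUE),
    train = list(learning_rate = 1e-5, epochs = 1L, seed = 1L,
                 augment = TRUE, shuffle = TRUE),
    postprocess = list(tau = 0.5, min_cluster_size = 100L,
                       noise_policy = "discard", min_pixels = 20L)
  ), class = "run_config")
}

#' @rdname default_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  if (is.null(raw)) return(cfg)
  bad_sections <- setdiff(names(raw), names(cfg))
  if (length(bad_sections) > 0) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
    if (length(bad) > 0) {
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    for (key in names(raw[[sec]])) cfg[[sec]][[key]] <- raw[[sec]][[key]]
  }
  cfg
}

run_scene_config <- function(cfg) {
  s <- cfg$scene
  scene_config(image_size = s$image_size, n_animals = s$n_animals,
               a_range = s$a_range, b_range = s$b_range,
               overlap_fraction = s$overlap_fraction,
               night_mode_prob = s$night_mode_prob, dirt_prob = s$dirt_prob,
               noise_sigma = s$noise_sigma, head_fraction = s$head_fraction,
               cameras = s$cameras, seed = s$seed)
}

run_disc_config <- function(cfg) {
  l <- cfg$loss
  discriminative_config(delta_v = l$delta_v, delta_d = l$delta_d,
                        alpha = l$alpha, beta = l$beta, gamma = l$gamma,
                        include_background = l$include_background)
}

run_cluster_config <- function(cfg) {
  p <- cfg$postprocess
  clustering_config(min_cluster_size = p$min_cluster_size,
                    noise_policy = p$noise_policy)
}

head_set_specs <- function(head_set, embedding_dim = 8L) {
  switch(head_set,
    binary = list(head_spec("binary")),
    categorical = list(head_spec("categorical")),
    combined = list(head_spec("binary"),
                    head_spec("embedding", out_channels = embedding_dim)),
    `combined-bodypart` = list(head_spec("bodypart"),
                               head_spec("embedding", out_channels = embedding_dim)),
    stop("unknown head set '", head_set,
         "' (use binary, categorical, combined or combined-bodypart)",
         call. = FALSE)
  )
}
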