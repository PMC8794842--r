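#' Default experiment configuration
#'
#' Full declarative description of a run: substrate, network, task, loss and
#' training sections plus experiment-level sweep settings. Values here are
#' the package defaults; [read_config()] merges a YAML file over them and
#' [validate_config()] rejects unknown keys.
#'
#' @return nested named list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    task = list(
      type = "latency",           # latency | temporal
      n_classes = 10L,
      n_channels = 70L,           # latency: pixels; temporal: channels
      samples_per_class = 100L,
      t_steps = 100L,
      pixel_noise_sd = 0.15,
      rotation_deg = 0,
      time_jitter_sd = 2,
      channel_jitter_sd = 1,
      deletion_p = 0.1,
      background_rate = 0.002,
      test_fraction = 0.2,
      disjoint_test = FALSE,
      tau_in = 20,
      theta_in = 0.2,
      t_max = 60,
      seed = 1L
    ),
    substrate = list(
      n_hidden = 64L,
      dt = 1,
      fine_factor = 1L,
      refractory = 0L,
      mismatch = list(sigma_d = 0, which = c("tau_mem", "tau_syn", "threshold"),
                      seed = 1L),
      noise = list(membrane_sd = 0.01, readout_sd = 0.01),
      tau_mem = 20, tau_syn = 10, threshold = 1
    ),
    network = list(
      recurrent = FALSE,
      sigma_w = 1,
      hidden_w_max = 1.5,
      quantize = TRUE
    ),
    loss = list(
      mode = "max_over_time",
      rho_a = 0.01, rho_b = 0, rho_r = 0, theta_r = 0,
      beta = 10, surrogate = "superspike", surrogate_eps = 0.01,
      detach_reset = TRUE
    ),
    training = list(
      mode = "itl",               # itl | software
      epochs = 30L,
      batch_size = 50L,
      lr = 1e-3,
      lr_decay = 1,
      clip = Inf,
      dropout_rate = 0
    ),
    experiment = list(
      seeds = c(1L, 2L, 3L),
      sigma_grid = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
      rho_grid = c(0, 1e-4, 1e-3, 1e-2, 1e-1),
      dropout_rates = c(0, 0.4),
      ablation_fractions = c(0, 0.05, 0.15, 0.3),
      out_dir = NULL
    )
  ), class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Parses the file, validates it against the schema of [default_config()]
#' (unknown keys are an error) and merges it over the defaults.
#'
#' @param path path to a YAML file with any subset of the config sections.
#' @return merged `experiment_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- paste0(path, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a section")
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Validate an experiment configuration
#'
#' @param config a nested list as from [read_config()].
#' @return the config, invisibly; errors on unknown keys or invalid values.
#' @export
validate_config <- function(config) {
  merge_config(default_config(), unclass(config))
  stopifnot(config$task$type %in% c("latency", "temporal"),
            config$training$mode %in% c("itl", "software"),
            config$substrate$fine_factor >= 1,
            config$training$epochs >= 1)
  invisible(config)
}

#' Archive a resolved configuration
#'
#' Writes the fully merged config as YAML next to a run's outputs so every
#' result is reproducible from its archived configuration and seed.
#'
#' @param config the resolved config.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cfg <- rapply(unclass(config),
                function(x) if (identical(x, Inf)) ".inf" else x,
                how = "replace")
  yaml::write_yaml(cfg, path)
}

# --- construction of run ingredients from a config ------------------------

config_dataset <- function(config, seed) {
  tk <- config$task
  if (tk$type == "latency") {
    npix <- tk$n_channels
    shape <- if (npix == 256) c(16L, 16L) else c(1L, npix)
    spec <- latency_task_spec(
      n_classes = tk$n_classes, shape = shape,
      samples_per_class = tk$samples_per_class,
      pixel_noise_sd = tk$pixel_noise_sd, rotation_deg = tk$rotation_deg,
      seed = derive_seed(seed, "data", tk$seed))
    ds <- make_latency_images(spec)
    split <- train_test_split(ds, tk$test_fraction,
                              seed = derive_seed(seed, "split", tk$seed))
    enc <- latency_code_spec(tau_in = tk$tau_in, theta_in = tk$theta_in,
                             t_max = tk$t_max)
    dense <- function(d) {
      sb <- latency_encode(d$images, enc, duration = tk$t_steps,
                           labels = d$labels)
      as_dense(sb, dt = config$substrate$dt, t_steps = tk$t_steps)
    }
    list(x_train = dense(split$train), y_train = split$train$labels,
         x_test = dense(split$test), y_test = split$test$labels)
  } else {
    spec <- temporal_task_spec(
      n_classes = tk$n_classes, n_channels = tk$n_channels,
      samples_per_class = tk$samples_per_class, t_steps = tk$t_steps,
      time_jitter_sd = tk$time_jitter_sd,
      channel_jitter_sd = tk$channel_jitter_sd,
      deletion_p = tk$deletion_p, background_rate = tk$background_rate,
      seed = derive_seed(seed, "data", tk$seed))
    ds <- make_temporal_patterns(spec)
    split <- train_test_split(ds, tk$test_fraction,
                              disjoint = tk$disjoint_test,
                              seed = derive_seed(seed, "split", tk$seed))
    dense <- function(d) as_dense(d, dt = config$substrate$dt,
                                  t_steps = tk$t_steps)
    list(x_train = dense(split$train), y_train = split$train$labels,
         x_test = dense(split$test), y_test = split$test$labels)
  }
}

config_substrate <- function(config, sigma_d = NULL, seed = 1L) {
  sb <- config$substrate
  mm <- sb$mismatch
  sd_use <- sigma_d %||% mm$sigma_d
  mismatch <- if (sd_use > 0)
    mismatch_spec(sd_use, mm$which, seed = derive_seed(seed, "mismatch",
                                                       mm$seed)) else NULL
  n_out <- config$task$n_classes
  substrate(
    n_in = config$task$n_channels, n_hidden = sb$n_hidden, n_out = n_out,
    dt = sb$dt, fine_factor = sb$fine_factor,
    params = neuron_params(sb$n_hidden, tau_mem = sb$tau_mem,
                           tau_syn = sb$tau_syn, threshold = sb$threshold),
    params_out = neuron_params(n_out, tau_mem = sb$tau_mem,
                               tau_syn = sb$tau_syn, threshold = Inf),
    mismatch = mismatch,
    noise = noise_spec(sb$noise$membrane_sd, sb$noise$readout_sd),
    refractory = sb$refractory)
}

config_loss <- function(config) {
  ls <- config$loss
  loss_config(mode = ls$mode, rho_a = ls$rho_a, rho_b = ls$rho_b,
              rho_r = ls$rho_r, theta_r = ls$theta_r)
}

config_surrogate <- function(config) {
  surrogate_spec(beta = config$loss$beta, form = config$loss$surrogate,
                 eps = config$loss$surrogate_eps)
}

config_state <- function(config, seed) {
  tr <- config$training
  w <- init_weights(config$task$n_channels, config$substrate$n_hidden,
                    config$task$n_classes,
                    recurrent = config$network$recurrent,
                    sigma_w = config$network$sigma_w,
                    seed = derive_seed(seed, "init"))
  train_state(w, lr = tr$lr, lr_decay = tr$lr_decay, clip = tr$clip)
}
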