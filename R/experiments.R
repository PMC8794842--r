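# Experiment runners: reproducible wrappers around the training loop for the
# headline studies (single run, self-calibration sweep, sparsity sweep,
# robustness, latency probe). Every runner is a pure function of
# (config, seed) and optionally archives CSV metrics plus the resolved
# config under config$experiment$out_dir.

run_one <- function(config, seed, sub = NULL, dataset = NULL,
                    state = NULL, dropout_rate = NULL) {
  dataset <- dataset %||% config_dataset(config, seed)
  state <- state %||% config_state(config, seed)
  lcfg <- config_loss(config)
  spec <- config_surrogate(config)
  tr <- config$training
  dr <- dropout_rate %||% tr$dropout_rate
  if (tr$mode == "itl") {
    sub <- sub %||% config_substrate(config, seed = seed)
    state <- fit_itl(sub, dataset$x_train, dataset$y_train, state, lcfg,
                     spec, epochs = tr$epochs, batch_size = tr$batch_size,
                     dropout_rate = dr, quantize = config$network$quantize,
                     seed = derive_seed(seed, "fit"),
                     detach_reset = config$loss$detach_reset)
    test <- evaluate_network(state$weights, dataset$x_test, dataset$y_test,
                             lcfg, sub = sub,
                             quantize = config$network$quantize)
  } else {
    ideal <- config_substrate(config, sigma_d = 0, seed = seed)
    state <- train_software_only(dataset$x_train, dataset$y_train, state,
                                 lcfg, ideal$target_hidden, ideal$target_out,
                                 spec, dt = config$substrate$dt,
                                 epochs = tr$epochs,
                                 batch_size = tr$batch_size,
                                 dropout_rate = dr,
                                 seed = derive_seed(seed, "fit"),
                                 detach_reset = config$loss$detach_reset)
    test <- evaluate_network(state$weights, dataset$x_test, dataset$y_test,
                             lcfg, params = ideal$target_hidden,
                             params_out = ideal$target_out,
                             dt = config$substrate$dt)
  }
  list(state = state, test = test, dataset = dataset, sub = sub)
}

write_metrics <- function(df, config, name) {
  out <- config$experiment$out_dir
  if (is.null(out)) return(invisible(NULL))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  write_config(config, file.path(out, paste0(name, "_config.yaml")))
  invisible(path)
}

#' Run a single training experiment
#'
#' Trains one network according to the configuration and reports per-epoch
#' training metrics plus final test accuracy. With an `out_dir` set in the
#' config, metrics and the resolved config are archived as CSV/YAML;
#' re-running with an identical config and seed reproduces them
#' byte-identically.
#'
#' @param config an `experiment_config` (see [default_config()],
#'   [read_config()]).
#' @param seed master seed of the run.
#' @return list with `history` (per-epoch data frame), `test_accuracy`,
#'   `test_loss`, `hidden_spikes_per_sample` and the trained `state`.
#' @export
run_train <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  res <- run_one(config, seed)
  history <- res$state$history
  history$seed <- seed
  write_metrics(history, config, "train")
  list(history = history, test_accuracy = res$test$accuracy,
       test_loss = res$test$loss,
       hidden_spikes_per_sample = res$test$mean_hidden_spikes,
       state = res$state)
}

#' Self-calibration sweep: ITL training vs. weight transfer
#'
#' For every decalibration level in `config$experiment$sigma_grid` and every
#' seed, trains in the loop on a substrate decalibrated by `sigma_d`
#' (the computation graph keeps assuming ideal dynamics) and, as a baseline,
#' transfers a software-trained network of the same seed onto the same
#' decalibrated substrate. Reports per-cell test accuracies and per-level
#' medians.
#'
#' @param config an `experiment_config`.
#' @return list with `cells` (one row per sigma_d x method x seed) and
#'   `summary` (medians per sigma_d x method).
#' @export
run_selfcal_sweep <- function(config = default_config()) {
  validate_config(config)
  ex <- config$experiment
  rows <- list()
  for (seed in ex$seeds) {
    dataset <- config_dataset(config, seed)
    # software baseline, trained once per seed
    sw_cfg <- config; sw_cfg$training$mode <- "software"
    sw <- run_one(sw_cfg, seed, dataset = dataset)
    for (sd in ex$sigma_grid) {
      sub <- config_substrate(config, sigma_d = sd, seed = seed)
      itl <- run_one(config, seed, sub = sub, dataset = dataset)
      tr <- weight_transfer(sw$state$weights, sub, dataset$x_test,
                            dataset$y_test, config_loss(config))
      rows[[length(rows) + 1]] <- data.frame(
        sigma_d = sd, seed = seed,
        itl_accuracy = itl$test$accuracy,
        transfer_accuracy = tr$accuracy,
        software_accuracy = sw$test$accuracy)
    }
  }
  cells <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(cells, cells$sigma_d), function(d)
    data.frame(sigma_d = d$sigma_d[1],
               itl_median = stats::median(d$itl_accuracy),
               transfer_median = stats::median(d$transfer_accuracy))))
  rownames(summary) <- NULL
  write_metrics(cells, config, "selfcal")
  list(cells = cells, summary = summary)
}

#' Sparsity sweep over the activity-regularization strength
#'
#' Trains networks across `config$experiment$rho_grid` (the quadratic
#' spike-count penalty) and records median hidden-layer spikes per pattern
#' and test accuracy at each strength — the accuracy-vs-activity trade-off
#' curve.
#'
#' @param config an `experiment_config`.
#' @return list with `cells` and `summary` (medians per rho_b).
#' @export
run_sparsity_sweep <- function(config = default_config()) {
  validate_config(config)
  ex <- config$experiment
  rows <- list()
  for (seed in ex$seeds) {
    dataset <- config_dataset(config, seed)
    for (rho in ex$rho_grid) {
      cfg <- config
      cfg$loss$rho_b <- rho
      res <- run_one(cfg, seed, dataset = dataset)
      rows[[length(rows) + 1]] <- data.frame(
        rho_b = rho, seed = seed,
        test_accuracy = res$test$accuracy,
        hidden_spikes = res$test$mean_hidden_spikes)
    }
  }
  cells <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(cells, cells$rho_b), function(d)
    data.frame(rho_b = d$rho_b[1],
               accuracy_median = stats::median(d$test_accuracy),
               spikes_median = stats::median(d$hidden_spikes))))
  summary <- summary[order(summary$rho_b), ]
  rownames(summary) <- NULL
  write_metrics(cells, config, "sparsity")
  list(cells = cells, summary = summary)
}

#' Robustness to hidden-neuron failure, with and without dropout
#'
#' Trains networks at each dropout rate in
#' `config$experiment$dropout_rates`, then silences random hidden subsets at
#' each fraction in `config$experiment$ablation_fractions` and measures the
#' test-error inflation relative to the intact network.
#'
#' @param config an `experiment_config`.
#' @return list with `cells` (dropout x fraction x seed) and `summary`
#'   (median inflation per dropout x fraction).
#' @export
run_robustness <- function(config = default_config()) {
  validate_config(config)
  ex <- config$experiment
  lcfg <- config_loss(config)
  rows <- list()
  for (seed in ex$seeds) {
    dataset <- config_dataset(config, seed)
    for (dr in ex$dropout_rates) {
      sub <- config_substrate(config, seed = seed)
      res <- run_one(config, seed, sub = sub, dataset = dataset,
                     dropout_rate = dr)
      err0 <- NULL
      for (fr in sort(ex$ablation_fractions)) {
        wa <- ablate_hidden(res$state$weights, fr,
                            seed = derive_seed(seed, "ablate", fr))
        ev <- evaluate_network(wa, dataset$x_test, dataset$y_test, lcfg,
                               sub = sub, quantize = config$network$quantize)
        err <- 1 - ev$accuracy
        if (fr == 0) err0 <- err
        rows[[length(rows) + 1]] <- data.frame(
          dropout = dr, fraction = fr, seed = seed, test_error = err,
          inflation = if (err0 > 0) err / err0 - 1 else err - err0)
      }
    }
  }
  cells <- do.call(rbind, rows)
  key <- interaction(cells$dropout, cells$fraction)
  summary <- do.call(rbind, lapply(split(cells, key), function(d)
    data.frame(dropout = d$dropout[1], fraction = d$fraction[1],
               error_median = stats::median(d$test_error),
               inflation_median = stats::median(d$inflation))))
  summary <- summary[order(summary$dropout, summary$fraction), ]
  rownames(summary) <- NULL
  write_metrics(cells, config, "robustness")
  list(cells = cells, summary = summary)
}

#' Recurrence benefit: trained vs. shuffled-frozen recurrent weights
#'
#' For each seed, trains a recurrent network on the (order-sensitive)
#' temporal task, then initializes a control network whose recurrent matrix
#' is the trained one with entries randomly permuted and frozen, training
#' only the input and readout weights. Lower test error of the trained-
#' recurrent network indicates that learned recurrence, not just reservoir
#' dynamics, carries the task.
#'
#' @param config an `experiment_config` with `network$recurrent = TRUE` and
#'   a temporal task.
#' @return list with `cells` (per-seed errors) and `summary` (medians).
#' @export
run_recurrence_control <- function(config = default_config()) {
  validate_config(config)
  if (!config$network$recurrent) stop("config must enable a recurrent network")
  rows <- list()
  for (seed in config$experiment$seeds) {
    dataset <- config_dataset(config, seed)
    trained <- run_one(config, seed, dataset = dataset)
    ctrl_state <- config_state(config, derive_seed(seed, "control"))
    frozen <- freeze_recurrent_control(trained$state$weights,
                                       seed = derive_seed(seed, "shuffle"))
    ctrl_state$weights$w_rec <- frozen$w_rec
    attr(ctrl_state$weights, "freeze_rec") <- TRUE
    ctrl <- run_one(config, seed, dataset = dataset, state = ctrl_state)
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed,
      trained_error = 1 - trained$test$accuracy,
      frozen_error = 1 - ctrl$test$accuracy)
  }
  cells <- do.call(rbind, rows)
  summary <- data.frame(
    trained_error_median = stats::median(cells$trained_error),
    frozen_error_median = stats::median(cells$frozen_error))
  write_metrics(cells, config, "recurrence")
  list(cells = cells, summary = summary)
}

#' Classification-latency probe
#'
#' Re-evaluates the max-over-time decision on output traces restricted to
#' growing intervals `[0, T']`, yielding accuracy as a function of the
#' decision horizon and the earliest horizon at which the final accuracy is
#' reached.
#'
#' @param v_out recorded output traces `(batch, n_classes, T)`.
#' @param labels integer labels.
#' @return data frame with `horizon` and `accuracy`, plus attribute
#'   `earliest_peak` (smallest horizon attaining the full-window accuracy).
#' @export
run_latency_probe <- function(v_out, labels) {
  T <- dim(v_out)[3]
  acc <- vapply(seq_len(T), function(h) {
    sc <- trace_scores(v_out[, , seq_len(h), drop = FALSE], "max_over_time")
    mean(max.col(sc$scores, ties.method = "first") == labels)
  }, 0)
  out <- data.frame(horizon = seq_len(T), accuracy = acc)
  attr(out, "earliest_peak") <- min(which(acc == acc[T]))
  out
}

#' Train a model and probe its classification latency
#'
#' Convenience runner: trains according to the configuration, records the
#' test-set output traces, and applies [run_latency_probe()] to them.
#'
#' @param config an `experiment_config` (a latency-coded task).
#' @param seed master seed.
#' @return the probe data frame (see [run_latency_probe()]) with attributes
#'   `earliest_peak` and `test_accuracy`.
#' @export
run_latency_experiment <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  res <- run_one(config, seed)
  probe <- run_latency_probe(res$test$v_out, res$dataset$y_test)
  attr(probe, "test_accuracy") <- res$test$accuracy
  write_metrics(probe, config, "latency_probe")
  probe
}
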