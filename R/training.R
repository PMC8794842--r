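#' Training state
#'
#' Holds the float master weights, the Adam moment estimates, the epoch
#' counter and the metrics history of a training run. The master copy is the
#' only thing gradients ever update; the substrate only ever sees quantized
#' copies derived from it at deployment time.
#'
#' @param weights initial [network_weights()].
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment parameters.
#' @param lr_decay multiplicative learning-rate decay per epoch (1 = none).
#' @param clip gradient-norm clip threshold (`Inf` = off); guards the
#'   unbounded literal surrogate form.
#' @return an object of class `train_state`.
#' @export
train_state <- function(weights, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, lr_decay = 1, clip = Inf) {
  z <- lapply(unclass(weights)[c("w_in", "w_rec", "w_out")],
              function(w) if (is.null(w)) NULL else w * 0)
  structure(list(weights = weights, m = z, v = z, step = 0L, epoch = 0L,
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 lr_decay = lr_decay, clip = clip,
                 history = NULL), class = "train_state")
}

adam_update <- function(state, grads, freeze_rec = FALSE) {
  state$step <- state$step + 1L
  lr_t <- state$lr * state$lr_decay^state$epoch
  # global norm clip
  if (is.finite(state$clip)) {
    nrm <- sqrt(sum(unlist(lapply(grads, function(g) sum(g^2)))))
    if (nrm > state$clip) grads <- lapply(grads, function(g) g * state$clip / nrm)
  }
  for (k in c("w_in", "w_rec", "w_out")) {
    if (is.null(state$weights[[k]])) next
    if (k == "w_rec" && freeze_rec) next
    g <- grads[[k]]
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * g
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * g^2
    mhat <- state$m[[k]] / (1 - state$beta1^state$step)
    vhat <- state$v[[k]] / (1 - state$beta2^state$step)
    state$weights[[k]] <- state$weights[[k]] -
      lr_t * mhat / (sqrt(vhat) + state$eps)
  }
  state
}

#' Per-batch dropout mask over hidden units
#'
#' Bernoulli(1 - rate) keep mask applied to hidden spikes both in the
#' computation graph and on the substrate deployment for the batch (silenced
#' units emit no spikes there — the "neuronal death" semantics the
#' post-training ablation probes). Disabled at evaluation.
#'
#' @param n_hidden number of hidden units.
#' @param rate dropout rate in \[0, 1\].
#' @param seed integer seed.
#' @return 0/1 numeric vector of length `n_hidden`.
#' @export
apply_dropout <- function(n_hidden, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(rep(1, n_hidden))
  with_seed(seed, as.numeric(stats::runif(n_hidden) >= rate))
}

#' One in-the-loop training step
#'
#' The ITL contract in a single call: (1) the float master weights are
#' quantized and deployed; (2) the forward pass is emulated on the substrate
#' with recording; (3) the computation graph is unrolled with the
#' *idealized* calibration-target parameters, injecting the recorded traces
#' and spikes; (4) the configured loss is evaluated on the recorded output
#' traces; (5) BPTT yields weight gradients; (6) Adam updates the float
#' master copy.
#'
#' @param state a [train_state()].
#' @param sub an [substrate()] object.
#' @param x dense input array `(batch, n_in, T)`.
#' @param labels integer labels for the batch.
#' @param config a [loss_config()].
#' @param spec a [surrogate_spec()].
#' @param quantize deploy quantized weights (hardware-faithful) or the float
#'   copy?
#' @param hidden_mask optional dropout mask for this batch.
#' @param detach_reset see [unroll()].
#' @return list with the updated `state` and `metrics` (loss terms,
#'   accuracy, mean hidden spikes/sample).
#' @export
itl_step <- function(state, sub, x, labels, config, spec = surrogate_spec(),
                     quantize = TRUE, hidden_mask = NULL,
                     detach_reset = TRUE) {
  sub <- deploy_weights(sub, state$weights, quantize = quantize)
  rec <- emulate_forward(sub, x, hidden_mask = hidden_mask,
                         record_events = FALSE)
  g <- unroll(x, state$weights, sub$target_hidden, sub$target_out,
              recording = rec, spec = spec, dt = sub$dt,
              hidden_mask = hidden_mask, detach_reset = detach_reset)
  lg <- loss_and_grads(g$v_out, g$s_hidden, labels, config)
  if (!is.finite(lg$loss))
    stop("non-finite training loss; inspect weights and surrogate settings")
  grads <- g$backward(lg$g_vout, lg$g_spikes)
  state <- adam_update(state, grads,
                       freeze_rec = isTRUE(attr(state$weights, "freeze_rec")))
  list(state = state,
       metrics = list(loss = lg$loss, terms = lg$terms,
                      accuracy = lg$accuracy,
                      hidden_spikes = lg$mean_hidden_spikes))
}

# one software step: identical loop with the model simulation as forward
software_step <- function(state, params, params_out, x, labels, config, spec,
                          dt = 1, hidden_mask = NULL, detach_reset = TRUE) {
  g <- unroll(x, state$weights, params, params_out, recording = NULL,
              spec = spec, dt = dt, hidden_mask = hidden_mask,
              detach_reset = detach_reset)
  lg <- loss_and_grads(g$v_out, g$s_hidden, labels, config)
  if (!is.finite(lg$loss)) stop("non-finite training loss")
  grads <- g$backward(lg$g_vout, lg$g_spikes)
  state <- adam_update(state, grads,
                       freeze_rec = isTRUE(attr(state$weights, "freeze_rec")))
  list(state = state,
       metrics = list(loss = lg$loss, terms = lg$terms,
                      accuracy = lg$accuracy,
                      hidden_spikes = lg$mean_hidden_spikes))
}

#' Train a network in the loop with the substrate
#'
#' Minibatch ITL training: every batch runs the emulate-record-unroll-update
#' cycle of [itl_step()]. Fully reproducible from `seed` (shuffling, dropout
#' masks and substrate trial noise all derive from it).
#'
#' @param sub an [substrate()] object.
#' @param x dense input array `(n, n_in, T)`.
#' @param labels integer labels, length `n`.
#' @param state a [train_state()] with initial weights.
#' @param config a [loss_config()].
#' @param spec a [surrogate_spec()].
#' @param epochs number of passes over the data.
#' @param batch_size minibatch size.
#' @param dropout_rate hidden dropout rate during training.
#' @param quantize hardware-faithful quantized deployment?
#' @param seed integer seed for the run.
#' @param detach_reset see [unroll()].
#' @return the final `train_state`, with `$history` a per-epoch data frame.
#' @export
fit_itl <- function(sub, x, labels, state, config, spec = surrogate_spec(),
                    epochs = 30, batch_size = 50, dropout_rate = 0,
                    quantize = TRUE, seed = 1L, detach_reset = TRUE) {
  fit_loop(mode = "itl", sub = sub, x = x, labels = labels, state = state,
           config = config, spec = spec, epochs = epochs,
           batch_size = batch_size, dropout_rate = dropout_rate,
           quantize = quantize, seed = seed, detach_reset = detach_reset)
}

#' Train the same network purely in software
#'
#' Identical optimization loop, but the forward pass is the idealized model
#' simulation: no substrate, no mismatch, no noise, and unquantized float
#' weights throughout. Baseline for weight transfer and for the
#' ITL-equals-simulation oracle.
#'
#' @inheritParams fit_itl
#' @param params,params_out idealized neuron parameters for the simulation.
#' @param dt grid step.
#' @return the final `train_state`.
#' @export
train_software_only <- function(x, labels, state, config,
                                params, params_out,
                                spec = surrogate_spec(), dt = 1, epochs = 30,
                                batch_size = 50, dropout_rate = 0, seed = 1L,
                                detach_reset = TRUE) {
  fit_loop(mode = "software", sub = NULL, x = x, labels = labels,
           state = state, config = config, spec = spec, epochs = epochs,
           batch_size = batch_size, dropout_rate = dropout_rate,
           quantize = FALSE, seed = seed, detach_reset = detach_reset,
           params = params, params_out = params_out, dt = dt)
}

fit_loop <- function(mode, sub, x, labels, state, config, spec, epochs,
                     batch_size, dropout_rate, quantize, seed, detach_reset,
                     params = NULL, params_out = NULL, dt = NULL) {
  n <- dim(x)[1]
  n_h <- nrow(state$weights$w_in)
  history <- vector("list", epochs)
  set.seed(seed)
  for (ep in seq_len(epochs)) {
    state$epoch <- ep - 1L
    order <- sample.int(n)
    batches <- split(order, ceiling(seq_along(order) / batch_size))
    ep_loss <- 0; ep_acc <- 0; ep_spk <- 0
    ep_terms <- c(task = 0, amplitude = 0, sparsity = 0, homeostatic = 0)
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      mask <- if (dropout_rate > 0)
        as.numeric(stats::runif(n_h) >= dropout_rate) else NULL
      xb <- x[idx, , , drop = FALSE]
      res <- if (mode == "itl")
        itl_step(state, sub, xb, labels[idx], config, spec,
                 quantize = quantize, hidden_mask = mask,
                 detach_reset = detach_reset)
      else
        software_step(state, params, params_out, xb, labels[idx], config,
                      spec, dt = dt, hidden_mask = mask,
                      detach_reset = detach_reset)
      state <- res$state
      w <- length(idx) / n
      ep_loss <- ep_loss + res$metrics$loss * w
      ep_acc <- ep_acc + res$metrics$accuracy * w
      ep_spk <- ep_spk + res$metrics$hidden_spikes * w
      tm <- res$metrics$terms
      ep_terms[names(tm)] <- ep_terms[names(tm)] + tm * w
    }
    history[[ep]] <- data.frame(epoch = ep, loss = ep_loss,
                                loss_task = ep_terms[["task"]],
                                loss_amplitude = ep_terms[["amplitude"]],
                                loss_sparsity = ep_terms[["sparsity"]],
                                loss_homeostatic = ep_terms[["homeostatic"]],
                                train_accuracy = ep_acc,
                                hidden_spikes = ep_spk)
  }
  state$epoch <- as.integer(epochs)
  state$history <- do.call(rbind, history)
  state
}

#' Evaluate a network on a substrate or in software
#'
#' Side-effect-free forward evaluation (no dropout, no weight updates).
#'
#' @param weights a [network_weights()] object.
#' @param x dense input array.
#' @param labels integer labels.
#' @param config a [loss_config()] (determines the readout mode).
#' @param sub optional [substrate()]; when `NULL` the idealized software
#'   model is used.
#' @param params,params_out idealized parameters for the software route.
#' @param quantize quantized deployment on the substrate route?
#' @param dt grid step for the software route.
#' @return list with `accuracy`, `loss`, `mean_hidden_spikes`, and the
#'   forward traces `v_out`, `s_hidden`.
#' @export
evaluate_network <- function(weights, x, labels, config, sub = NULL,
                             params = NULL, params_out = NULL,
                             quantize = TRUE, dt = 1) {
  if (!is.null(sub)) {
    sub <- deploy_weights(sub, weights, quantize = quantize)
    rec <- emulate_forward(sub, x, record_events = FALSE)
    v_out <- rec$v_out; s_h <- rec$spikes
  } else {
    sim <- simulate_network(x, weights, params, params_out, dt = dt)
    v_out <- sim$v_out; s_h <- sim$spikes
  }
  lg <- loss_and_grads(v_out, s_h, labels, config)
  list(accuracy = lg$accuracy, loss = lg$loss,
       mean_hidden_spikes = lg$mean_hidden_spikes,
       v_out = v_out, s_hidden = s_h)
}

#' Transfer software-trained weights onto a substrate
#'
#' Deploys (quantizes and writes) software-trained weights onto a — possibly
#' decalibrated — substrate and evaluates, without any in-the-loop
#' fine-tuning. The baseline that self-calibration through ITL learning is
#' compared against.
#'
#' @param weights software-trained [network_weights()].
#' @param sub the target [substrate()].
#' @param x,labels evaluation data.
#' @param config a [loss_config()].
#' @return evaluation metrics as in [evaluate_network()].
#' @export
weight_transfer <- function(weights, sub, x, labels, config) {
  evaluate_network(weights, x, labels, config, sub = sub, quantize = TRUE)
}
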