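#' Construct a simulated analog substrate
#'
#' Creates a configuration object for the emulated neuromorphic back end: a
#' population of spiking hidden LIF neurons and a non-spiking leaky-integrator
#' readout layer, each with per-neuron parameters. Fixed-pattern mismatch is
#' drawn once here (frozen for the lifetime of the instance); trial noise from
#' `noise` is drawn independently on every forward pass.
#'
#' The substrate integrates at a fine step `dt / fine_factor` and samples
#' membranes on the coarse grid `dt` (the readout abstraction). The fine
#' integration uses an exact per-step exponential propagator, so for
#' bin-aligned inputs the sampled membrane values coincide with the coarse
#' discrete-time model for any `fine_factor`; spike generation and reset,
#' however, happen at fine resolution, so with `fine_factor > 1` the device
#' can emit spikes between sampling points, which the idealized computation
#' graph only approximates.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param dt sampling interval of the membrane readout, in model time units.
#' @param fine_factor integer >= 1; the dynamics evolve at `dt / fine_factor`.
#' @param params calibration-target parameters for the hidden layer
#'   (`threshold` is forced finite); defaults to [neuron_params()] targets.
#' @param params_out targets for the readout layer; thresholds are set to
#'   `Inf` (non-spiking).
#' @param mismatch optional [mismatch_spec()]; applied to hidden and readout
#'   populations with independent draws (readout thresholds stay `Inf`).
#' @param noise a [noise_spec()]; defaults to small (1% of threshold) noise.
#' @param refractory refractory period in fine steps (0 = none).
#' @return an object of class `snn_substrate`.
#' @export
substrate <- function(n_in, n_hidden, n_out, dt = 1, fine_factor = 10L,
                      params = neuron_params(n_hidden, tau_mem = 20 * dt,
                                             tau_syn = 10 * dt),
                      params_out = neuron_params(n_out, tau_mem = 20 * dt,
                                                 tau_syn = 10 * dt,
                                                 threshold = Inf),
                      mismatch = NULL, noise = noise_spec(),
                      refractory = 0L) {
  stopifnot(fine_factor >= 1)
  params_out$threshold <- rep(Inf, n_out)
  actual_h <- params
  actual_o <- params_out
  if (!is.null(mismatch) && mismatch$sigma_d > 0) {
    actual_h <- decalibrate(params, mismatch)
    spec_o <- mismatch
    spec_o$seed <- derive_seed(mismatch$seed, "readout")
    actual_o <- decalibrate(params_out, spec_o)
  }
  structure(list(
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
    n_out = as.integer(n_out),
    dt = dt, fine_factor = as.integer(fine_factor),
    target_hidden = params, target_out = params_out,
    params_hidden = actual_h, params_out = actual_o,
    mismatch = mismatch, noise = noise,
    refractory = as.integer(refractory),
    weights = NULL, quantized = NULL, state = NULL
  ), class = "snn_substrate")
}

#' @export
print.snn_substrate <- function(x, ...) {
  cat(sprintf("<snn_substrate> %d-%d-%d, dt = %g (fine step %g)\n",
              x$n_in, x$n_hidden, x$n_out, x$dt, x$dt / x$fine_factor))
  if (!is.null(x$mismatch))
    cat(sprintf("  mismatch: sigma_d = %g on %s\n", x$mismatch$sigma_d,
                paste(x$mismatch$which, collapse = ", ")))
  cat(sprintf("  noise: membrane %g, readout %g\n",
              x$noise$membrane_sd, x$noise$readout_sd))
  if (!is.null(x$weights)) cat("  weights deployed",
                               if (!is.null(x$quantized)) "(quantized)\n" else "(float)\n")
  invisible(x)
}

#' Deploy weights onto the substrate
#'
#' Writes a weight configuration to the substrate. With `quantize = TRUE`
#' (the hardware-faithful default) the float master weights are scaled,
#' rounded and cropped via [weight_scale()] and the substrate sees the
#' de-scaled integer values; with `FALSE` the float weights are used directly
#' (idealized substrate).
#'
#' @param sub an [substrate()] object.
#' @param weights a [network_weights()] object.
#' @param quantize apply the 7-bit weight resolution?
#' @param hidden_w_max fixed-scale parameter for hidden synapses, see
#'   [weight_scale()].
#' @return the substrate with the deployed weight view attached.
#' @export
deploy_weights <- function(sub, weights, quantize = TRUE, hidden_w_max = 1.5) {
  stopifnot(inherits(sub, "snn_substrate"), inherits(weights, "network_weights"))
  stopifnot(ncol(weights$w_in) == sub$n_in, nrow(weights$w_in) == sub$n_hidden,
            nrow(weights$w_out) == sub$n_out)
  if (quantize) {
    ws <- weight_scale(weights, hidden_w_max = hidden_w_max)
    sub$weights <- ws$effective
    sub$quantized <- ws$q
  } else {
    sub$weights <- list(w_in = weights$w_in, w_rec = weights$w_rec,
                        w_out = weights$w_out)
    sub$quantized <- NULL
  }
  sub
}

#' Reset the substrate state
#'
#' Clamps all membranes to their leak potentials and all synaptic currents to
#' zero, enabling back-to-back presentation of samples. Idempotent.
#'
#' @param sub an [substrate()] object.
#' @return the substrate with cleared state.
#' @export
reset_state <- function(sub) {
  stopifnot(inherits(sub, "snn_substrate"))
  sub$state <- NULL
  sub
}

#' Emulate a forward pass on the substrate
#'
#' Integrates the (possibly mismatched, noisy, weight-quantized) network
#' dynamics for a batch of input spike patterns and returns the sampled
#' recording: membrane traces on the sampling grid, coarse-binned binary
#' spike trains, and the raw spike event list at fine resolution.
#'
#' @param sub an [substrate()] object with deployed weights (see
#'   [deploy_weights()]), or pass `weights`.
#' @param inputs a [spike_batch()] or a dense input array
#'   `(batch, n_in, T)`.
#' @param weights optional [network_weights()] deployed on the fly
#'   (quantized by default).
#' @param t_steps number of sampling steps; required when `inputs` is a
#'   `spike_batch` whose duration should be overridden.
#' @param hidden_mask optional 0/1 vector of length `n_hidden`; units with 0
#'   are silenced (emit no spikes) for this pass.
#' @param i_ext optional constant external current per hidden neuron.
#' @param record_events keep the raw spike-time event list?
#' @param init_state optional state (as returned in `$final_state`) to resume
#'   from; default starts from leak potential / zero currents.
#' @param quantize when deploying `weights` on the fly, apply the 7-bit
#'   weight resolution (see [deploy_weights()]).
#' @return an object of class `substrate_recording` with elements
#'   `v_hidden`, `spikes` (`(batch, n, T)` arrays), `v_out`, `spike_times`
#'   (matrix time/neuron/sample), `grid_dt`, `final_state`.
#' @export
emulate_forward <- function(sub, inputs, weights = NULL, t_steps = NULL,
                            hidden_mask = NULL, i_ext = NULL,
                            record_events = TRUE, init_state = NULL,
                            quantize = TRUE) {
  stopifnot(inherits(sub, "snn_substrate"))
  if (!is.null(weights)) sub <- deploy_weights(sub, weights, quantize = quantize)
  if (is.null(sub$weights)) stop("no weights deployed on the substrate")
  x <- if (inherits(inputs, "spike_batch"))
    as_dense(inputs, dt = sub$dt, t_steps = t_steps) else inputs
  stopifnot(length(dim(x)) == 3, dim(x)[2] == sub$n_in)
  mask <- hidden_mask %||% rep(1, sub$n_hidden)
  iext <- i_ext %||% rep(0, sub$n_hidden)
  st <- init_state %||% sub$state
  e <- matrix(0, 0, 0)
  ph <- sub$params_hidden; po <- sub$params_out
  res <- substrate_kernel(
    x, sub$weights$w_in, sub$weights$w_rec %||% e, sub$weights$w_out,
    ph$tau_mem, ph$tau_syn, ph$threshold, ph$v_leak, ph$v_reset,
    po$tau_mem, po$tau_syn, po$v_leak,
    sub$dt, sub$fine_factor,
    sub$noise$membrane_sd, sub$noise$readout_sd,
    mask, iext, record_events,
    st$v_h %||% e, st$i_h %||% e, st$v_o %||% e, st$i_o %||% e,
    sub$refractory)
  ev <- res$events
  colnames(ev) <- if (ncol(ev) == 3) c("time", "neuron", "sample") else NULL
  structure(list(
    v_hidden = res$v_hidden, spikes = res$s_hidden, v_out = res$v_out,
    spike_times = ev, grid_dt = sub$dt, fine_factor = sub$fine_factor,
    final_state = res$final
  ), class = "substrate_recording")
}

#' @export
print.substrate_recording <- function(x, ...) {
  d <- dim(x$v_hidden)
  cat(sprintf("<substrate_recording> batch %d, %d hidden, %d steps (dt = %g)\n",
              d[1], d[2], d[3], x$grid_dt))
  cat(sprintf("  %d spike events, %d output units\n",
              nrow(x$spike_times), dim(x$v_out)[2]))
  invisible(x)
}

#' Interpolate a recording onto a finer grid
#'
#' Linearly interpolates the sampled membrane traces onto a grid of step
#' `grid_dt / factor` and re-bins the spikes at the finer resolution from the
#' raw event list, which is kept at fine precision by the substrate. Useful
#' when the computation graph is evaluated on a finer time scale to better
#' capture causal order between spikes.
#'
#' @param recording a `substrate_recording`.
#' @param factor integer >= 1; 1 returns the recording unchanged.
#' @return a `substrate_recording` on the finer grid.
#' @export
interpolate_recording <- function(recording, factor) {
  stopifnot(inherits(recording, "substrate_recording"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(recording)
  interp <- function(v) {
    d <- dim(v); T <- d[3]; Tf <- T * factor
    out <- array(0, c(d[1], d[2], Tf))
    # original sample t sits at fine index t*factor; fill by linear
    # interpolation between successive samples (left edge from 0)
    prev <- array(0, d[1:2])
    for (t in seq_len(T)) {
      cur <- v[, , t, drop = FALSE]
      dim(cur) <- d[1:2]
      for (f in seq_len(factor)) {
        w <- f / factor
        out[, , (t - 1) * factor + f] <- (1 - w) * prev + w * cur
      }
      prev <- cur
    }
    out
  }
  dt_f <- recording$grid_dt / factor
  d <- dim(recording$spikes)
  sp <- array(0, c(d[1], d[2], d[3] * factor))
  ev <- recording$spike_times
  if (nrow(ev) > 0) {
    bin <- ceiling(ev[, "time"] / dt_f)
    bin[bin < 1] <- 1
    keep <- bin <= d[3] * factor
    sp[cbind(ev[keep, "sample"], ev[keep, "neuron"], bin[keep])] <- 1
  }
  structure(list(
    v_hidden = interp(recording$v_hidden), spikes = sp,
    v_out = interp(recording$v_out), spike_times = ev,
    grid_dt = dt_f, fine_factor = recording$fine_factor,
    final_state = recording$final_state
  ), class = "substrate_recording")
}
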