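#' Surrogate-derivative specification
#'
#' Shape and steepness of the pseudo-derivative substituted for the spike
#' nonlinearity's derivative during BPTT. The default `"superspike"` form is
#' `(1 + beta * |v - threshold|)^-2`: bounded in (0, 1], maximal at the
#' threshold, symmetric and monotonically decreasing in the distance to it.
#' The `"literal"` form `(beta * |v - threshold|)^-2` diverges at the
#' threshold and is guarded by an epsilon floor on the distance; use it with
#' gradient clipping. `"zero"` disables the surrogate route entirely
#' (diagnostic: no gradient can flow through spikes).
#'
#' @param beta steepness of the surrogate; >= 0.
#' @param form one of `"superspike"`, `"literal"`, `"zero"`.
#' @param eps distance floor for the `"literal"` form.
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(beta = 10, form = c("superspike", "literal", "zero"),
                           eps = 1e-2) {
  if (beta < 0) stop("beta must be >= 0")
  form <- match.arg(form)
  structure(list(beta = beta, form = form, eps = eps,
                 form_id = match(form, c("superspike", "literal", "zero")) - 1L),
            class = "surrogate_spec")
}

#' Surrogate derivative of the spike nonlinearity
#'
#' Evaluates the pseudo-derivative `dS/dV` at membrane value(s) `v` for a
#' firing threshold. Used in place of the (zero-almost-everywhere) true
#' derivative of the threshold function during the backward pass.
#'
#' @param v membrane value(s).
#' @param threshold firing threshold (scalar or same shape as `v`).
#' @param spec a [surrogate_spec()].
#' @return numeric of the same shape as `v`.
#' @examples
#' surrogate_spike_derivative(1, 1, surrogate_spec(beta = 5))   # 1 at threshold
#' surrogate_spike_derivative(2, 1, surrogate_spec(beta = 1))   # (1 + 1)^-2
#' @export
surrogate_spike_derivative <- function(v, threshold, spec = surrogate_spec()) {
  u <- abs(v - threshold)
  switch(spec$form,
         superspike = 1 / (1 + spec$beta * u)^2,
         literal = 1 / (spec$beta * pmax(u, spec$eps))^2,
         zero = 0 * u)
}

#' Identity injection of measured values
#'
#' The trace-injection primitive: an auxiliary identity `f(x, x~) = x` whose
#' forward value is the measured quantity while the backward pass routes the
#' entire upstream gradient to the modeled argument (`df/dx = 0`,
#' `df/dx~ = 1`). Injecting recorded membranes and spikes through this
#' identity is what renders the emulated network differentiable.
#'
#' @param measured measured (recorded) values.
#' @param modeled model-estimated values of the same shape.
#' @return `measured`, unchanged.
#' @seealso [inject_value_grad()] for the backward rule.
#' @export
inject_value <- function(measured, modeled) {
  if (!identical(dim(measured) %||% length(measured),
                 dim(modeled) %||% length(modeled)))
    stop("measured and modeled must have the same shape")
  measured
}

#' Backward rule of the identity injection
#'
#' @param upstream gradient flowing into the injected value.
#' @return list with components `measured` (always zero) and `modeled`
#'   (the upstream gradient, passed through unchanged).
#' @export
inject_value_grad <- function(upstream) {
  list(measured = upstream * 0, modeled = upstream)
}

#' Unroll the differentiable computation graph
#'
#' Builds the discrete-time LIF computation graph on the sampling grid and
#' returns the forward output traces together with a backward closure that
#' computes BPTT weight gradients for arbitrary loss gradients.
#'
#' Two modes share one code path:
#' * With a `recording` (in-the-loop mode), the recorded spikes and membrane
#'   traces are injected through the identity of [inject_value()]: forward
#'   values are the measured ones, and the surrogate derivative is evaluated
#'   on the recorded membranes, while the model recursions (with the
#'   *idealized* `params`, even when the substrate is decalibrated) carry the
#'   gradients.
#' * With `recording = NULL` (pure simulation), the graph generates its own
#'   spikes by thresholding the model membrane — the classical software
#'   surrogate-gradient setup.
#'
#' @param inputs a [spike_batch()] or dense `(batch, n_in, T)` array.
#' @param weights a [network_weights()] object (float master copy).
#' @param params idealized hidden-layer [neuron_params()] used in the graph.
#' @param params_out idealized readout parameters.
#' @param recording optional `substrate_recording` to inject.
#' @param spec a [surrogate_spec()].
#' @param dt grid step.
#' @param t_steps number of steps (when `inputs` is a `spike_batch`).
#' @param hidden_mask optional 0/1 dropout mask over hidden units.
#' @param detach_reset if `TRUE` (default) the reset gate is excluded from
#'   gradient flow.
#' @return list with `v_out` (forward output traces, `(batch, n_out, T)`),
#'   `s_hidden`, `v_hidden` (forward-used values), and `backward(g_vout,
#'   g_spikes)`, a function returning the weight gradients as a list
#'   `w_in`/`w_rec`/`w_out`.
#' @export
unroll <- function(inputs, weights, params, params_out,
                   recording = NULL, spec = surrogate_spec(), dt = 1,
                   t_steps = NULL, hidden_mask = NULL, detach_reset = TRUE) {
  stopifnot(inherits(weights, "network_weights"))
  x <- if (inherits(inputs, "spike_batch"))
    as_dense(inputs, dt = dt, t_steps = t_steps) else inputs
  n_h <- nrow(weights$w_in)
  mask <- hidden_mask %||% rep(1, n_h)

  if (is.null(recording)) {
    sim <- simulate_network(x, weights, params, params_out, dt = dt,
                            hidden_mask = mask)
    s_h <- sim$spikes
    v_h <- sim$v_hidden
    v_o <- sim$v_out
  } else {
    stopifnot(inherits(recording, "substrate_recording"))
    if (abs(recording$grid_dt - dt) > 1e-12)
      stop("recording grid (", recording$grid_dt,
           ") does not match the graph step (", dt, ")")
    if (dim(recording$spikes)[2] != n_h)
      stop("recording has ", dim(recording$spikes)[2],
           " hidden channels; weights expect ", n_h)
    s_h <- recording$spikes
    v_h <- recording$v_hidden
    v_o <- recording$v_out
    if (any(mask == 0)) {
      s_h[, mask == 0, ] <- 0
    }
  }

  lam_m_h <- exp(-dt / params$tau_mem)
  lam_s_h <- exp(-dt / params$tau_syn)
  lam_m_o <- exp(-dt / params_out$tau_mem)
  lam_s_o <- exp(-dt / params_out$tau_syn)
  e <- matrix(0, 0, 0)

  backward <- function(g_vout, g_spikes = NULL) {
    if (is.null(g_spikes)) g_spikes <- array(0, dim(s_h))
    g <- graph_backward_kernel(
      x, s_h, v_h, g_vout, g_spikes,
      weights$w_in, weights$w_rec %||% e, weights$w_out,
      lam_m_h, lam_s_h, lam_m_o, lam_s_o, params$threshold,
      spec$beta, spec$form_id, spec$eps, mask, detach_reset)
    if (is.null(weights$w_rec)) g$w_rec <- NULL
    g
  }

  list(v_out = v_o, s_hidden = s_h, v_hidden = v_h, backward = backward)
}

#' Pure software simulation of the network
#'
#' Runs the idealized discrete-time model (the same recursions the
#' computation graph assumes) as a forward simulation: spikes are generated
#' by thresholding the model membrane on the sampling grid, with no
#' mismatch, no noise and float weights. Equivalent to an ideal noiseless
#' substrate clocked on the sampling grid.
#'
#' @inheritParams unroll
#' @param x dense input array or [spike_batch()].
#' @return a `substrate_recording` (model-generated).
#' @export
simulate_network <- function(x, weights, params, params_out, dt = 1,
                             t_steps = NULL, hidden_mask = NULL) {
  sub <- substrate(ncol(weights$w_in), nrow(weights$w_in), nrow(weights$w_out),
                   dt = dt, fine_factor = 1L, params = params,
                   params_out = params_out, noise = noise_spec(0, 0))
  sub <- deploy_weights(sub, weights, quantize = FALSE)
  emulate_forward(sub, x, t_steps = t_steps, hidden_mask = hidden_mask,
                  record_events = FALSE)
}
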