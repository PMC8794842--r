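#' Per-neuron LIF parameters
#'
#' Container for the physical model parameters of a population of leaky
#' integrate-and-fire neurons, in the dimensionless convention (leak potential
#' 0, capacitance 1, firing threshold 1 unless stated otherwise). All fields
#' are vectors of length `n`, so heterogeneous (mismatched) populations are
#' represented directly.
#'
#' @param n number of neurons.
#' @param tau_mem membrane time constant(s), in model time units; must be > 0.
#' @param tau_syn synaptic time constant(s); must be > 0.
#' @param threshold firing threshold(s). Use `Inf` for non-spiking
#'   (readout) units.
#' @param v_leak leak (resting) potential(s).
#' @param v_reset reset potential(s) applied at the step after a spike.
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params(4)
#' p$tau_mem
#' @export
neuron_params <- function(n, tau_mem = 20, tau_syn = 10, threshold = 1,
                          v_leak = 0, v_reset = 0) {
  p <- list(
    n = as.integer(n),
    tau_mem = rep_len(tau_mem, n),
    tau_syn = rep_len(tau_syn, n),
    threshold = rep_len(threshold, n),
    v_leak = rep_len(v_leak, n),
    v_reset = rep_len(v_reset, n)
  )
  class(p) <- "neuron_params"
  validate_neuron_params(p)
  p
}

validate_neuron_params <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  if (any(p$tau_mem <= 0)) stop("tau_mem must be positive for every neuron")
  if (any(p$tau_syn <= 0)) stop("tau_syn must be positive for every neuron")
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf("<neuron_params> %d neurons\n", x$n))
  cat(sprintf("  tau_mem: mean %.3g  tau_syn: mean %.3g  threshold: mean %.3g\n",
              mean(x$tau_mem), mean(x$tau_syn), mean(x$threshold[is.finite(x$threshold)])))
  lot <- sum(leak_over_threshold(x))
  if (lot > 0) cat(sprintf("  %d neuron(s) flagged leak-over-threshold\n", lot))
  invisible(x)
}

#' Flag leak-over-threshold neurons
#'
#' A neuron whose firing threshold does not exceed its leak potential sits in
#' a dysfunctional state: it fires continuously without any input. Strong
#' decalibration of the threshold can push neurons into this regime.
#'
#' @param params a [neuron_params()] object.
#' @return logical vector, `TRUE` where `threshold <= v_leak`.
#' @export
leak_over_threshold <- function(params) {
  validate_neuron_params(params)
  params$threshold <= params$v_leak
}

#' Fixed-pattern mismatch specification
#'
#' Describes how far per-neuron parameters are detuned from their calibration
#' targets: each selected parameter is redrawn from a normal distribution
#' centred on the target with standard deviation `sigma_d` times the target.
#' The draw is made once per substrate instance (fixed-pattern deviation, the
#' same across trials), in contrast to the per-trial noise of [noise_spec()].
#'
#' @param sigma_d normalized SD of the decalibration, as a fraction of the
#'   target value (typically 0 to 0.5).
#' @param which character vector naming the parameters to detune, a subset of
#'   `c("tau_mem", "tau_syn", "threshold")`.
#' @param seed integer seed making the draw reproducible.
#' @return an object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(sigma_d, which = c("tau_mem", "tau_syn", "threshold"),
                          seed = 1L) {
  if (sigma_d < 0) stop("sigma_d must be >= 0")
  which <- match.arg(which, c("tau_mem", "tau_syn", "threshold"),
                     several.ok = TRUE)
  if (sigma_d > 0 && length(which) == 0)
    stop("'which' must be non-empty when sigma_d > 0")
  structure(list(sigma_d = sigma_d, which = which, seed = as.integer(seed)),
            class = "mismatch_spec")
}

#' Trial-to-trial noise specification
#'
#' Models the intrinsic stochasticity of the analog substrate as additive
#' Gaussian noise: `membrane_sd` is the diffusion SD of the membrane per
#' sampling interval (applied in the dynamics, scaled to the fine integration
#' step), and `readout_sd` the SD of the sampling jitter added to recorded
#' membrane values. With both zero the substrate is deterministic given
#' weights and inputs.
#'
#' @param membrane_sd per-sampling-interval membrane noise SD (model units,
#'   i.e. fractions of the unit threshold). Default 1% of the threshold.
#' @param readout_sd readout sampling noise SD. Default 1% of the threshold.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(membrane_sd = 0.01, readout_sd = 0.01) {
  if (membrane_sd < 0 || readout_sd < 0) stop("noise SDs must be >= 0")
  structure(list(membrane_sd = membrane_sd, readout_sd = readout_sd),
            class = "noise_spec")
}

#' Decalibrate neuron parameters
#'
#' Draws new per-neuron values for the parameters selected in `spec` from
#' normal distributions whose mean is the calibration target (the value in
#' `params`) and whose SD is `sigma_d` times that target. Time constants are
#' redrawn until positive, so their interpretation as decay constants
#' survives strong decalibration; thresholds are not redrawn and may fall
#' below the leak potential, leaving the neuron in a leak-over-threshold
#' state (see [leak_over_threshold()]).
#'
#' @param params calibration-target parameters, a [neuron_params()] object.
#' @param spec a [mismatch_spec()].
#' @return a new `neuron_params` object with the detuned values.
#' @examples
#' p <- neuron_params(256)
#' d <- decalibrate(p, mismatch_spec(0.3, seed = 7))
#' sd(d$tau_mem) / mean(d$tau_mem)  # close to 0.3
#' @export
decalibrate <- function(params, spec) {
  validate_neuron_params(params)
  stopifnot(inherits(spec, "mismatch_spec"))
  if (spec$sigma_d == 0) return(params)
  out <- params
  with_seed(spec$seed, {
    for (field in spec$which) {
      target <- params[[field]]
      finite <- is.finite(target)
      draw <- target
      draw[finite] <- stats::rnorm(sum(finite), mean = target[finite],
                                   sd = spec$sigma_d * abs(target[finite]))
      if (field %in% c("tau_mem", "tau_syn")) {
        bad <- which(draw <= 0)
        tries <- 0L
        while (length(bad) > 0) {
          tries <- tries + 1L
          if (tries > 1000L)
            stop("decalibrate: failed to draw positive time constants after ",
                 "1000 redraws; sigma_d is degenerate")
          draw[bad] <- stats::rnorm(length(bad), mean = target[bad],
                                    sd = spec$sigma_d * abs(target[bad]))
          bad <- bad[draw[bad] <= 0]
        }
      }
      # non-spiking units (threshold Inf) keep their threshold
      if (field == "threshold") draw[!is.finite(target)] <- target[!is.finite(target)]
      out[[field]] <- draw
    }
  })
  out
}
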