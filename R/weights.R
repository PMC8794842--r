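#' Signed network weights with a quantized deployment view
#'
#' Bundles the input, recurrent and output weight matrices of a single-hidden-
#' layer spiking network. The float matrices are the trainable master copy;
#' [weight_scale()] derives the 7-bit signed integer view that is deployed on
#' the substrate (two 6-bit synapse circuits of opposite sign merged into one
#' signed weight in \[-63, 63\]).
#'
#' @param w_in input-to-hidden matrix, `n_hidden x n_in`.
#' @param w_out hidden-to-output matrix, `n_out x n_hidden`.
#' @param w_rec optional hidden-to-hidden matrix, `n_hidden x n_hidden`;
#'   `NULL` for a feed-forward network.
#' @param fan_in_limit maximum allowed fan-in per hidden neuron (synapse
#'   column depth of the substrate).
#' @return an object of class `network_weights`.
#' @export
network_weights <- function(w_in, w_out, w_rec = NULL, fan_in_limit = 256L) {
  w_in <- as.matrix(w_in); w_out <- as.matrix(w_out)
  n_h <- nrow(w_in)
  if (!is.null(w_rec)) {
    w_rec <- as.matrix(w_rec)
    stopifnot(nrow(w_rec) == n_h, ncol(w_rec) == n_h)
  }
  stopifnot(ncol(w_out) == n_h)
  fan_in <- ncol(w_in) + if (is.null(w_rec)) 0L else n_h
  if (fan_in > fan_in_limit)
    stop(sprintf("fan-in per hidden neuron (%d) exceeds the substrate limit (%d)",
                 fan_in, fan_in_limit))
  structure(list(w_in = w_in, w_rec = w_rec, w_out = w_out,
                 fan_in_limit = as.integer(fan_in_limit)),
            class = "network_weights")
}

#' @export
print.network_weights <- function(x, ...) {
  cat(sprintf("<network_weights> %d -> %d%s -> %d\n",
              ncol(x$w_in), nrow(x$w_in),
              if (is.null(x$w_rec)) "" else " (recurrent)", nrow(x$w_out)))
  invisible(x)
}

#' Quantize a weight matrix to the substrate's resolution
#'
#' Scales, rounds and crops weights to signed 7-bit integers: each entry maps
#' to `clip(round(w * scale), -63, 63)`. Saturation at the bounds is the
#' defined behavior, not an error. Re-applying with `scale = 1` leaves an
#' already-quantized matrix unchanged.
#'
#' @param w numeric matrix (or vector) of weights.
#' @param scale positive scale factor applied before rounding.
#' @param w_max magnitude of the largest representable integer weight.
#' @return integer-valued matrix of the same shape.
#' @examples
#' quantize_weights(c(0, 1, 2), scale = 63)  # 0, 63, 63 (saturated)
#' @export
quantize_weights <- function(w, scale, w_max = 63L) {
  if (scale <= 0) stop("scale must be positive")
  q <- round(w * scale)
  q[q > w_max] <- w_max
  q[q < -w_max] <- -w_max
  q
}

#' Scale and quantize network weights for deployment
#'
#' Hidden-layer matrices (input and recurrent) use a fixed configurable scale
#' `63 / hidden_w_max`, chosen once to align the software weight range with
#' the integer range. The output layer, being non-spiking, can be scaled
#' arbitrarily, so it uses a dynamic rule: the largest absolute software
#' weight maps to the maximum representable weight (63). Both the integer
#' matrices and the scales are returned so the effective deployed weight
#' `q / scale` can be reconstructed consistently.
#'
#' @param weights a [network_weights()] object.
#' @param hidden_w_max software weight magnitude mapped to 63 on hidden
#'   synapses.
#' @return list with `q` (integer matrices), `scales` (per matrix) and
#'   `effective` (de-scaled deployed values `q / scale`).
#' @export
weight_scale <- function(weights, hidden_w_max = 1.5) {
  stopifnot(inherits(weights, "network_weights"))
  s_hidden <- 63 / hidden_w_max
  m <- max(abs(weights$w_out))
  s_out <- if (m > 0) 63 / m else 1.0
  q <- list(
    w_in = quantize_weights(weights$w_in, s_hidden),
    w_rec = if (is.null(weights$w_rec)) NULL else quantize_weights(weights$w_rec, s_hidden),
    w_out = quantize_weights(weights$w_out, s_out)
  )
  eff <- list(
    w_in = q$w_in / s_hidden,
    w_rec = if (is.null(q$w_rec)) NULL else q$w_rec / s_hidden,
    w_out = q$w_out / s_out
  )
  list(q = q, scales = c(w_in = s_hidden, w_rec = s_hidden, w_out = s_out),
       effective = eff)
}

#' Initialize network weights
#'
#' Kaiming-style initialization: entries are drawn from a zero-mean normal
#' distribution with SD `sigma_w / sqrt(fan_in)` of the receiving layer
#' (hidden fan-in for input and recurrent weights, hidden size for output
#' weights).
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param recurrent logical; include a recurrent hidden matrix?
#' @param sigma_w weight-scale multiplier.
#' @param seed integer seed; draws are reproducible.
#' @param sigma_w_rec optional separate multiplier for the recurrent matrix
#'   (defaults to `sigma_w`).
#' @return a [network_weights()] object.
#' @export
init_weights <- function(n_in, n_hidden, n_out, recurrent = FALSE,
                         sigma_w = 1, seed = 1L, sigma_w_rec = sigma_w) {
  with_seed(seed, {
    w_in <- matrix(stats::rnorm(n_hidden * n_in, 0, sigma_w / sqrt(n_in)),
                   n_hidden, n_in)
    w_rec <- if (recurrent)
      matrix(stats::rnorm(n_hidden * n_hidden, 0, sigma_w_rec / sqrt(n_hidden)),
             n_hidden, n_hidden) else NULL
    w_out <- matrix(stats::rnorm(n_out * n_hidden, 0, sigma_w / sqrt(n_hidden)),
                    n_out, n_hidden)
    network_weights(w_in, w_out, w_rec)
  })
}

#' Silence randomly selected hidden units
#'
#' Emulates post-deployment neuron failure: `floor(fraction * n_hidden)`
#' hidden units are drawn without replacement and all their input, recurrent
#' and output connections are zeroed.
#'
#' @param weights a [network_weights()] object.
#' @param fraction fraction of hidden units to silence, in \[0, 1\].
#' @param seed integer seed selecting the units.
#' @return a new `network_weights` object with the selected units silenced.
#' @export
ablate_hidden <- function(weights, fraction, seed = 1L) {
  stopifnot(inherits(weights, "network_weights"), fraction >= 0, fraction <= 1)
  n_h <- nrow(weights$w_in)
  k <- floor(fraction * n_h)
  if (k == 0) return(weights)
  idx <- with_seed(seed, sample.int(n_h, k))
  out <- weights
  out$w_in[idx, ] <- 0
  out$w_out[, idx] <- 0
  if (!is.null(out$w_rec)) { out$w_rec[idx, ] <- 0; out$w_rec[, idx] <- 0 }
  out
}

#' Shuffle the recurrent weights and mark them frozen
#'
#' Control condition for assessing the benefit of learned recurrence: the
#' entries of the recurrent matrix are randomly permuted (preserving their
#' multiset) and flagged non-trainable, so subsequent training only updates
#' the input and output weights.
#'
#' @param weights a trained [network_weights()] object with a recurrent
#'   matrix.
#' @param seed integer seed for the permutation.
#' @return a `network_weights` object with shuffled `w_rec` and attribute
#'   `freeze_rec = TRUE`.
#' @export
freeze_recurrent_control <- function(weights, seed = 1L) {
  stopifnot(inherits(weights, "network_weights"))
  if (is.null(weights$w_rec)) stop("weights have no recurrent matrix")
  out <- weights
  perm <- with_seed(seed, sample.int(length(out$w_rec)))
  out$w_rec <- matrix(out$w_rec[perm], nrow(out$w_rec), ncol(out$w_rec))
  attr(out, "freeze_rec") <- TRUE
  out
}
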