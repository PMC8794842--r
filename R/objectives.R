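#' Loss configuration
#'
#' Bundles the task-loss mode and regularizer strengths applied to a batch:
#' the classification loss on the output membrane traces (max- or
#' sum-over-time readout), an amplitude penalty discouraging output
#' excursions that would clip on an analog substrate, a quadratic sparsity
#' penalty on per-neuron hidden spike counts, and a one-sided homeostatic
#' penalty on the total hidden spike count. Losses are averaged over the
#' batch; regularizers are computed per sample and batch-averaged.
#'
#' @param mode `"max_over_time"` or `"sum_over_time"`.
#' @param rho_a amplitude-penalty strength.
#' @param rho_b sparsity strength (quadratic in per-neuron spike counts).
#' @param rho_r homeostatic strength (one-sided quadratic in the total count).
#' @param theta_r activity threshold of the homeostatic term.
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(mode = c("max_over_time", "sum_over_time"),
                        rho_a = 0, rho_b = 0, rho_r = 0, theta_r = 0) {
  mode <- match.arg(mode)
  if (rho_a < 0 || rho_b < 0 || rho_r < 0)
    stop("regularizer strengths must be >= 0")
  structure(list(mode = mode, rho_a = rho_a, rho_b = rho_b,
                 rho_r = rho_r, theta_r = theta_r),
            class = "loss_config")
}

# per-class scores: running max (with earliest argmax) or sum over time
trace_scores <- function(v_out, mode) {
  d <- dim(v_out)
  scores <- matrix(v_out[, , 1], d[1], d[2])
  if (mode == "sum_over_time") {
    if (d[3] > 1) for (t in 2:d[3]) scores <- scores + v_out[, , t]
    list(scores = scores, argmax = NULL)
  } else {
    argmax <- matrix(1L, d[1], d[2])
    if (d[3] > 1) for (t in 2:d[3]) {
      cur <- matrix(v_out[, , t], d[1], d[2])
      upd <- cur > scores              # strict: ties keep the earliest step
      argmax[upd] <- t
      scores[upd] <- cur[upd]
    }
    list(scores = scores, argmax = argmax)
  }
}

nll_from_scores <- function(scores, labels) {
  b <- nrow(scores)
  ll <- scores[cbind(seq_len(b), labels)] - logsumexp_rows(scores)
  -mean(ll)
}

#' Max-over-time classification loss
#'
#' Negative log-likelihood of the true class under a softmax over the
#' per-class maxima of the output membrane traces, averaged over the batch.
#'
#' @param v_out output traces, array `(batch, n_classes, T)` (a single
#'   sample may be passed as a `T x n_classes` matrix).
#' @param labels integer class labels in `1..n_classes`, length batch.
#' @return scalar loss.
#' @examples
#' v <- array(0, c(1, 10, 5))       # all classes identical
#' max_over_time_nll(v, 1)          # log(10)
#' @export
max_over_time_nll <- function(v_out, labels) {
  v_out <- as_trace_array(v_out)
  if (dim(v_out)[3] < 1) stop("empty trace")
  nll_from_scores(trace_scores(v_out, "max_over_time")$scores, labels)
}

#' Sum-over-time classification loss
#'
#' As [max_over_time_nll()] with the per-class sum over time as the score;
#' suited to evidence accumulated across a whole pattern, as in speech-like
#' tasks.
#'
#' @inheritParams max_over_time_nll
#' @return scalar loss.
#' @export
sum_over_time_nll <- function(v_out, labels) {
  v_out <- as_trace_array(v_out)
  if (dim(v_out)[3] < 1) stop("empty trace")
  nll_from_scores(trace_scores(v_out, "sum_over_time")$scores, labels)
}

#' Amplitude penalty on output traces
#'
#' `rho_a` times the mean over output units of the squared per-unit
#' max-over-time, batch-averaged. Discourages trace amplitudes that would
#' saturate the analog readout range.
#'
#' @inheritParams max_over_time_nll
#' @param rho_a penalty strength.
#' @return scalar penalty.
#' @export
amplitude_penalty <- function(v_out, rho_a) {
  v_out <- as_trace_array(v_out)
  m <- trace_scores(v_out, "max_over_time")$scores
  rho_a * mean(rowMeans(m^2))
}

#' Quadratic sparsity regularizer on hidden spikes
#'
#' `rho_b / N_H` times the sum over hidden neurons of the squared per-neuron
#' spike count, per sample, batch-averaged. Because its gradient reaches the
#' weights only through the surrogate route, it can only reduce activity and
#' exerts no upward homeostatic pull.
#'
#' @param s_hidden binary hidden spike array `(batch, n_hidden, T)` (or
#'   `T x n_hidden` for one sample).
#' @param rho_b penalty strength.
#' @return scalar penalty.
#' @examples
#' s <- array(0, c(1, 2, 4)); s[1, 1, 1:3] <- 1; s[1, 2, 1] <- 1
#' sparsity_regularizer(s, 1)  # (3^2 + 1^2) / 2 = 5
#' @export
sparsity_regularizer <- function(s_hidden, rho_b) {
  s_hidden <- as_trace_array(s_hidden)
  counts <- apply(s_hidden, c(1, 2), sum)      # batch x n_hidden
  n_h <- ncol(counts)
  rho_b * mean(rowSums(counts^2) / n_h)
}

#' One-sided homeostatic regularizer
#'
#' Zero while the total hidden spike count of a sample stays below the
#' activity threshold `theta_r`; quadratic in the excess above it.
#'
#' @inheritParams sparsity_regularizer
#' @param rho_r penalty strength.
#' @param theta_r activity threshold (total spikes per sample).
#' @return scalar penalty.
#' @export
homeostatic_regularizer <- function(s_hidden, rho_r, theta_r) {
  s_hidden <- as_trace_array(s_hidden)
  tot <- apply(s_hidden, 1, sum)
  rho_r * mean(pmax(0, tot - theta_r)^2)
}

as_trace_array <- function(v) {
  if (length(dim(v)) == 3) return(v)
  v <- as.matrix(v)                       # T x n, single sample
  array(aperm(v, c(2, 1)), c(1, ncol(v), nrow(v)))
}

#' Total loss and its gradients
#'
#' Evaluates the configured task loss plus regularizers on a batch and
#' returns the gradients with respect to the output traces and the hidden
#' spike train, ready to feed the backward pass of [unroll()]. All gradients
#' carry the 1/batch factor.
#'
#' @param v_out output traces `(batch, n_classes, T)`.
#' @param s_hidden hidden spikes `(batch, n_hidden, T)`.
#' @param labels integer labels.
#' @param config a [loss_config()].
#' @return list with `loss` (total), `terms` (named components), `accuracy`,
#'   `g_vout` and `g_spikes` (arrays shaped like the inputs).
#' @export
loss_and_grads <- function(v_out, s_hidden, labels, config) {
  stopifnot(inherits(config, "loss_config"))
  d <- dim(v_out); b <- d[1]; n_c <- d[2]; T <- d[3]
  sc <- trace_scores(v_out, config$mode)
  p <- softmax_rows(sc$scores)
  loss_task <- -mean(log(pmax(p[cbind(seq_len(b), labels)], 1e-300)))
  g_scores <- p
  g_scores[cbind(seq_len(b), labels)] <-
    g_scores[cbind(seq_len(b), labels)] - 1
  g_scores <- g_scores / b

  # amplitude penalty always uses the per-unit max
  terms <- c(task = loss_task)
  g_max <- NULL
  if (config$rho_a > 0) {
    mx <- if (config$mode == "max_over_time") sc
          else trace_scores(v_out, "max_over_time")
    terms["amplitude"] <- config$rho_a * mean(rowMeans(mx$scores^2))
    g_max <- list(argmax = mx$argmax,
                  g = 2 * config$rho_a * mx$scores / (n_c * b))
  }

  g_vout <- array(0, d)
  if (config$mode == "max_over_time") {
    idx <- cbind(rep(seq_len(b), n_c), rep(seq_len(n_c), each = b),
                 as.vector(sc$argmax))
    g_vout[idx] <- g_vout[idx] + as.vector(g_scores)
  } else {
    for (t in seq_len(T)) g_vout[, , t] <- g_vout[, , t] + g_scores
  }
  if (!is.null(g_max)) {
    idx <- cbind(rep(seq_len(b), n_c), rep(seq_len(n_c), each = b),
                 as.vector(g_max$argmax))
    g_vout[idx] <- g_vout[idx] + as.vector(g_max$g)
  }

  g_spikes <- array(0, dim(s_hidden))
  n_h <- dim(s_hidden)[2]
  counts <- apply(s_hidden, c(1, 2), sum)
  if (config$rho_b > 0) {
    terms["sparsity"] <- config$rho_b * mean(rowSums(counts^2) / n_h)
    gc <- 2 * config$rho_b * counts / (n_h * b)      # batch x n_hidden
    for (t in seq_len(dim(s_hidden)[3]))
      g_spikes[, , t] <- g_spikes[, , t] + gc
  }
  if (config$rho_r > 0) {
    tot <- rowSums(counts)
    excess <- pmax(0, tot - config$theta_r)
    terms["homeostatic"] <- config$rho_r * mean(excess^2)
    gtot <- 2 * config$rho_r * excess / b            # per sample
    for (t in seq_len(dim(s_hidden)[3]))
      g_spikes[, , t] <- g_spikes[, , t] + gtot      # recycled over units
  }

  pred <- max.col(sc$scores, ties.method = "first")
  list(loss = sum(terms), terms = terms,
       accuracy = mean(pred == labels),
       mean_hidden_spikes = mean(rowSums(counts)),
       g_vout = g_vout, g_spikes = g_spikes)
}
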