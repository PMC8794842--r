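# Slow, transparent pure-R reference implementation of the discrete-time
# model and its BPTT gradients, written directly from the unrolled recursion
# with explicit per-step lists. Used as the independent oracle for the
# compiled kernels and for the ITL-equals-simulation property.

`%||%` <- function(a, b) if (is.null(a)) b else a

zeros_cube <- function(b, n, t) array(0, dim = c(b, n, t))

ref_surrogate <- function(v, thr, spec) {
  u <- abs(v - thr)
  switch(spec$form,
         superspike = 1 / (1 + spec$beta * u)^2,
         literal = 1 / (spec$beta * pmax(u, spec$eps))^2,
         zero = u * 0)
}

# forward simulation on the sampling grid (one sample, matrices T x n);
# returns the per-step states. x: T x n_in binary.
ref_forward <- function(x, w, params, params_out, spec,
                        s_inject = NULL, v_inject = NULL, mask = NULL) {
  T <- nrow(x); n_h <- nrow(w$w_in); n_o <- nrow(w$w_out)
  lam_m <- exp(-1 / params$tau_mem); lam_s <- exp(-1 / params$tau_syn)
  lam_mo <- exp(-1 / params_out$tau_mem); lam_so <- exp(-1 / params_out$tau_syn)
  mask <- mask %||% rep(1, n_h)
  V <- I <- matrix(0, T + 1, n_h); S <- matrix(0, T + 1, n_h)
  Vo <- Io <- matrix(0, T + 1, n_o)
  for (t in 1:T) {
    V[t + 1, ] <- (1 - S[t, ]) * (V[t, ] * lam_m + I[t, ])
    if (!is.null(v_inject)) V[t + 1, ] <- v_inject[t, ]   # identity injection
    I[t + 1, ] <- I[t, ] * lam_s + as.vector(w$w_in %*% x[t, ])
    if (!is.null(w$w_rec)) I[t + 1, ] <- I[t + 1, ] + as.vector(w$w_rec %*% S[t, ])
    S[t + 1, ] <- if (!is.null(s_inject)) s_inject[t, ]
                  else mask * as.numeric(V[t + 1, ] >= params$threshold)
    Vo[t + 1, ] <- Vo[t, ] * lam_mo + Io[t, ]
    Io[t + 1, ] <- Io[t, ] * lam_so + as.vector(w$w_out %*% S[t, ])
  }
  list(V = V, I = I, S = S, Vo = Vo, Io = Io)
}

# BPTT on the reference forward; g_vout / g_s: T x n matrices of direct loss
# gradients w.r.t. Vo[t+1] / S[t+1] (i.e. recorded step t). Returns weight
# gradients.
ref_backward <- function(x, w, params, params_out, spec, fwd,
                         g_vout, g_s = NULL, mask = NULL,
                         detach_reset = TRUE) {
  T <- nrow(x); n_h <- nrow(w$w_in); n_o <- nrow(w$w_out)
  lam_m <- exp(-1 / params$tau_mem); lam_s <- exp(-1 / params$tau_syn)
  lam_mo <- exp(-1 / params_out$tau_mem); lam_so <- exp(-1 / params_out$tau_syn)
  mask <- mask %||% rep(1, n_h)
  if (is.null(g_s)) g_s <- matrix(0, T, n_h)
  aV <- aI <- matrix(0, T + 2, n_h); aVo <- aIo <- matrix(0, T + 2, n_o)
  gW_in <- matrix(0, n_h, ncol(w$w_in))
  gW_rec <- if (is.null(w$w_rec)) NULL else matrix(0, n_h, n_h)
  gW_out <- matrix(0, n_o, n_h)
  for (t in T:1) {
    aVo[t + 1, ] <- g_vout[t, ] + lam_mo * aVo[t + 2, ]
    aIo[t + 1, ] <- aVo[t + 2, ] + lam_so * aIo[t + 2, ]
    gS <- g_s[t, ] + as.vector(t(w$w_out) %*% aIo[t + 2, ])
    if (!is.null(w$w_rec)) gS <- gS + as.vector(t(w$w_rec) %*% aI[t + 2, ])
    if (!detach_reset)
      gS <- gS - (fwd$V[t + 1, ] * lam_m + fwd$I[t + 1, ]) * aV[t + 2, ]
    sd <- mask * ref_surrogate(fwd$V[t + 1, ], params$threshold, spec)
    gate <- 1 - fwd$S[t + 1, ]          # reset gate carries S[t] (row t+1)
    aV[t + 1, ] <- gate * lam_m * aV[t + 2, ] + sd * gS
    aI[t + 1, ] <- gate * aV[t + 2, ] + lam_s * aI[t + 2, ]
    gW_in <- gW_in + outer(aI[t + 1, ], x[t, ])
    if (!is.null(gW_rec)) gW_rec <- gW_rec + outer(aI[t + 1, ], fwd$S[t, ])
    gW_out <- gW_out + outer(aIo[t + 1, ], fwd$S[t, ])
  }
  list(w_in = gW_in, w_rec = gW_rec, w_out = gW_out)
}

# convenience: dense cube for a single sample from a T x n_in matrix
one_sample_cube <- function(x) array(t(x), c(1, ncol(x), nrow(x)))

# small random test network
make_test_net <- function(n_in = 6, n_h = 5, n_o = 3, recurrent = FALSE,
                          seed = 1, sigma = 0.3) {
  set.seed(seed)
  network_weights(
    matrix(rnorm(n_h * n_in, 0, sigma), n_h, n_in),
    matrix(rnorm(n_o * n_h, 0, sigma), n_o, n_h),
    if (recurrent) matrix(rnorm(n_h * n_h, 0, sigma / 2), n_h, n_h) else NULL)
}

random_spikes <- function(T, n, p = 0.1, seed = 1) {
  set.seed(seed)
  matrix(as.numeric(runif(T * n) < p), T, n)
}
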