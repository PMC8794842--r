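test_that("decalibration reproduces the requested mismatch width", {
  p <- neuron_params(256)
  expect_identical(decalibrate(p, mismatch_spec(0, seed = 1)), p)

  d <- decalibrate(p, mismatch_spec(0.3, seed = 7))
  for (f in c("tau_mem", "tau_syn", "threshold")) {
    cv <- stats::sd(d[[f]]) / mean(d[[f]])
    expect_gt(cv, 0.3 - 3 * 0.3 / sqrt(2 * 255))   # sampling error on the SD
    expect_lt(cv, 0.3 + 4 * 0.3 / sqrt(2 * 255))
  }
  expect_true(all(d$tau_mem > 0), info = "time constants redrawn positive")
  # frozen pattern: same spec gives the same draw
  expect_identical(d, decalibrate(p, mismatch_spec(0.3, seed = 7)))
  expect_false(identical(d, decalibrate(p, mismatch_spec(0.3, seed = 8))))
})

test_that("strong threshold decalibration yields leak-over-threshold flags", {
  p <- neuron_params(256)
  counts <- vapply(1:5, function(s) {
    d <- decalibrate(p, mismatch_spec(0.5, which = "threshold", seed = s))
    sum(leak_over_threshold(d))
  }, 0L)
  # P(threshold <= 0) = pnorm(-2) ~ 2.3%; some flags expected across seeds
  expect_gt(sum(counts), 0)
  expect_lt(mean(counts) / 256, 0.10)
  expect_identical(sum(leak_over_threshold(p)), 0L)
})

test_that("weight quantization scales, rounds and saturates", {
  expect_equal(quantize_weights(matrix(0, 2, 2), 63), matrix(0, 2, 2))
  expect_equal(quantize_weights(1.0, 63), 63)
  expect_equal(quantize_weights(2.0, 63), 63)
  expect_equal(quantize_weights(-2.0, 63), -63)
  q <- quantize_weights(matrix(rnorm(100), 10), 40)
  expect_equal(quantize_weights(q, 1), q)   # idempotent on quantized values
  expect_true(all(abs(q) <= 63))
})

test_that("output-layer weight scaling is dynamic and scale-covariant", {
  w <- network_weights(matrix(0.1, 2, 3), matrix(c(0.5, -0.25, 0.1, 0), 2, 2))
  ws <- weight_scale(w)
  expect_equal(unname(ws$scales["w_out"]), 63 / 0.5)
  expect_equal(max(abs(ws$q$w_out)), 63)
  w2 <- w; w2$w_out <- w$w_out * 2
  expect_equal(weight_scale(w2)$q$w_out, ws$q$w_out)  # doubling is invisible
  w0 <- w; w0$w_out <- w$w_out * 0
  ws0 <- weight_scale(w0)
  expect_equal(unname(ws0$scales["w_out"]), 1.0)
  expect_true(all(ws0$q$w_out == 0))
})

test_that("quiescent substrate stays at the leak potential", {
  sub <- substrate(2, 3, 2, fine_factor = 5, noise = noise_spec(0, 0))
  sub <- deploy_weights(sub, network_weights(matrix(0, 3, 2), matrix(0, 2, 3)),
                        quantize = FALSE)
  rec <- emulate_forward(sub, array(0, c(1, 2, 20)))
  expect_equal(max(abs(rec$v_hidden)), 0)
  expect_equal(sum(rec$spikes), 0)
  expect_equal(nrow(rec$spike_times), 0L)
})

test_that("PSP peak matches the closed-form double exponential", {
  tm <- 20; ts <- 10; wv <- 0.1; T <- 80
  sub <- substrate(1, 1, 1, fine_factor = 10, noise = noise_spec(0, 0))
  sub <- deploy_weights(sub, network_weights(matrix(wv, 1, 1), matrix(0, 1, 1)),
                        quantize = FALSE)
  x <- array(0, c(1, 1, T)); x[1, 1, 6] <- 1
  rec <- emulate_forward(sub, x)
  tstar <- tm * ts / (tm - ts) * log(tm / ts)
  peak <- wv * (exp(-tstar / tm) - exp(-tstar / ts)) /
    (exp(-1 / tm) - exp(-1 / ts))
  # sampled on the fine grid: agreement to within one fine step's curvature
  expect_lt(abs(max(rec$v_hidden) - peak) / peak, 1e-3)
})

test_that("constant-drive firing matches the analytic LIF interval", {
  tm <- 20; I0 <- 0.08; F <- 20
  sub <- substrate(1, 1, 1, fine_factor = F, noise = noise_spec(0, 0))
  sub <- deploy_weights(sub, network_weights(matrix(0, 1, 1), matrix(0, 1, 1)),
                        quantize = FALSE)
  rec <- emulate_forward(sub, array(0, c(1, 1, 200)), i_ext = I0)
  isi <- diff(rec$spike_times[, "time"])
  expect_gt(length(isi), 3)
  expect_lt(stats::sd(isi), 1e-12)        # perfectly periodic without noise
  t_true <- tm * log(I0 * tm / (I0 * tm - 1))
  delta <- 1 / F
  # reset occupies exactly one fine step; the rest is grid rounding
  expect_lt(abs(isi[1] - delta - t_true), delta)
})

test_that("membranes decay exponentially between inputs", {
  sub <- substrate(1, 4, 1, fine_factor = 4, noise = noise_spec(0, 0),
                   params = neuron_params(4, tau_mem = c(10, 15, 20, 40)))
  sub <- deploy_weights(sub, network_weights(matrix(0, 4, 1), matrix(0, 1, 4)),
                        quantize = FALSE)
  init <- list(v_h = matrix(0.8, 1, 4), i_h = matrix(0, 1, 4),
               v_o = matrix(0, 1, 1), i_o = matrix(0, 1, 1))
  rec <- emulate_forward(sub, array(0, c(1, 1, 25)), init_state = init)
  for (j in 1:4) {
    expected <- 0.8 * exp(-(1:25) / sub$params_hidden$tau_mem[j])
    expect_lt(max(abs(rec$v_hidden[1, j, ] - expected) / expected), 1e-6)
  }
})

test_that("reset enables identical back-to-back presentations", {
  set.seed(3)
  sub <- substrate(4, 6, 2, fine_factor = 2, noise = noise_spec(0, 0))
  w <- init_weights(4, 6, 2, sigma_w = 3, seed = 5)
  sub <- deploy_weights(sub, w, quantize = FALSE)
  x <- array(as.numeric(runif(4 * 30) < 0.2), c(1, 4, 30))
  r1 <- emulate_forward(sub, x)
  # second presentation resumed from the final state, after a reset
  sub2 <- reset_state(sub)
  expect_null(sub2$state)
  r2 <- emulate_forward(sub2, x)
  expect_identical(r1$v_hidden, r2$v_hidden)
  expect_identical(r1$spike_times, r2$spike_times)
  # without reset the carried state changes the response
  r3 <- emulate_forward(sub, x, init_state = r1$final_state)
  expect_false(identical(r1$v_hidden, r3$v_hidden))
})

test_that("fixed-pattern mismatch is frozen while trial noise varies", {
  mk <- function() substrate(2, 8, 2, mismatch = mismatch_spec(0.3, seed = 4),
                             noise = noise_spec(0.05, 0.05))
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$params_hidden, s2$params_hidden)
  w <- init_weights(2, 8, 2, seed = 1)
  s1 <- deploy_weights(s1, w)
  x <- array(0, c(1, 2, 10)); x[1, 1, 2] <- 1
  set.seed(11); r1 <- emulate_forward(s1, x)
  set.seed(12); r2 <- emulate_forward(s1, x)
  expect_false(identical(r1$v_hidden, r2$v_hidden))
  set.seed(11); r3 <- emulate_forward(s1, x)
  expect_identical(r1$v_hidden, r3$v_hidden)
})

test_that("raw spike times fall into their recorded grid bins", {
  sub <- substrate(1, 1, 1, fine_factor = 10, noise = noise_spec(0, 0))
  sub <- deploy_weights(sub, network_weights(matrix(0, 1, 1), matrix(0, 1, 1)),
                        quantize = FALSE)
  rec <- emulate_forward(sub, array(0, c(1, 1, 100)), i_ext = 0.1)
  expect_gt(nrow(rec$spike_times), 0)
  bins <- ceiling(rec$spike_times[, "time"] / rec$grid_dt)
  for (k in seq_len(nrow(rec$spike_times)))
    expect_equal(rec$spikes[1, 1, bins[k]], 1)
  expect_equal(sum(rec$spikes), nrow(rec$spike_times))
})

test_that("non-finite substrate state raises a diagnostic", {
  sub <- substrate(1, 2, 1, noise = noise_spec(0, 0))
  w <- network_weights(matrix(1e308, 2, 1), matrix(1, 1, 2),
                       w_rec = matrix(1e308, 2, 2))
  sub <- deploy_weights(sub, w, quantize = FALSE)
  x <- array(0, c(1, 1, 20)); x[1, 1, 1] <- 1
  expect_error(emulate_forward(sub, x), "non-finite")
})

test_that("fan-in limit is enforced at construction", {
  expect_error(network_weights(matrix(0, 10, 300), matrix(0, 2, 10)),
               "fan-in")
  expect_error(network_weights(matrix(0, 200, 100), matrix(0, 2, 200),
                               w_rec = matrix(0, 200, 200)), "fan-in")
  expect_silent(network_weights(matrix(0, 10, 256), matrix(0, 2, 10)))
})
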