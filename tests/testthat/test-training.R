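test_that("weight initialization matches the Kaiming scale", {
  w0 <- init_weights(256, 246, 10, sigma_w = 0, seed = 1)
  expect_equal(max(abs(w0$w_in)), 0)
  w <- init_weights(256, 246, 10, sigma_w = 1, seed = 2)
  expect_lt(abs(stats::sd(w$w_in) - 1 / sqrt(256)) * sqrt(256), 0.05)
  expect_lt(abs(stats::sd(w$w_out) - 1 / sqrt(246)) * sqrt(246), 0.05)
  expect_identical(w, init_weights(256, 246, 10, sigma_w = 1, seed = 2))
  expect_false(identical(w, init_weights(256, 246, 10, sigma_w = 1, seed = 3)))
})

test_that("hidden ablation silences exactly the requested fraction", {
  w <- init_weights(10, 246, 5, recurrent = TRUE, seed = 1,
                    sigma_w = 1)
  expect_identical(ablate_hidden(w, 0), w)
  wa <- ablate_hidden(w, 0.15, seed = 4)
  dead <- which(rowSums(abs(wa$w_in)) == 0)
  expect_length(dead, 36L)                      # floor(0.15 * 246)
  expect_equal(colSums(abs(wa$w_out))[dead], numeric(36),
               ignore_attr = TRUE)
  expect_equal(rowSums(abs(wa$w_rec))[dead], numeric(36), ignore_attr = TRUE)
  expect_equal(colSums(abs(wa$w_rec))[dead], numeric(36), ignore_attr = TRUE)
  # full ablation leaves the readout at the leak potential
  wf <- ablate_hidden(w, 1, seed = 1)
  params <- neuron_params(246); po <- neuron_params(5, threshold = Inf)
  sim <- simulate_network(zeros_cube(1, 10, 10) + 1, wf, params, po)
  expect_equal(max(abs(sim$v_out)), 0)
})

test_that("dropout masks keep roughly 1 - rate of the units", {
  expect_equal(apply_dropout(50, 0), rep(1, 50))
  expect_equal(apply_dropout(50, 1, seed = 2), rep(0, 50))
  keep <- mean(vapply(1:200, function(s) mean(apply_dropout(100, 0.4, s)), 0))
  expect_lt(abs(keep - 0.6), 0.01)
})

test_that("recurrent shuffle preserves the multiset and freezes updates", {
  w <- init_weights(6, 8, 3, recurrent = TRUE, seed = 3)
  f <- freeze_recurrent_control(w, seed = 5)
  expect_equal(sort(as.vector(f$w_rec)), sort(as.vector(w$w_rec)))
  expect_false(identical(f$w_rec, w$w_rec))
  expect_true(isTRUE(attr(f, "freeze_rec")))
  expect_error(freeze_recurrent_control(init_weights(6, 8, 3), 1),
               "no recurrent")

  # frozen matrix does not move during training
  st <- train_state(f, lr = 0.05)
  x <- array(as.numeric(runif(5 * 6 * 20) < 0.2), c(5, 6, 20))
  sub <- substrate(6, 8, 3, noise = noise_spec(0, 0))
  res <- itl_step(st, sub, x, c(1, 2, 3, 1, 2), loss_config())
  expect_identical(res$state$weights$w_rec, f$w_rec)
  expect_false(identical(res$state$weights$w_in, f$w_in))
})

test_that("the ITL step updates the float master copy only", {
  w <- init_weights(6, 8, 3, seed = 2)
  st <- train_state(w, lr = 1e-2)
  sub <- substrate(6, 8, 3, noise = noise_spec(0, 0))
  x <- array(as.numeric(runif(4 * 6 * 20) < 0.25), c(4, 6, 20))
  labels <- c(1, 3, 2, 1)
  res <- itl_step(st, sub, x, labels, loss_config())
  expect_false(identical(res$state$weights$w_in, w$w_in))
  expect_true(is.finite(res$metrics$loss))
  # the master copy is continuous even though the substrate saw integers
  dq <- weight_scale(res$state$weights)$q$w_in
  expect_false(identical(res$state$weights$w_in, dq))

  # zero learning rate computes metrics without moving weights
  st0 <- train_state(w, lr = 0)
  res0 <- itl_step(st0, sub, x, labels, loss_config())
  expect_identical(res0$state$weights$w_in, w$w_in)
  expect_true(is.finite(res0$metrics$loss))
})

test_that("ideal ITL and software training produce identical trajectories", {
  set.seed(1)
  x <- array(as.numeric(runif(20 * 6 * 30) < 0.15), c(20, 6, 30))
  labels <- sample(1:3, 20, replace = TRUE)
  w <- init_weights(6, 10, 3, seed = 7)
  sub <- substrate(6, 10, 3, fine_factor = 1, noise = noise_spec(0, 0))
  cfg <- loss_config(rho_a = 0.01, rho_b = 1e-3)
  itl <- fit_itl(sub, x, labels, train_state(w, lr = 5e-3), cfg,
                 epochs = 3, batch_size = 10, quantize = FALSE, seed = 42)
  sw <- train_software_only(x, labels, train_state(w, lr = 5e-3), cfg,
                            sub$target_hidden, sub$target_out,
                            epochs = 3, batch_size = 10, seed = 42)
  expect_equal(itl$weights$w_in, sw$weights$w_in, tolerance = 1e-12)
  expect_equal(itl$history, sw$history, tolerance = 1e-12)

  # a decalibrated substrate breaks the equivalence
  subd <- substrate(6, 10, 3, fine_factor = 1, noise = noise_spec(0, 0),
                    mismatch = mismatch_spec(0.3, seed = 2))
  itld <- fit_itl(subd, x, labels, train_state(w, lr = 5e-3), cfg,
                  epochs = 3, batch_size = 10, quantize = FALSE, seed = 42)
  expect_false(isTRUE(all.equal(itld$weights$w_in, sw$weights$w_in)))
})

test_that("weight transfer evaluates without touching the weights", {
  set.seed(2)
  x <- array(as.numeric(runif(10 * 6 * 20) < 0.2), c(10, 6, 20))
  labels <- sample(1:3, 10, replace = TRUE)
  w <- init_weights(6, 8, 3, seed = 1)
  sub <- substrate(6, 8, 3, noise = noise_spec(0, 0))
  wc <- unserialize(serialize(w, NULL))
  tr <- weight_transfer(w, sub, x, labels, loss_config())
  expect_identical(w, wc)
  expect_true(tr$accuracy >= 0 && tr$accuracy <= 1)
})

test_that("training from a quiescent hidden layer ignites through the surrogate", {
  # weak subthreshold weights: no hidden spikes at the start. Gradients still
  # flow through the surrogate route — the substrate's intrinsic noise breaks
  # the tie in the max-over-time readout of the otherwise flat output traces
  # — and spiking activity emerges on a separable task.
  ds <- make_latency_images(latency_task_spec(n_classes = 2, shape = c(4, 4),
                                              samples_per_class = 20,
                                              pixel_noise_sd = 0.05, seed = 3))
  enc <- latency_encode(ds$images, latency_code_spec(tau_in = 5, theta_in = 0.2,
                                                     t_max = 30),
                        duration = 30, labels = ds$labels)
  x <- as_dense(enc, t_steps = 30)
  w <- init_weights(16, 12, 2, sigma_w = 0.1, seed = 1)
  sub <- substrate(16, 12, 2, fine_factor = 1)       # default 1% noise
  sub0 <- deploy_weights(sub, w, quantize = FALSE)
  expect_equal(sum(emulate_forward(sub0, x)$spikes), 0)
  st <- fit_itl(sub, x, ds$labels, train_state(w, lr = 5e-3),
                loss_config(rho_a = 0.01), epochs = 30, batch_size = 10,
                quantize = FALSE, seed = 9)
  ev <- evaluate_network(st$weights, x, ds$labels, loss_config(), sub = sub,
                         quantize = FALSE)
  expect_gt(ev$mean_hidden_spikes, 0)
  expect_gt(ev$accuracy, 0.9)
})
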