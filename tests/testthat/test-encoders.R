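test_that("latency code follows the printed spike-time formula", {
  spec <- latency_code_spec(tau_in = 3, theta_in = 0.5, t_max = 100)
  sb <- latency_encode(c(1, 0.5, 0.2, 0.8), spec, duration = 100)
  ev <- sb$events[[1]]
  expect_equal(ev$channel, c(1, 4))          # pixels at/below theta are silent
  expect_equal(ev$time[ev$channel == 1], 3 * log(2))
  expect_equal(ev$time[ev$channel == 4], 3 * log(0.8 / 0.3))
  expect_error(latency_encode(c(0.5, 1.2), spec), "\\[0, 1\\]")
})

test_that("latency code is strictly earlier for brighter pixels", {
  spec <- latency_code_spec(tau_in = 10, theta_in = 0.2, t_max = 1e6)
  xs <- seq(0.21, 1, by = 0.01)
  sb <- latency_encode(xs, spec, duration = 1e6)
  ev <- sb$events[[1]]
  t_by_channel <- ev$time[order(ev$channel)]
  expect_equal(length(t_by_channel), length(xs))
  expect_true(all(diff(t_by_channel) < 0))
  # cutoff drops late spikes
  sb2 <- latency_encode(xs, latency_code_spec(10, 0.2, t_max = 5))
  expect_lt(nrow(sb2$events[[1]]), length(xs))
  expect_true(all(sb2$events[[1]]$time <= 5))
})

test_that("image downscaling crops the border and preserves intensity", {
  expect_equal(downscale_image(matrix(0.37, 28, 28)), matrix(0.37, 16, 16))
  expect_equal(downscale_image(matrix(0, 28, 28)), matrix(0, 16, 16))
  img <- matrix(0, 28, 28)
  img[10:12, 14:16] <- 1                      # 3x3 block inside the crop
  out <- downscale_image(img)
  expect_true(all(out >= 0 & out <= 1))
  # area averaging: total mass scales by the area ratio (24/16)^2
  expect_equal(sum(out), sum(img) / (24 / 16)^2, tolerance = 1e-10)
  expect_error(downscale_image(matrix(0, 27, 28)), "28x28")
})

test_that("channel subsampling keeps every 9th unit after the first 70", {
  # channels here are 1-based: source channel 71 is the 0-based unit 70
  ev <- data.frame(time = c(1, 2, 3, 4, 5),
                   channel = c(70, 71, 79, 692, 700))
  sb <- spike_batch(list(ev), 700, 10)
  out <- subsample_channels(sb)
  expect_equal(out$n_channels, 70L)           # 700 -> 70 channels
  # sources 70 (among the first seventy) and 79, 700 (off-stride) dropped;
  # source 71 -> 1, source 692 (the last retained unit) -> 70
  expect_equal(out$events[[1]]$channel, c(1L, 70L))
  expect_equal(out$events[[1]]$time, c(2, 4))
})

test_that("time scaling compresses and preserves order", {
  ev <- data.frame(time = c(0.2, 1.4, 0.9), channel = c(1, 2, 3))
  sb <- spike_batch(list(ev), 3, 2)
  expect_equal(scale_time(sb, 1)$events, sb$events)
  out <- scale_time(sb, 2000)
  expect_equal(out$duration, 2 / 2000)
  expect_equal(out$events[[1]]$time, ev$time / 2000)
  expect_equal(order(out$events[[1]]$time), order(ev$time))
})

test_that("channel jitter reassigns but never creates or drops events", {
  ev <- data.frame(time = runif(500, 0, 10), channel = rep(350L, 500))
  sb <- spike_batch(list(ev), 700, 10)
  expect_identical(jitter_channels(sb, 0), sb)
  out <- jitter_channels(sb, 1, seed = 9)
  expect_equal(nrow(out$events[[1]]), 500)
  expect_identical(out$events[[1]]$time, ev$time)
  expect_lt(abs(stats::sd(out$events[[1]]$channel) - 1), 0.2)
  expect_lt(abs(mean(out$events[[1]]$channel) - 350), 0.2)
  expect_identical(jitter_channels(sb, 1, seed = 9), out)
  # clipping at the range edges, not dropping
  edge <- spike_batch(list(data.frame(time = runif(100), channel = rep(1L, 100))),
                      700, 1)
  je <- jitter_channels(edge, 3, seed = 1)
  expect_equal(nrow(je$events[[1]]), 100)
  expect_true(all(je$events[[1]]$channel >= 1))
})

test_that("augmentation composes with subsampling in the stated order", {
  # jitter on the 700-channel stream moves events between *source* channels,
  # so survivors after subsampling differ from subsample-then-jitter
  set.seed(2)
  ev <- data.frame(time = runif(400, 0, 5),
                   channel = sample(c(71L, 80L, 89L), 400, TRUE))
  sb <- spike_batch(list(ev), 700, 5)
  a <- subsample_channels(jitter_channels(sb, 2, seed = 3))
  b <- subsample_channels(sb)
  expect_equal(a$n_channels, 70L)
  # jitter before subsampling loses events that land on dropped channels
  expect_lt(nrow(a$events[[1]]), nrow(b$events[[1]]))
})

test_that("dense binning assigns events by flooring onto the grid", {
  ev <- data.frame(time = c(0, 0.99, 1.0, 2.5), channel = c(1, 1, 2, 3))
  sb <- spike_batch(list(ev), 3, 4)
  x <- as_dense(sb, dt = 1)
  expect_equal(dim(x), c(1, 3, 4))
  expect_equal(x[1, 1, 1], 1)     # two events collapse into one binary entry
  expect_equal(x[1, 2, 2], 1)     # tie at the bin edge opens the later bin
  expect_equal(x[1, 3, 3], 1)
  expect_equal(sum(x), 3)
})

test_that("rotation preserves shape and roughly preserves mass", {
  img <- matrix(0, 20, 20); img[8:12, 8:12] <- 1
  out <- rotate_image(img, 15)
  expect_equal(dim(out), c(20L, 20L))
  expect_lt(abs(sum(out) - sum(img)) / sum(img), 0.1)
  expect_identical(rotate_image(img, 0), img)
})
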