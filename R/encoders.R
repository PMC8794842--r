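#' Batched input spike events
#'
#' Holds a batch of input patterns as raw (time, channel) event lists plus
#' the metadata needed to bin them onto a simulation grid. Times are in
#' model time units; channels are 1-based.
#'
#' @param events list with one `data.frame(time, channel)` per sample.
#' @param n_channels number of input channels.
#' @param duration pattern duration in model time units.
#' @param labels optional integer class labels.
#' @return an object of class `spike_batch`.
#' @export
spike_batch <- function(events, n_channels, duration, labels = NULL) {
  stopifnot(is.list(events))
  for (ev in events) {
    if (nrow(ev) == 0) next
    if (any(ev$channel < 1 | ev$channel > n_channels))
      stop("event channel out of range 1..", n_channels)
    if (any(ev$time < 0 | ev$time >= duration))
      stop("event time out of range [0, duration)")
  }
  structure(list(events = events, n_channels = as.integer(n_channels),
                 duration = duration, labels = labels),
            class = "spike_batch")
}

#' @export
print.spike_batch <- function(x, ...) {
  n_ev <- vapply(x$events, nrow, 0L)
  cat(sprintf("<spike_batch> %d samples, %d channels, duration %g\n",
              length(x$events), x$n_channels, x$duration))
  cat(sprintf("  spikes/sample: mean %.1f (range %d-%d)\n",
              mean(n_ev), min(n_ev), max(n_ev)))
  invisible(x)
}

#' @export
`[.spike_batch` <- function(x, i) {
  spike_batch(x$events[i], x$n_channels, x$duration,
              labels = if (is.null(x$labels)) NULL else x$labels[i])
}

#' @export
length.spike_batch <- function(x) length(x$events)

#' Bin a spike batch onto a dense time grid
#'
#' Events are assigned to grid bins by `floor(time / dt)` (ties at bin edges
#' go to the earlier... i.e. the bin they open); multiple events of one
#' channel in a bin collapse to a single binary entry.
#'
#' @param batch a [spike_batch()].
#' @param dt grid step.
#' @param t_steps number of bins; defaults to `ceiling(duration / dt)`.
#' @return binary array `(batch, n_channels, t_steps)`.
#' @export
as_dense <- function(batch, dt = 1, t_steps = NULL) {
  stopifnot(inherits(batch, "spike_batch"))
  T <- t_steps %||% ceiling(batch$duration / dt)
  x <- array(0, c(length(batch$events), batch$n_channels, T))
  for (b in seq_along(batch$events)) {
    ev <- batch$events[[b]]
    if (nrow(ev) == 0) next
    bin <- floor(ev$time / dt) + 1L
    keep <- bin >= 1 & bin <= T
    x[cbind(b, ev$channel[keep], bin[keep])] <- 1
  }
  x
}

#' Latency-code specification
#'
#' Parameters of the input LIF units that convert intensities into single
#' spike times: a pixel of normalized intensity `x` acts as a constant input
#' current and triggers a spike at `t = tau_in * log(x / (x - theta_in))`
#' when `x` exceeds the input threshold; weaker pixels stay silent.
#'
#' @param tau_in input unit time constant (model time units).
#' @param theta_in input threshold, in (0, 1).
#' @param t_max cutoff; later spikes are dropped.
#' @return an object of class `latency_code_spec`.
#' @export
latency_code_spec <- function(tau_in = 20, theta_in = 0.2, t_max = 60) {
  if (tau_in <= 0) stop("tau_in must be > 0")
  if (theta_in <= 0 || theta_in >= 1) stop("theta_in must be in (0, 1)")
  structure(list(tau_in = tau_in, theta_in = theta_in, t_max = t_max),
            class = "latency_code_spec")
}

#' Latency-encode intensity images into spikes
#'
#' Each pixel with intensity above the input threshold emits exactly one
#' spike, earlier for brighter pixels: `t_i = tau_in * log(x_i /
#' (x_i - theta_in))`. Pixels at or below the threshold emit none (the spike
#' time diverges), and spikes beyond `t_max` are dropped.
#'
#' @param pixels matrix `n_samples x n_pixels` with values in \[0, 1\]
#'   (a single image may be passed as a vector).
#' @param spec a [latency_code_spec()].
#' @param duration pattern duration of the resulting batch; defaults to
#'   `spec$t_max`.
#' @param labels optional labels carried through.
#' @return a [spike_batch()] with `n_pixels` channels.
#' @examples
#' sb <- latency_encode(c(1, 0.5, 0.1), latency_code_spec(theta_in = 0.5))
#' sb$events[[1]]  # one spike at tau_in * log(2); dimmer pixels silent
#' @export
latency_encode <- function(pixels, spec = latency_code_spec(),
                           duration = NULL, labels = NULL) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1)
  if (any(pixels < 0 | pixels > 1)) stop("pixels must lie in [0, 1]")
  duration <- duration %||% spec$t_max
  events <- lapply(seq_len(nrow(pixels)), function(i) {
    x <- pixels[i, ]
    on <- which(x > spec$theta_in)
    t <- spec$tau_in * log(x[on] / (x[on] - spec$theta_in))
    keep <- t <= spec$t_max & t < duration
    data.frame(time = t[keep], channel = on[keep])
  })
  spike_batch(events, n_channels = ncol(pixels), duration = duration,
              labels = labels)
}

#' Downscale a 28x28 image to 16x16
#'
#' Crops the two outermost pixels on every side (28 -> 24) and rescales the
#' remainder to 16x16 by area averaging, which preserves mean intensity.
#'
#' @param img numeric 28x28 matrix, values in \[0, 1\].
#' @return 16x16 matrix in \[0, 1\].
#' @export
downscale_image <- function(img) {
  if (!identical(dim(img), c(28L, 28L))) stop("expected a 28x28 image")
  crop <- img[3:26, 3:26]
  A <- area_weights(24L, 16L)
  A %*% crop %*% t(A)
}

# n_out x n_in row-stochastic matrix of fractional interval overlaps
area_weights <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  r <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * r; hi <- i * r
    for (j in seq_len(ceiling(hi) - floor(lo))) {
      cell <- floor(lo) + j
      A[i, cell] <- (min(hi, cell) - max(lo, cell - 1)) / r
    }
  }
  A
}

#' Rotate a grayscale image
#'
#' Rotation about the image centre with bilinear resampling; used as data
#' augmentation before downscaling. Pixels sampled from outside the source
#' are zero.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param angle rotation angle in degrees (counter-clockwise).
#' @return matrix of the same shape.
#' @export
rotate_image <- function(img, angle) {
  if (angle == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    dy <- i - cy
    for (j in seq_len(w)) {
      dx <- j - cx
      # inverse mapping: source position of output pixel (i, j)
      sy <- cy + cos(th) * dy + sin(th) * dx
      sx <- cx - sin(th) * dy + cos(th) * dx
      y0 <- floor(sy); x0 <- floor(sx)
      if (y0 >= 1 && y0 < h && x0 >= 1 && x0 < w) {
        fy <- sy - y0; fx <- sx - x0
        out[i, j] <- (1 - fy) * ((1 - fx) * img[y0, x0] + fx * img[y0, x0 + 1]) +
                     fy * ((1 - fx) * img[y0 + 1, x0] + fx * img[y0 + 1, x0 + 1])
      }
    }
  }
  out
}

#' Subsample event-stream channels
#'
#' Reduces a 700-channel event stream to 70 channels by omitting the first
#' `n_skip` source channels and then retaining every `stride`-th one, with
#' contiguous remapping of the survivors to `1..n_kept`. Events on dropped
#' channels are discarded.
#'
#' @param batch a [spike_batch()] with `n_source` channels.
#' @param n_skip number of leading source channels to omit.
#' @param stride keep every `stride`-th channel after the skip.
#' @return a [spike_batch()] with the reduced channel set.
#' @export
subsample_channels <- function(batch, n_skip = 70L, stride = 9L) {
  stopifnot(inherits(batch, "spike_batch"))
  src <- seq_len(batch$n_channels)
  kept <- src[src > n_skip & (src - n_skip - 1L) %% stride == 0L]
  map <- rep(NA_integer_, batch$n_channels)
  map[kept] <- seq_along(kept)
  events <- lapply(batch$events, function(ev) {
    new <- map[ev$channel]
    keep <- !is.na(new)
    data.frame(time = ev$time[keep], channel = new[keep])
  })
  spike_batch(events, n_channels = length(kept), duration = batch$duration,
              labels = batch$labels)
}

#' Rescale event times
#'
#' Divides all event times (and the pattern duration) by `factor`, mapping
#' dataset time (e.g. seconds of audio) onto model time. Order preserving.
#'
#' @param batch a [spike_batch()].
#' @param factor positive scale factor.
#' @return a [spike_batch()] on the compressed time axis.
#' @export
scale_time <- function(batch, factor) {
  stopifnot(inherits(batch, "spike_batch"))
  if (factor <= 0) stop("factor must be > 0")
  events <- lapply(batch$events, function(ev)
    data.frame(time = ev$time / factor, channel = ev$channel))
  spike_batch(events, batch$n_channels, batch$duration / factor,
              labels = batch$labels)
}

#' Stochastic channel-jitter augmentation
#'
#' Reassigns each event from channel `i` to `round(Normal(i, sigma))`,
#' clipped to the valid channel range (round half away from zero). Event
#' count and times are preserved. Intended to be applied on the full-
#' resolution channel set, before any subsampling.
#'
#' @param batch a [spike_batch()].
#' @param sigma SD of the channel displacement; 0 is the identity.
#' @param seed integer seed.
#' @return a [spike_batch()] with jittered channels.
#' @export
jitter_channels <- function(batch, sigma, seed = 1L) {
  stopifnot(inherits(batch, "spike_batch"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(batch)
  with_seed(seed, {
    events <- lapply(batch$events, function(ev) {
      if (nrow(ev) == 0) return(ev)
      shifted <- stats::rnorm(nrow(ev), mean = ev$channel, sd = sigma)
      ch <- sign(shifted) * floor(abs(shifted) + 0.5)   # half away from zero
      ch <- pmin(pmax(ch, 1), batch$n_channels)
      data.frame(time = ev$time, channel = as.integer(ch))
    })
    spike_batch(events, batch$n_channels, batch$duration,
                labels = batch$labels)
  })
}

#' Read an IDX-format array file
#'
#' Minimal reader for the IDX binary container used by classic image
#' datasets (magic header, big-endian dimensions, unsigned-byte data).
#' Returns images as an `n x rows x cols` array scaled to \[0, 1\], or a
#' vector for 1-dimensional label files.
#'
#' @param path file path (optionally gzip-compressed).
#' @return numeric array or vector.
#' @export
read_idx <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  ndim <- magic %% 256
  dims <- readBin(con, "integer", ndim, size = 4, endian = "big")
  data <- readBin(con, "integer", prod(dims), size = 1, signed = FALSE)
  if (ndim == 1) return(data)
  arr <- array(data, dim = rev(dims))
  aperm(arr, rev(seq_len(ndim))) / 255
}
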