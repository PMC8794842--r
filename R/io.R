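# HDF5 serialization of recordings and event datasets (rhdf5). Recordings
# round-trip the sampled traces, coarse spike raster and the raw event list;
# datasets use the common event-stream layout (groups spikes/times,
# spikes/units, labels) so externally provided files are drop-in
# replacements for the synthetic generators.

need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("package 'rhdf5' is required for HDF5 I/O")
}

#' Write a substrate recording to HDF5
#'
#' Layout: datasets `v_sampled` (T x N x batch), `spikes` (same shape),
#' `v_out`, `spike_times` (event rows: time, neuron, sample) and attributes
#' `grid_dt`, `fine_factor`.
#'
#' @param recording a `substrate_recording`.
#' @param path output file.
#' @export
write_recording_h5 <- function(recording, path) {
  need_rhdf5()
  stopifnot(inherits(recording, "substrate_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  tr <- function(a) aperm(a, c(3, 2, 1))   # (batch, n, T) -> (T, n, batch)
  rhdf5::h5write(tr(recording$v_hidden), path, "v_sampled")
  rhdf5::h5write(tr(recording$spikes), path, "spikes")
  rhdf5::h5write(tr(recording$v_out), path, "v_out")
  rhdf5::h5write(unclass(recording$spike_times), path, "spike_times")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(recording$grid_dt, fid, "grid_dt")
  rhdf5::h5writeAttribute(recording$fine_factor, fid, "fine_factor")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a substrate recording from HDF5
#'
#' @param path file written by [write_recording_h5()].
#' @return a `substrate_recording`.
#' @export
read_recording_h5 <- function(path) {
  need_rhdf5()
  tr <- function(a) aperm(a, c(3, 2, 1))
  ev <- rhdf5::h5read(path, "spike_times")
  if (length(ev)) colnames(ev) <- c("time", "neuron", "sample")
  fid <- rhdf5::H5Fopen(path)
  grid_dt <- as.numeric(rhdf5::h5readAttributes(fid, "/")$grid_dt)
  fine_factor <- as.integer(rhdf5::h5readAttributes(fid, "/")$fine_factor)
  rhdf5::H5Fclose(fid)
  structure(list(
    v_hidden = tr(rhdf5::h5read(path, "v_sampled")),
    spikes = tr(rhdf5::h5read(path, "spikes")),
    v_out = tr(rhdf5::h5read(path, "v_out")),
    spike_times = ev, grid_dt = grid_dt, fine_factor = fine_factor,
    final_state = NULL), class = "substrate_recording")
}

#' Write a spike dataset in the event-stream HDF5 layout
#'
#' Groups `spikes/times` and `spikes/units` hold the concatenated event
#' times and 0-based channel indices with `spikes/offsets` marking the first
#' event of each sample; `labels` holds 0-based class labels. Attributes
#' record `n_channels` and `duration`.
#'
#' @param batch a labeled [spike_batch()].
#' @param path output file.
#' @export
write_spike_dataset_h5 <- function(batch, path) {
  need_rhdf5()
  stopifnot(inherits(batch, "spike_batch"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "spikes")
  n_ev <- vapply(batch$events, nrow, 0L)
  rhdf5::h5write(unlist(lapply(batch$events, `[[`, "time")) %||% numeric(0),
                 path, "spikes/times")
  rhdf5::h5write(as.integer(
    unlist(lapply(batch$events, `[[`, "channel")) - 1L) %||% integer(0),
    path, "spikes/units")
  rhdf5::h5write(cumsum(c(0L, n_ev[-length(n_ev)])), path, "spikes/offsets")
  rhdf5::h5write(as.integer((batch$labels %||% rep(0L, length(n_ev))) - 1L),
                 path, "labels")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(batch$n_channels, fid, "n_channels")
  rhdf5::h5writeAttribute(batch$duration, fid, "duration")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read a spike dataset from the event-stream HDF5 layout
#'
#' Accepts both the offsets-based layout of [write_spike_dataset_h5()] and
#' ragged per-sample arrays (`spikes/times` and `spikes/units` stored as
#' lists), as used by public event datasets.
#'
#' @param path HDF5 file.
#' @param n_channels,duration overrides when the file carries no attributes.
#' @return a labeled [spike_batch()].
#' @export
read_spike_dataset_h5 <- function(path, n_channels = NULL, duration = NULL) {
  need_rhdf5()
  times <- rhdf5::h5read(path, "spikes/times")
  units <- rhdf5::h5read(path, "spikes/units")
  labels <- tryCatch(as.integer(rhdf5::h5read(path, "labels")) + 1L,
                     error = function(e) NULL)
  att <- tryCatch(rhdf5::h5readAttributes(path, "/"), error = function(e) list())
  n_channels <- n_channels %||% att$n_channels %||%
    (max(unlist(units)) + 1L)
  if (is.list(times)) {
    events <- Map(function(t, u)
      data.frame(time = as.numeric(t), channel = as.integer(u) + 1L),
      times, units)
  } else {
    off <- as.integer(rhdf5::h5read(path, "spikes/offsets"))
    bounds <- c(off, length(times))
    events <- lapply(seq_along(off), function(i) {
      idx <- if (bounds[i + 1] > bounds[i])
        (bounds[i] + 1):bounds[i + 1] else integer(0)
      data.frame(time = as.numeric(times[idx]),
                 channel = as.integer(units[idx]) + 1L)
    })
  }
  duration <- duration %||% att$duration %||%
    (max(unlist(lapply(events, `[[`, "time")), 0) + 1e-9)
  spike_batch(events, as.integer(n_channels), as.numeric(duration),
              labels = labels)
}

#' Write a training checkpoint to HDF5
#'
#' Stores the float master weights, the Adam moment estimates, the step and
#' epoch counters, and a hash of the resolved configuration so a checkpoint
#' can be matched to the run that produced it.
#'
#' @param state a [train_state()].
#' @param path output file.
#' @param config optional resolved config; its serialization hash is stored.
#' @export
write_checkpoint_h5 <- function(state, path, config = NULL) {
  need_rhdf5()
  stopifnot(inherits(state, "train_state"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  for (grp in c("weights", "adam_m", "adam_v")) rhdf5::h5createGroup(path, grp)
  src <- list(weights = unclass(state$weights)[c("w_in", "w_rec", "w_out")],
              adam_m = state$m, adam_v = state$v)
  for (grp in names(src))
    for (k in names(src[[grp]]))
      if (!is.null(src[[grp]][[k]]))
        rhdf5::h5write(src[[grp]][[k]], path, paste0(grp, "/", k))
  rhdf5::h5write(state$step, path, "step")
  rhdf5::h5write(state$epoch, path, "epoch")
  hash <- if (is.null(config)) "" else
    paste(utils::head(serialize(config, NULL, ascii = TRUE), 1e6), collapse = "")
  rhdf5::h5write(substr(digest_string(hash), 1, 16), path, "config_hash")
  invisible(path)
}

# tiny stable string hash (hex), no external dependency
digest_string <- function(s) {
  h <- c(17, 31, 47, 61)
  for (ch in utf8ToInt(s)) h <- (h * c(131, 137, 139, 149) + ch) %% 2^28
  paste(sprintf("%07x", h), collapse = "")
}

#' Read a training checkpoint from HDF5
#'
#' @param path file written by [write_checkpoint_h5()].
#' @return a [train_state()] with restored weights, moments and counters
#'   (optimizer hyperparameters take their defaults unless reset by the
#'   caller).
#' @export
read_checkpoint_h5 <- function(path) {
  need_rhdf5()
  get <- function(name) tryCatch(rhdf5::h5read(path, name),
                                 error = function(e) NULL)
  w <- network_weights(get("weights/w_in"), get("weights/w_out"),
                       get("weights/w_rec"))
  state <- train_state(w)
  for (k in names(state$m)) {
    m <- get(paste0("adam_m/", k)); v <- get(paste0("adam_v/", k))
    if (!is.null(m)) state$m[[k]] <- m
    if (!is.null(v)) state$v[[k]] <- v
  }
  state$step <- as.integer(get("step"))
  state$epoch <- as.integer(get("epoch"))
  state
}
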