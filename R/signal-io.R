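#' Construct a sampled signal
#'
#' A light container for a regularly sampled amplitude trace (e.g. a
#' rectified EMG channel), holding the sample vector, the sampling rate and
#' a channel label.
#'
#' @param samples Numeric vector of amplitudes, one per time bin. Must be
#'   finite throughout.
#' @param fs Sampling rate in Hz (`> 0`).
#' @param channel_id Character label for the channel.
#' @return An object of class `sdo_signal`: a list with elements `samples`,
#'   `fs` and `channel_id`.
#' @examples
#' sig <- sdo_signal(sin(seq(0, 2 * pi, length.out = 200)), fs = 100)
#' sig
#' @export
sdo_signal <- function(samples, fs, channel_id = "ch1") {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("signal samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         channel_id = as.character(channel_id)),
    class = "sdo_signal"
  )
}

#' @export
print.sdo_signal <- function(x, ...) {
  cat(sprintf(
    "<sdo_signal> channel '%s': %d samples @ %g Hz (%.3f s), range [%.4g, %.4g]\n",
    x$channel_id, length(x$samples), x$fs, length(x$samples) / x$fs,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
as.data.frame.sdo_signal <- function(x, ...) {
  data.frame(time_s = (seq_along(x$samples) - 1) / x$fs,
             amplitude = x$samples)
}

#' Construct a spike train
#'
#' Holds sorted event times for one spiking unit in one trial. Times are in
#' seconds from trial onset.
#'
#' @param times Numeric vector of event times in seconds; sorted internally.
#' @param unit_id,trial_id Labels for the unit and trial.
#' @return An object of class `spike_train` with elements `times`, `unit_id`,
#'   `trial_id` and spike count `k`.
#' @examples
#' spike_train(c(0.5, 0.1, 0.9))
#' @export
spike_train <- function(times, unit_id = "unit1", trial_id = "trial1") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("spike times must not contain NA", call. = FALSE)
  times <- sort(times)
  if (any(times < 0)) stop("spike times must be nonnegative", call. = FALSE)
  structure(
    list(times = times, unit_id = as.character(unit_id),
         trial_id = as.character(trial_id), k = length(times)),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit '%s', trial '%s': %d spikes",
              x$unit_id, x$trial_id, x$k))
  if (x$k > 0) cat(sprintf(" in [%.4g, %.4g] s", x$times[1], x$times[x$k]))
  cat("\n")
  invisible(x)
}

# spike times -> 1-based sample bins; the bin containing the timestamp
spike_bins <- function(spikes, fs) {
  times <- if (inherits(spikes, "spike_train")) spikes$times else as.numeric(spikes)
  as.integer(floor(times * fs)) + 1L
}

#' Read / write signals and spike trains as delimited text
#'
#' Signals are stored as two-column tab-separated text (`time_s`,
#' `amplitude`); spike trains as three-column text (`trial_id`, `unit_id`,
#' `time_s`). The sampling rate of a signal is recovered from the time
#' column.
#'
#' @param path File path.
#' @param x Object to write (`sdo_signal` or `spike_train`).
#' @return `read_signal_tsv()` returns an [sdo_signal()]; `read_spikes_tsv()`
#'   returns a list of [spike_train()] objects, one per (trial, unit) pair.
#'   The writers return `path` invisibly.
#' @name sdo_io
#' @export
read_signal_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    stop("signal file must have columns time_s, amplitude", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) stop("time_s must be increasing", call. = FALSE)
  sdo_signal(df$amplitude, fs = 1 / stats::median(dt),
             channel_id = sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname sdo_io
#' @export
write_signal_tsv <- function(x, path) {
  stopifnot(inherits(x, "sdo_signal"))
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname sdo_io
#' @export
read_spikes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("trial_id", "unit_id", "time_s") %in% names(df))) {
    stop("spike file must have columns trial_id, unit_id, time_s", call. = FALSE)
  }
  sp <- split(df, interaction(df$trial_id, df$unit_id, drop = TRUE))
  unname(lapply(sp, function(d) {
    spike_train(d$time_s, unit_id = d$unit_id[1], trial_id = d$trial_id[1])
  }))
}

#' @rdname sdo_io
#' @export
write_spikes_tsv <- function(x, path) {
  if (inherits(x, "spike_train")) x <- list(x)
  df <- do.call(rbind, lapply(x, function(tr) {
    data.frame(trial_id = tr$trial_id, unit_id = tr$unit_id, time_s = tr$times)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an SDO matrix to JSON
#'
#' Matrices are stored row-major with their state count, form tag, mean
#' pre-spike distribution and the spike count used in estimation, so a file
#' round-trips to an identical [sdo_matrix] object.
#'
#' @param x An `sdo_matrix` (or hypothesis matrix).
#' @param path Output path.
#' @return `write_sdo_json()` returns `path` invisibly; `read_sdo_json()`
#'   returns the reconstructed `sdo_matrix`.
#' @export
write_sdo_json <- function(x, path) {
  stopifnot(inherits(x, "sdo_matrix"))
  obj <- list(
    n_states = nrow(x$L),
    form = x$form,
    L = as.vector(t(x$L)),    # row-major
    p0_bar = x$p0_bar,
    n_spikes = x$n_spikes,
    h_id = x$h_id %||% NA_character_
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sdo_json
#' @export
read_sdo_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n_states
  L <- matrix(obj$L, nrow = n, byrow = TRUE)
  new_sdo_matrix(L, form = obj$form, n_spikes = obj$n_spikes,
                 p0_bar = obj$p0_bar,
                 h_id = if (is.null(obj$h_id) || is.na(obj$h_id)) NULL else obj$h_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
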