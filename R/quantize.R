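#' Preprocess a raw EMG signal
#'
#' Applies the standard EMG conditioning chain, all stages zero-phase:
#' (1) notch filters at the mains frequency and its harmonics, (2) a
#' high-pass Butterworth filter, and (3) a centered root-mean-square (RMS)
#' smoothing/rectification window. The output is nonnegative and the same
#' length as the input.
#'
#' Each notch is a second-order IIR biquad (quality factor `notch_q`)
#' applied forward-backward via [signal::filtfilt()], as is the high-pass
#' stage, so the chain introduces no phase delay.
#'
#' @param raw An [sdo_signal()].
#' @param notch_hz Mains frequency to notch out (Hz). Default 60.
#' @param notch_harmonics Number of harmonics of `notch_hz` to notch
#'   (default 8: 60, 120, ..., 480 Hz).
#' @param notch_q Notch quality factor (center frequency / bandwidth).
#' @param hp_hz High-pass corner frequency (Hz).
#' @param hp_order High-pass Butterworth order.
#' @param rms_points RMS window length in samples.
#' @return An [sdo_signal()] of smoothed, rectified amplitude.
#' @examples
#' fs <- 2000
#' raw <- sdo_signal(rnorm(fs), fs)
#' emg <- preprocess_emg(raw)
#' all(emg$samples >= 0)
#' @export
preprocess_emg <- function(raw, notch_hz = 60, notch_harmonics = 8,
                           notch_q = 30, hp_hz = 10, hp_order = 4,
                           rms_points = 20) {
  stopifnot(inherits(raw, "sdo_signal"))
  fs <- raw$fs
  top_harmonic <- notch_hz * notch_harmonics
  if (fs <= 2 * top_harmonic) {
    stop(sprintf("fs = %g Hz cannot notch %d harmonics of %g Hz (need fs > %g)",
                 fs, notch_harmonics, notch_hz, 2 * top_harmonic), call. = FALSE)
  }
  x <- raw$samples
  # filtfilt needs a margin of ~3x filter order on both ends
  if (length(x) < 12 * (hp_order + 2)) {
    stop("signal shorter than filter transient length", call. = FALSE)
  }

  # reflect-pad so the IIR filtfilt transients fall outside the signal
  pad <- min(length(x) - 1L, ceiling(6 * fs / hp_hz))
  xp <- c(rev(x[seq_len(pad) + 1L]), x,
          rev(x[length(x) - seq_len(pad)]))
  for (h in seq_len(notch_harmonics)) {
    co <- notch_coefficients(h * notch_hz, fs, notch_q)
    xp <- signal::filtfilt(co$b, co$a, xp)
  }
  hp <- signal::butter(hp_order, hp_hz / (fs / 2), type = "high")
  xp <- signal::filtfilt(hp, xp)
  x <- xp[pad + seq_along(x)]
  x <- rms_smooth(x, rms_points)
  sdo_signal(x, fs = fs, channel_id = raw$channel_id)
}

# biquad notch: unit gain at DC and Nyquist, null at f0; Q = f0 / bandwidth
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# centered moving RMS with truncated windows at the edges (keeps length)
rms_smooth <- function(x, n_points) {
  stopifnot(n_points >= 1)
  csum <- cumsum(c(0, x^2))
  nx <- length(x)
  half_lo <- floor((n_points - 1) / 2)
  half_hi <- n_points - 1 - half_lo
  lo <- pmax(seq_len(nx) - half_lo, 1L)
  hi <- pmin(seq_len(nx) + half_hi, nx)
  sqrt((csum[hi + 1L] - csum[lo]) / (hi - lo + 1L))
}

#' Build an amplitude quantizer
#'
#' Defines `n_states` amplitude bins spanning the observed range of
#' `samples`. The `"linear"` scheme uses equal-width bins between the
#' minimum and maximum; the `"log"` scheme uses bins of equal width in the
#' log-amplitude domain, which allocates states more evenly when amplitudes
#' are roughly exponentially distributed (typical of rectified EMG).
#'
#' For the log scheme, if nonpositive samples are present a floor offset of
#' half the smallest positive sample is added before taking logs (the bin
#' edges are mapped back to the original amplitude scale).
#'
#' @param samples Numeric amplitude vector (or an [sdo_signal()]).
#' @param n_states Number of states (>= 2). Default 20.
#' @param scheme `"linear"` or `"log"`.
#' @return An object of class `sdo_quantizer`: list with `edges`
#'   (length `n_states + 1`, strictly increasing), `scheme`, `n_states`.
#' @examples
#' q <- build_quantizer(runif(1000, 0, 10), n_states = 20)
#' diff(q$edges)[1]  # 0.5
#' @export
build_quantizer <- function(samples, n_states = 20,
                            scheme = c("linear", "log")) {
  if (inherits(samples, "sdo_signal")) samples <- samples$samples
  scheme <- match.arg(scheme)
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("samples must not contain NA", call. = FALSE)
  if (n_states < 2) stop("n_states must be >= 2", call. = FALSE)
  lo <- min(samples); hi <- max(samples)
  if (!(hi > lo)) stop("degenerate amplitude range (constant signal)", call. = FALSE)
  if (scheme == "linear") {
    edges <- seq(lo, hi, length.out = n_states + 1)
  } else {
    offset <- 0
    if (lo <= 0) {
      pos <- samples[samples > 0]
      if (length(pos) == 0L) {
        stop("log scheme requires positive values (or a floor offset)", call. = FALSE)
      }
      offset <- min(pos) * 0.5 - lo
    }
    log_edges <- seq(log(lo + offset), log(hi + offset),
                     length.out = n_states + 1)
    edges <- exp(log_edges) - offset
    edges[1] <- lo; edges[n_states + 1] <- hi  # guard fp drift at the span ends
  }
  structure(list(edges = edges, scheme = scheme, n_states = as.integer(n_states)),
            class = "sdo_quantizer")
}

#' @export
print.sdo_quantizer <- function(x, ...) {
  cat(sprintf("<sdo_quantizer> %d %s states on [%.4g, %.4g]\n",
              x$n_states, x$scheme, x$edges[1], x$edges[x$n_states + 1]))
  invisible(x)
}

#' Quantize a signal into discrete states
#'
#' Maps each amplitude sample to a state label in `1..n_states` using the
#' half-open bin convention `[edge_i, edge_{i+1})` with the top bin closed,
#' so the exact maximum maps to state `n_states` and values exactly on an
#' interior edge go to the higher bin. Values outside the quantizer's span
#' (possible when quantizing new data with a previously built quantizer)
#' are clamped to the end states with a warning.
#'
#' @param signal An [sdo_signal()] or numeric vector.
#' @param quantizer An [build_quantizer()] result.
#' @param fs Sampling rate, required when `signal` is a bare vector.
#' @return An object of class `state_series`: list with integer `states`,
#'   `fs` and `n_states`.
#' @examples
#' q <- build_quantizer(0:10, n_states = 5)
#' quantize(sdo_signal(c(0, 5, 10), fs = 1), q)$states
#' @export
quantize <- function(signal, quantizer, fs = NULL) {
  stopifnot(inherits(quantizer, "sdo_quantizer"))
  if (inherits(signal, "sdo_signal")) {
    x <- signal$samples
    fs <- signal$fs
  } else {
    x <- as.numeric(signal)
    if (is.null(fs)) stop("`fs` required when quantizing a bare vector", call. = FALSE)
  }
  if (anyNA(x)) stop("cannot quantize NA samples", call. = FALSE)
  edges <- quantizer$edges
  n <- quantizer$n_states
  n_out <- sum(x < edges[1] | x > edges[n + 1])
  if (n_out > 0) {
    warning(sprintf("%d samples outside quantizer range; clamped to end states",
                    n_out), call. = FALSE)
  }
  st <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  state_series(st, fs = fs, n_states = n)
}

#' Construct a state series
#'
#' @param states Integer state labels in `1..n_states`.
#' @param fs Sampling rate in Hz.
#' @param n_states Total number of states.
#' @return An object of class `state_series`.
#' @export
state_series <- function(states, fs, n_states) {
  states <- as.integer(states)
  if (anyNA(states) || any(states < 1L) || any(states > n_states)) {
    stop("states must lie in 1..n_states", call. = FALSE)
  }
  structure(list(states = states, fs = as.numeric(fs),
                 n_states = as.integer(n_states)),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  occ <- tabulate(x$states, x$n_states) / length(x$states)
  cat(sprintf("<state_series> %d bins @ %g Hz, %d states (occupancy entropy %.3f nats)\n",
              length(x$states), x$fs, x$n_states,
              -sum(occ[occ > 0] * log(occ[occ > 0]))))
  invisible(x)
}

#' Midpoints of quantizer bins, used e.g. to map states back to amplitudes
#' @param quantizer An `sdo_quantizer`.
#' @return Numeric vector of `n_states` bin midpoints.
#' @export
quantizer_midpoints <- function(quantizer) {
  e <- quantizer$edges
  (e[-1] + e[-length(e)]) / 2
}
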