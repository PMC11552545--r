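#' Classical spike-triggered average
#'
#' Averages perievent signal segments over spikes. The pre window covers
#' `pre_ms` before the spike bin; the post window starts at the spike bin
#' (lag 0 belongs to the post window). Spikes whose segments would cross
#' the trial boundary are dropped.
#'
#' @param signal An [sdo_signal()].
#' @param spikes A [spike_train()] or integer spike bins.
#' @param pre_ms,post_ms Window durations in milliseconds.
#' @return A list of class `sta_result` with `waveform` (mean amplitude
#'   per perievent bin), `lags_ms`, `k` (spikes used), `n_dropped`.
#' @export
compute_sta <- function(signal, spikes, pre_ms = 20, post_ms = 20) {
  seg <- perievent_segments(signal, spikes, pre_ms, post_ms)
  structure(
    list(waveform = colMeans(seg$segments), lags_ms = seg$lags_ms,
         k = nrow(seg$segments), n_dropped = seg$n_dropped),
    class = "sta_result"
  )
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("<sta_result> %d lags over [%g, %g] ms, %d spikes\n",
              length(x$waveform), min(x$lags_ms), max(x$lags_ms), x$k))
  invisible(x)
}

# k x m matrix of perievent segments; offsets -npre..(npost-1) around spike bin
perievent_segments <- function(signal, spikes, pre_ms, post_ms) {
  stopifnot(inherits(signal, "sdo_signal"))
  fs <- signal$fs
  x <- signal$samples
  bins <- if (is.numeric(spikes) && !inherits(spikes, "spike_train")) {
    as.integer(spikes)
  } else {
    spike_bins(spikes, fs)
  }
  npre <- round(pre_ms / 1000 * fs)
  npost <- round(post_ms / 1000 * fs)
  offsets <- seq.int(-npre, npost - 1L)
  keep <- bins + offsets[1] >= 1L & bins + offsets[length(offsets)] <= length(x)
  n_dropped <- sum(!keep)
  bins <- bins[keep]
  if (length(bins) == 0L) stop("no spikes with complete segments", call. = FALSE)
  idx <- outer(bins, offsets, `+`)
  list(segments = matrix(x[idx], nrow = length(bins)),
       lags_ms = offsets / fs * 1000, n_dropped = n_dropped, bins = bins)
}

not_analyzed <- function(test) {
  tibble::tibble(test = test, p_value = NA_real_, significant = NA,
                 analyzed = FALSE)
}

#' STA significance: paired t-test of pre/post window mean amplitudes
#'
#' For each spike, the mean signal *amplitude* (rectified, `|x|`) over the
#' `window_ms` pre-spike window and the `window_ms` post-spike window are
#' compared with a paired two-sided t-test. Rectification makes the test
#' sensitive to spike-triggered changes in signal power as well as level
#' (for nonnegative signals such as processed EMG it is a no-op), and is
#' what separates this amplitude test from the waveform-based ISA and
#' bootstrap-deviation tests. Spike trains with fewer than `min_spikes`
#' usable spikes are flagged not-analyzed.
#'
#' @inheritParams compute_sta
#' @param window_ms Window length (ms) on each side.
#' @param alpha Significance level.
#' @param min_spikes Minimum usable spikes.
#' @return A one-row tibble: `test`, `p_value`, `significant`, `analyzed`.
#' @export
sta_simple_t <- function(signal, spikes, window_ms = 20, alpha = 0.05,
                         min_spikes = 500) {
  seg <- perievent_segments(signal, spikes, window_ms, window_ms)
  k <- nrow(seg$segments)
  if (k < min_spikes) return(not_analyzed("simple_t"))
  npre <- sum(seg$lags_ms < 0)
  amp <- abs(seg$segments)
  pre_mean <- rowMeans(amp[, seq_len(npre), drop = FALSE])
  post_mean <- rowMeans(amp[, -seq_len(npre), drop = FALSE])
  d <- post_mean - pre_mean
  p <- if (all(d == 0)) 1 else t.test(d)$p.value
  tibble::tibble(test = "simple_t", p_value = p,
                 significant = p < alpha, analyzed = TRUE)
}

#' STA significance: increment-shifted average (ISA) detrended test
#'
#' For every spike a segment spanning 40 ms before to 100 ms after the
#' spike is extracted. The ISA is the average of the time-shifted 60 ms
#' subsamples taken at every sample step with centers covering
#' `[-20, +40]` ms around the spike; it estimates the local (slow) trend.
#' The ISA is subtracted from the spike-triggered segment over
#' `[-20, +40]` ms, the mean of the two baseline windows
#' (`[-20, 0]` and `[20, 40]` ms) is subtracted from the mean of the test
#' window (`[0, 20]` ms), and the resulting per-spike effects are tested
#' against zero with a two-sided t-test.
#'
#' @inheritParams sta_simple_t
#' @return A one-row tibble: `test`, `p_value`, `significant`, `analyzed`.
#' @export
sta_isa <- function(signal, spikes, alpha = 0.05, min_spikes = 500) {
  eff <- tryCatch(isa_per_spike_effects(signal, spikes),
                  error = function(e) NULL)
  if (is.null(eff) || length(eff) < min_spikes) {
    return(not_analyzed("isa"))
  }
  p <- if (all(eff == 0)) 1 else t.test(eff)$p.value
  tibble::tibble(test = "isa", p_value = p,
                 significant = p < alpha, analyzed = TRUE)
}

# per-spike ISA-detrended effects: mean of the [0, 20] ms test window minus
# the mean of the [-20, 0] / [20, 40] ms baselines, after subtracting the
# increment-shifted average (the elementwise mean of the time-shifted 60 ms
# subsamples, equivalently a 60 ms moving average of the perievent segment)
isa_per_spike_effects <- function(signal, spikes) {
  fs <- signal$fs
  ms <- function(t_ms) round(t_ms / 1000 * fs)
  # window centers t in [-20, +40] ms, each subsample [t - 20, t + 40] ms
  # -> segment offsets [-40, +80] ms inclusive
  off_lo <- ms(-40); off_hi <- ms(80)
  seg <- perievent_segments_offsets(signal, spikes, off_lo, off_hi)
  S <- seg$segments                      # k x (off_hi - off_lo + 1)
  wlen <- ms(60) + 1L                    # 60 ms subsample, inclusive ends
  cs <- cbind(0, t(apply(S, 1, cumsum)))
  n_isa <- ncol(S) - wlen + 1L           # number of shifted subsamples
  isa <- (cs[, (wlen + 1):(ncol(S) + 1)] - cs[, 1:n_isa]) / wlen
  win_cols <- (ms(-20) - off_lo + 1L):(ms(40) - off_lo + 1L)
  D <- S[, win_cols, drop = FALSE] - isa  # detrended [-20, +40] ms window
  rel <- seq.int(ms(-20), ms(40))        # offsets of D's columns
  test_cols <- which(rel >= 0 & rel <= ms(20))
  base_cols <- which(rel < 0 | rel > ms(20))
  rowMeans(D[, test_cols, drop = FALSE]) -
    rowMeans(D[, base_cols, drop = FALSE])
}

perievent_segments_offsets <- function(signal, spikes, off_lo, off_hi) {
  fs <- signal$fs
  x <- signal$samples
  bins <- if (is.numeric(spikes) && !inherits(spikes, "spike_train")) {
    as.integer(spikes)
  } else {
    spike_bins(spikes, fs)
  }
  offsets <- seq.int(off_lo, off_hi)
  keep <- bins + off_lo >= 1L & bins + off_hi <= length(x)
  bins <- bins[keep]
  if (length(bins) == 0L) stop("no spikes with complete segments", call. = FALSE)
  idx <- outer(bins, offsets, `+`)
  list(segments = matrix(x[idx], nrow = length(bins)),
       n_dropped = sum(!keep))
}

#' STA significance: bootstrap standard-deviation threshold test
#'
#' The per-lag standard deviation of the STA over `[-20, +20]` ms is
#' estimated from the average waveforms of `n_boot` bootstrap resamples of
#' the spike set. The STA is reduced to 1 ms lag points, mean-leveled and
#' rectified; the relationship is significant if any point exceeds its
#' bootstrap SD times the Bonferroni-corrected inverse-t threshold for the
#' number of points tested.
#'
#' @inheritParams sta_simple_t
#' @param n_boot Number of bootstrap resamples.
#' @return A one-row tibble: `test`, `p_value` (`NA`, threshold test),
#'   `significant`, `analyzed`.
#' @export
sta_bootstrap_sd <- function(signal, spikes, n_boot = 20, alpha = 0.05,
                             min_spikes = 500) {
  seg <- perievent_segments(signal, spikes, 20, 20)
  k <- nrow(seg$segments)
  if (k < min_spikes) return(not_analyzed("bootstrap_sd"))
  per_ms <- max(1L, round(signal$fs / 1000))
  decimate_1ms <- function(v) {
    colMeans(matrix(v, nrow = per_ms))
  }
  sta_dec <- decimate_1ms(colMeans(seg$segments))
  n_points <- length(sta_dec)
  boot_stas <- vapply(seq_len(n_boot), function(b) {
    decimate_1ms(colMeans(seg$segments[sample.int(k, k, replace = TRUE), ,
                                       drop = FALSE]))
  }, numeric(n_points))
  sd_point <- apply(boot_stas, 1, sd)
  # df from the bootstrap SD estimate (n_boot resamples), not the spike count
  thr <- qt(1 - alpha / n_points, df = n_boot - 1)
  dev <- abs(sta_dec - mean(sta_dec))
  sig <- any(dev > thr * sd_point & sd_point > 0)
  tibble::tibble(test = "bootstrap_sd", p_value = NA_real_,
                 significant = sig, analyzed = TRUE)
}

#' Combine STA test decisions
#'
#' The classical battery flags a spike-signal relationship if any
#' individual test is significant. If no test could be analyzed the
#' combined decision is `NA`.
#'
#' @param results Tibble of per-test rows (as from [sta_battery()]).
#' @return Logical scalar (or `NA` if nothing was analyzed).
#' @export
sta_any_significant <- function(results) {
  an <- results$analyzed & !is.na(results$significant)
  if (!any(an)) return(NA)
  any(results$significant[an])
}

#' Run the full classical STA battery
#'
#' Applies the paired t-test, ISA-detrended test and bootstrap-SD test and
#' appends a `combined` row (OR over the three).
#'
#' @inheritParams sta_simple_t
#' @param n_boot Bootstrap resamples for the deviation test.
#' @return A tibble with rows `simple_t`, `isa`, `bootstrap_sd`,
#'   `combined`.
#' @export
sta_battery <- function(signal, spikes, alpha = 0.05, min_spikes = 500,
                        n_boot = 20) {
  res <- dplyr::bind_rows(
    sta_simple_t(signal, spikes, alpha = alpha, min_spikes = min_spikes),
    sta_isa(signal, spikes, alpha = alpha, min_spikes = min_spikes),
    sta_bootstrap_sd(signal, spikes, n_boot = n_boot, alpha = alpha,
                     min_spikes = min_spikes)
  )
  dplyr::bind_rows(
    res,
    tibble::tibble(test = "combined", p_value = NA_real_,
                   significant = sta_any_significant(res),
                   analyzed = any(res$analyzed))
  )
}
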