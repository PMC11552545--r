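#' Specify a stochastic test-signal generator
#'
#' Eight generator families produce stochastic time series with known
#' ground truth about whether spikes influence the signal:
#'
#' * **Y1** low-pass filtered white noise (no spike effect);
#' * **Y2** Y1 plus higher-amplitude white noise injected for the effect
#'   window after each spike (random spike effect);
#' * **Y3** Y1 plus a consistent impulse response after each spike;
#' * **Y4** stabilizing first-order dynamics toward a fixed point, driven
#'   by the increments of a Y1 process (no spike effect);
#' * **Y5** random walk of a left-stochastic Markov matrix (identity
#'   convolved with a Gaussian kernel), mean-leveled (no spike effect);
#' * **Y6** Y4 dynamics plus the Y3 impulse responses;
#' * **Y7** Y4 dynamics with a second stabilizing equation toward a
#'   positive set point active during the effect window after each spike
#'   (spike-triggered dynamics);
#' * **Y8** stationary ARMA(3,2) process, mean-leveled (no spike effect).
#'
#' Spike effects (Y2, Y3, Y6, Y7) act only in the `effect_window_s` after
#' each spike. Effect amplitudes are expressed in units of the background
#' (Y1) standard deviation.
#'
#' @param gen_id One of `"Y1"`..`"Y8"`.
#' @param fs Sampling rate (Hz).
#' @param duration Signal duration (s).
#' @param noise_scale SD of the white noise driving Y1-family signals.
#' @param lp_cutoff Low-pass corner for the white-noise family (Hz).
#' @param effect_window_s Duration of the post-spike effect window (s).
#' @param spike_noise_scale Y2 injected-noise SD, in background SDs.
#' @param impulse_peak Y3/Y6 half-sine impulse peak, in background SDs.
#' @param k_stab Stabilizing coefficient for Y4/Y6/Y7 (`0 < k < 1`).
#' @param x0_bg Background fixed point for Y4/Y6/Y7.
#' @param k_spike,x0_spike Y7 spike-triggered stabilizing coefficient and
#'   set point (set point in background SDs, must be positive).
#' @param markov_n,markov_sigma Y5 state count and Gaussian kernel width.
#' @param ar,ma Y8 ARMA coefficients (checked stationary/invertible).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(gen_id, fs = 2000, duration = 60,
                           noise_scale = 1, lp_cutoff = 100,
                           effect_window_s = 0.010,
                           spike_noise_scale = 3, impulse_peak = 3,
                           k_stab = 0.05, x0_bg = 0,
                           k_spike = 0.042, x0_spike = 0.12,
                           markov_n = 100, markov_sigma = 2,
                           ar = c(0.5, -0.3, 0.1), ma = c(0.4, 0.2)) {
  gen_id <- match.arg(gen_id, paste0("Y", 1:8))
  stopifnot(fs > 0, duration > 0, noise_scale >= 0,
            k_stab > 0, k_stab < 1, x0_spike > 0)
  # stationarity / invertibility of the ARMA branch
  if (gen_id == "Y8") {
    if (any(Mod(polyroot(c(1, -ar))) <= 1) || any(Mod(polyroot(c(1, ma))) <= 1)) {
      stop("ARMA coefficients are not stationary/invertible", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> %s: %g s @ %g Hz\n", x$gen_id, x$duration, x$fs))
  invisible(x)
}

#' Draw a random spike train for a simulation
#'
#' Spike bins are drawn uniformly at random over the trial with an
#' enforced minimum gap (default: the post-effect window), so consecutive
#' effect windows never overlap. The same train is shared across all
#' generators within one simulation.
#'
#' @param n_spikes Number of spikes.
#' @param duration Trial duration (s).
#' @param fs Sampling rate (Hz).
#' @param min_gap Minimum inter-spike gap (s).
#' @param margin Dead zone at each trial end (s) so every spike supports
#'   the full perievent segments of all analysis methods.
#' @return A [spike_train()].
#' @export
gen_spike_train <- function(n_spikes, duration = 60, fs = 2000,
                            min_gap = 0.010, margin = 0.1) {
  total <- floor((duration - 2 * margin) * fs)
  offset <- floor(margin * fs)
  gap <- ceiling(min_gap * fs)
  if (n_spikes == 0L) return(spike_train(numeric(0)))
  slack <- total - (n_spikes - 1) * gap
  if (slack < n_spikes) stop("infeasible spike density for min_gap", call. = FALSE)
  base <- sort(sample.int(slack, n_spikes))
  bins <- offset + base + (seq_len(n_spikes) - 1L) * gap
  spike_train((bins - 0.5) / fs)
}

#' Simulate a stochastic realization
#'
#' Generates one time series from a [generator_spec()], applying spike
#' effects (for Y2/Y3/Y6/Y7) at the provided spike train.
#'
#' @param spec A [generator_spec()].
#' @param spikes A [spike_train()] shared across generators of one
#'   simulation.
#' @return A list of class `sim_realization` with `signal`
#'   ([sdo_signal()]), `spikes`, `gen_id` and `has_effect` (ground truth).
#' @export
simulate_generator <- function(spec, spikes) {
  stopifnot(inherits(spec, "generator_spec"), inherits(spikes, "spike_train"))
  nT <- floor(spec$duration * spec$fs)
  bins <- spike_bins(spikes, spec$fs)
  w <- round(spec$effect_window_s * spec$fs)

  y1 <- lp_white_noise(nT, spec$fs, spec$noise_scale, spec$lp_cutoff)
  bg_sd <- stats::sd(y1)

  y <- switch(spec$gen_id,
    Y1 = y1,
    Y2 = add_window_noise(y1, bins, w, spec$spike_noise_scale * bg_sd),
    Y3 = add_impulse(y1, bins, w, spec$impulse_peak * bg_sd),
    Y4 = stabilized_series(y1, spec$k_stab, spec$x0_bg),
    Y5 = markov_walk(nT, spec$markov_n, spec$markov_sigma),
    Y6 = add_impulse(stabilized_series(y1, spec$k_stab, spec$x0_bg),
                     bins, w, spec$impulse_peak * bg_sd),
    Y7 = spike_stabilized_series(y1, bins, w, spec$k_stab, spec$x0_bg,
                                 spec$k_spike, spec$x0_spike * bg_sd),
    Y8 = arma_series(nT, spec$ar, spec$ma, spec$noise_scale)
  )
  structure(
    list(signal = sdo_signal(y, fs = spec$fs, channel_id = spec$gen_id),
         spikes = spikes, gen_id = spec$gen_id,
         has_effect = spec$gen_id %in% c("Y2", "Y3", "Y6", "Y7")),
    class = "sim_realization"
  )
}

lp_white_noise <- function(nT, fs, sd_noise, cutoff) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, rnorm(nT, sd = sd_noise))
}

# indices of the post-spike effect window (s, s + w], clipped to the trial
effect_indices <- function(bins, w, nT) {
  idx <- rep(bins, each = w) + rep(seq_len(w), times = length(bins))
  list(idx = idx[idx <= nT], per_spike = w)
}

add_window_noise <- function(y, bins, w, sd_noise) {
  ei <- effect_indices(bins, w, length(y))
  y[ei$idx] <- y[ei$idx] + rnorm(length(ei$idx), sd = sd_noise)
  y
}

add_impulse <- function(y, bins, w, peak) {
  shape <- peak * sin(pi * seq_len(w) / (w + 1))  # half-sine, 0 at both ends
  ei <- effect_indices(bins, w, length(y))
  y[ei$idx] <- y[ei$idx] + rep_len(shape, length(ei$idx))
  y
}

# y[1] = y1[1]; y[t] = (1 - k) y[t-1] + k x0 + dY1[t]: AR(1), vectorized
stabilized_series <- function(y1, k, x0) {
  drive <- k * x0 + diff(y1)
  out <- stats::filter(drive, filter = 1 - k, method = "recursive",
                       init = y1[1])
  c(y1[1], as.numeric(out))
}

# Y7: background stabilization always on; a second controller toward
# x0_spike switches on inside each post-spike effect window
spike_stabilized_series <- function(y1, bins, w, k, x0, k2, x0s) {
  nT <- length(y1)
  dy1 <- c(0, diff(y1))
  active <- logical(nT)
  ei <- effect_indices(bins, w, nT)
  active[ei$idx] <- TRUE
  y <- numeric(nT)
  y[1] <- y1[1]
  for (t in 2:nT) {
    dy <- k * (x0 - y[t - 1]) + dy1[t]
    if (active[t]) dy <- dy + k2 * (x0s - y[t - 1])
    y[t] <- y[t - 1] + dy
  }
  y
}

#' Left-stochastic Gaussian-kernel transition matrix
#'
#' The identity convolved column-wise with a Gaussian kernel of width
#' `sigma` states; each column is renormalized to sum to 1 after edge
#' truncation. Used as the Y5 random-walk kernel.
#'
#' @param n Number of states.
#' @param sigma Kernel width in states.
#' @return An `n x n` column-stochastic matrix.
#' @export
markov_kernel_matrix <- function(n, sigma) {
  gaussian_band_matrix(n, sigma)
}

markov_walk <- function(nT, n, sigma) {
  P <- markov_kernel_matrix(n, sigma)
  cum <- apply(P, 2, cumsum)
  u <- runif(nT)
  s <- integer(nT)
  s[1] <- ceiling(n / 2)
  for (t in 2:nT) {
    s[t] <- findInterval(u[t], cum[, s[t - 1]]) + 1L
  }
  as.numeric(s - mean(s))
}

arma_series <- function(nT, ar, ma, sd_noise) {
  y <- stats::arima.sim(model = list(ar = ar, ma = ma), n = nT,
                        sd = sd_noise)
  as.numeric(y - mean(y))
}

#' Run the simulation validation study
#'
#' For each simulation, draws one spike train shared by all requested
#' generators, simulates each generator, quantizes the signal to
#' `n_states` linear states over its observed range, and applies the SDO
#' significance battery and/or the classical STA battery. Ground truth:
#' spike effects are present exactly for Y2, Y3, Y6 and Y7.
#'
#' @param n_sims Simulations per generator.
#' @param generators Character vector of generator ids (default Y1-Y8).
#' @param n_spikes Spikes per simulation.
#' @param n_shuffles Surrogate spike trains per SDO battery.
#' @param n_states Number of signal states.
#' @param pre_bins,post_bins SDO window lengths (bins).
#' @param alpha Significance level before Bonferroni correction.
#' @param spec_overrides Named list of [generator_spec()] arguments applied
#'   to every generator (e.g. `list(duration = 30)`).
#' @param run_sdo,run_sta Which batteries to run.
#' @return A tibble with one row per (sim, generator, test):
#'   columns `sim`, `gen_id`, `basis` (`"STA"`/`"SDO"`), `test`,
#'   `p_value`, `significant`, `truth`, `correct`.
#' @export
run_validation_study <- function(n_sims = 25,
                                 generators = paste0("Y", 1:8),
                                 n_spikes = 500, n_shuffles = 1000,
                                 n_states = 20, pre_bins = 20,
                                 post_bins = 20, alpha = 0.05,
                                 spec_overrides = list(),
                                 run_sdo = TRUE, run_sta = TRUE) {
  specs <- lapply(generators, function(g) {
    do.call(generator_spec, c(list(gen_id = g), spec_overrides))
  })
  names(specs) <- generators
  fs <- specs[[1]]$fs
  duration <- specs[[1]]$duration

  rows <- vector("list", n_sims * length(generators))
  ri <- 0L
  for (i in seq_len(n_sims)) {
    spikes <- gen_spike_train(n_spikes, duration, fs,
                              min_gap = specs[[1]]$effect_window_s)
    for (g in generators) {
      real <- simulate_generator(specs[[g]], spikes)
      q <- build_quantizer(real$signal, n_states = n_states)
      ss <- quantize(real$signal, q)
      res <- list()
      if (run_sdo) {
        sig <- sdo_significance(ss, spikes, pre_bins, post_bins,
                                n_shuffles = n_shuffles, alpha = alpha)
        sdo_tbl <- sig$results[, c("statistic", "p_value", "significant")]
        names(sdo_tbl)[1] <- "test"
        sdo_tbl$basis <- "SDO"
        combined <- tibble::tibble(
          test = "combined", p_value = NA_real_,
          significant = sig$effect_significant, basis = "SDO")
        res <- c(res, list(sdo_tbl, combined))
      }
      if (run_sta) {
        sta_tbl <- sta_battery(real$signal, spikes, alpha = alpha)
        sta_tbl$basis <- "STA"
        res <- c(res, list(sta_tbl))
      }
      out <- dplyr::bind_rows(res)
      out$sim <- i
      out$gen_id <- g
      out$truth <- real$has_effect
      ri <- ri + 1L
      rows[[ri]] <- out
    }
  }
  res <- dplyr::bind_rows(rows[seq_len(ri)])
  res$correct <- res$significant == res$truth
  dplyr::select(res, sim, gen_id, basis, test, p_value, significant,
                truth, correct)
}
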