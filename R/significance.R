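#' Interspike-interval shuffle surrogates
#'
#' Builds surrogate spike trains by permuting the observed interspike
#' intervals, anchored at the first spike, on a trial-wise basis. Each
#' surrogate has exactly the original spike count, the original ISI
#' multiset, and the original first/last-spike span.
#'
#' @param train A [spike_train()] with at least 2 spikes.
#' @param n Number of surrogates.
#' @return A list of class `shuffle_set`: `trains` (list of
#'   [spike_train()]), `method`, `n_shuffles`.
#' @export
shuffle_isi <- function(train, n) {
  stopifnot(inherits(train, "spike_train"))
  if (train$k < 2) stop("ISI shuffling needs at least 2 spikes", call. = FALSE)
  isi <- diff(train$times)
  t1 <- train$times[1]
  trains <- lapply(seq_len(n), function(i) {
    spike_train(c(t1, t1 + cumsum(sample(isi))),
                unit_id = train$unit_id, trial_id = train$trial_id)
  })
  structure(list(trains = trains, method = "isi_shuffle", n_shuffles = n),
            class = "shuffle_set")
}

# integer-bin version used by the battery (exactly preserves sample bins)
shuffle_isi_bins <- function(bins, n) {
  k <- length(bins)
  isi <- diff(bins)
  out <- matrix(0L, nrow = k, ncol = n)
  for (i in seq_len(n)) {
    out[, i] <- c(bins[1], bins[1] + cumsum(sample(isi)))
  }
  out
}

#' Rate-process resampling surrogates
#'
#' Estimates the rate process underlying the observed train by Gaussian
#' kernel smoothing of the spike times, then resamples surrogate trains as
#' inhomogeneous Poisson realizations of that rate (spike counts Poisson
#' about the observed count; times drawn from the normalized rate).
#'
#' @param train A [spike_train()].
#' @param duration Trial duration (s).
#' @param kernel_sd Gaussian kernel width (s).
#' @param n Number of surrogates.
#' @param grid_dt Rate-grid resolution (s).
#' @return A `shuffle_set` (see [shuffle_isi()]).
#' @export
resample_rate_process <- function(train, duration, kernel_sd = 0.05, n,
                                  grid_dt = 0.001) {
  stopifnot(inherits(train, "spike_train"), duration > 0)
  if (train$k == 0) stop("zero total rate: empty spike train", call. = FALSE)
  grid <- seq(grid_dt / 2, duration, by = grid_dt)
  lambda <- rowSums(vapply(train$times, function(s) {
    stats::dnorm(grid, mean = s, sd = kernel_sd)
  }, numeric(length(grid))))
  if (sum(lambda) <= 0) stop("zero total rate", call. = FALSE)
  prob <- lambda / sum(lambda)
  trains <- lapply(seq_len(n), function(i) {
    k_i <- stats::rpois(1, train$k)
    ts <- sample(grid, k_i, replace = TRUE, prob = prob) +
      runif(k_i, -grid_dt / 2, grid_dt / 2)
    spike_train(pmin(pmax(ts, 0), duration), unit_id = train$unit_id,
                trial_id = train$trial_id)
  })
  structure(list(trains = trains, method = "rate_resample", n_shuffles = n),
            class = "shuffle_set")
}

#' SDO significance battery against shuffled-spike surrogates
#'
#' Estimates the spike-triggered SDO and compares it with a Monte-Carlo
#' null ensemble of SDOs from surrogate spike trains sharing the signal.
#' All operators are first normalized to conditional form and rescaled by
#' the observed spike-triggered pre-spike distribution so that
#' similarity statistics are computed on a common footing.
#'
#' Six statistics are computed:
#' * `element_sse` — per-element standardized squared error against the
#'   shuffle distribution of that element, summed over elements;
#' * `matrix_sse` — cumulative squared difference from the mean shuffled
#'   operator;
#' * `joint_sse` — the same, on the rescaled joint pre/post distributions;
#' * `statewise_bias` — per input state, above- minus below-diagonal mass
#'   (directional shift conditional on state); the reported p-value is the
#'   per-state minimum;
#' * `total_bias` — above- minus below-diagonal mass over the whole matrix;
#' * `state_tuning_kld` — Kullback-Leibler divergence of the observed
#'   state-at-spike distribution from the shuffle average (a tuning, not
#'   an effect, statistic).
#'
#' Each observed statistic is compared with the mean and internal variance
#' of its null distribution by a one-sided z test (on the magnitude for
#' the signed bias statistics); decisions use `alpha / n_corrections`
#' (Bonferroni correction for the number of states).
#'
#' @param states A [state_series()].
#' @param spikes A [spike_train()] or integer spike bins.
#' @param pre_bins,post_bins Window lengths in bins.
#' @param n_shuffles Number of surrogate trains (>= 2).
#' @param shuffle_method `"isi"` (ISI permutation) or `"rate"` (renewal
#'   resampling).
#' @param alpha Significance level.
#' @param n_corrections Bonferroni divisor; defaults to the state count.
#' @param kernel_sd Rate-smoothing kernel width (s), `"rate"` method only.
#' @param effect_tests Statistics that count as tests of spike *effect*
#'   for the combined decision (tuning is reported separately).
#' @return An object of class `sdo_significance`: list with `results`
#'   (tibble: statistic, observed, null_mean, null_sd, z, p_value,
#'   significant), `effect_significant`, `tuning_significant`,
#'   `statewise` (per-state bias table), `sdo` (the raw spike-triggered
#'   SDO), and the call parameters.
#' @export
sdo_significance <- function(states, spikes, pre_bins = 20, post_bins = 20,
                             n_shuffles = 1000,
                             shuffle_method = c("isi", "rate"),
                             alpha = 0.05, n_corrections = NULL,
                             kernel_sd = 0.05,
                             effect_tests = c("element_sse", "matrix_sse",
                                              "joint_sse", "total_bias")) {
  stopifnot(inherits(states, "state_series"))
  shuffle_method <- match.arg(shuffle_method)
  if (n_shuffles < 2) stop("need at least 2 shuffles", call. = FALSE)
  n <- states$n_states
  n_corrections <- n_corrections %||% n
  st <- states$states
  T_len <- length(st)

  bins <- if (is.numeric(spikes) && !inherits(spikes, "spike_train")) {
    as.integer(spikes)
  } else {
    spike_bins(spikes, states$fs)
  }
  bins <- bins[bins - pre_bins + 1L >= 1L & bins + post_bins <= T_len]
  if (length(bins) < 2) stop("need at least 2 in-bounds spikes", call. = FALSE)

  if (shuffle_method == "isi") {
    null_bins <- shuffle_isi_bins(bins, n_shuffles)
  } else {
    duration <- T_len / states$fs
    tr <- spike_train((bins - 0.5) / states$fs)
    ss <- resample_rate_process(tr, duration, kernel_sd, n_shuffles)
    kmax <- max(vapply(ss$trains, function(x) x$k, integer(1)))
    null_bins <- matrix(NA_integer_, kmax, n_shuffles)
    for (i in seq_len(n_shuffles)) {
      b <- spike_bins(ss$trains[[i]], states$fs)
      if (length(b)) null_bins[seq_along(b), i] <- b
    }
  }

  nmax <- max(length(bins), nrow(null_bins))  # rate surrogates vary in count
  obs_col <- rep(NA_integer_, nmax)
  obs_col[seq_along(bins)] <- bins
  if (nrow(null_bins) < nmax) {
    null_bins <- rbind(null_bins, matrix(NA_integer_, nmax - nrow(null_bins),
                                         ncol(null_bins)))
  }
  all_bins <- cbind(obs_col, null_bins, deparse.level = 0)
  stack <- perievent_stack_cpp(st, all_bins, n, as.integer(pre_bins),
                               as.integer(post_bins))
  res <- battery_statistics(stack, n, alpha, n_corrections)
  res$results$significant <- res$results$p_value < alpha / n_corrections
  L_obs <- matrix(stack$L[, 1], n, n)
  out <- list(
    results = res$results,
    statewise = res$statewise,
    effect_significant = any(res$results$significant[
      res$results$statistic %in% effect_tests], na.rm = TRUE),
    tuning_significant = isTRUE(res$results$significant[
      res$results$statistic == "state_tuning_kld"]),
    sdo = new_sdo_matrix(L_obs, "raw", n_spikes = stack$k_used[1],
                         p0_bar = stack$p0_bar[, 1]),
    n_shuffles = n_shuffles, alpha = alpha,
    n_corrections = n_corrections, shuffle_method = shuffle_method,
    effect_tests = effect_tests, n_spikes = stack$k_used[1]
  )
  class(out) <- "sdo_significance"
  out
}

# core statistic computation from a perievent stack (column 1 = observed)
battery_statistics <- function(stack, n, alpha, n_corrections) {
  S <- ncol(stack$L) - 1L
  p0_obs <- stack$p0_bar[, 1]
  # rescale all operators to the observed pre-spike distribution:
  # column j scaled by p0_obs[j] / p0bar_s[j] (zero where unobserved)
  scale_cols <- function(A, p0bar) {
    f <- ifelse(p0bar > 0, 1, 0) * p0_obs / ifelse(p0bar > 0, p0bar, 1)
    A * f[rep(seq_len(n), each = n), , drop = FALSE]
  }
  Lr <- scale_cols(stack$L, stack$p0_bar)
  Jr <- scale_cols(stack$joint, stack$p0_bar)
  L_obs <- Lr[, 1]; L_null <- Lr[, -1, drop = FALSE]
  J_obs <- Jr[, 1]; J_null <- Jr[, -1, drop = FALSE]

  z_p <- function(obs, null_stats, one_sided_upper = TRUE) {
    mu <- mean(null_stats); sdv <- sd(null_stats)
    if (!is.finite(sdv) || sdv == 0) {
      z <- if (obs > mu) Inf else if (obs < mu) -Inf else 0
    } else z <- (obs - mu) / sdv
    p <- if (one_sided_upper) pnorm(z, lower.tail = FALSE)
         else pnorm(abs(z), lower.tail = FALSE)
    list(observed = obs, null_mean = mu, null_sd = sdv, z = z, p = p)
  }

  # element-wise standardized SSE
  mbar <- rowMeans(L_null)
  msd <- sqrt(pmax(rowMeans(L_null^2) - mbar^2, 0) * S / max(S - 1, 1))
  ok <- msd > 1e-14
  el_obs <- sum(((L_obs - mbar)[ok] / msd[ok])^2)
  el_null <- colSums(((L_null - mbar)[ok, , drop = FALSE] / msd[ok])^2)
  r_el <- z_p(el_obs, el_null)

  # raw matrix SSE against the null mean operator
  mx_obs <- sum((L_obs - mbar)^2)
  mx_null <- colSums((L_null - mbar)^2)
  r_mx <- z_p(mx_obs, mx_null)

  # joint-distribution SSE
  jbar <- rowMeans(J_null)
  jx_obs <- sum((J_obs - jbar)^2)
  jx_null <- colSums((J_null - jbar)^2)
  r_jx <- z_p(jx_obs, jx_null)

  # directional bias: sign(i - j) summed mass, per column and in total
  sgn <- as.vector(sign(outer(seq_len(n), seq_len(n), `-`)))  # i - j
  col_group <- rep(seq_len(n), each = n)
  b_obs <- rowsum(L_obs * sgn, col_group)[, 1]
  b_null <- rowsum(L_null * sgn, col_group)
  bmu <- rowMeans(b_null)
  bsd <- apply(b_null, 1, sd)
  occupied <- p0_obs > 0 & bsd > 1e-14
  zst <- ifelse(occupied, (b_obs - bmu) / ifelse(bsd > 0, bsd, 1), 0)
  pst <- pnorm(abs(zst), lower.tail = FALSE)
  statewise <- tibble::tibble(
    state = seq_len(n), bias = b_obs, null_mean = bmu, null_sd = bsd,
    z = zst, p_value = ifelse(occupied, pst, NA_real_),
    significant = ifelse(occupied, pst < alpha / n_corrections, NA)
  )
  best <- if (any(occupied)) which.min(replace(pst, !occupied, Inf)) else 1L
  r_sw <- list(observed = b_obs[best], null_mean = bmu[best],
               null_sd = bsd[best], z = zst[best],
               p = if (any(occupied)) pst[best] else NA_real_)

  t_obs <- sum(L_obs * sgn)
  t_null <- colSums(L_null * sgn)
  r_tb <- z_p(t_obs, t_null, one_sided_upper = FALSE)

  # pre-spike state tuning: KLD of observed state-at-spike distribution
  pa_obs <- stack$p_at_spike[, 1]
  pa_null <- stack$p_at_spike[, -1, drop = FALSE]
  q <- rowMeans(pa_null)
  k_obs <- kld(pa_obs, q)
  k_null <- apply(pa_null, 2, kld, q = q)
  r_kl <- z_p(k_obs, k_null)

  rows <- list(element_sse = r_el, matrix_sse = r_mx, joint_sse = r_jx,
               statewise_bias = r_sw, total_bias = r_tb,
               state_tuning_kld = r_kl)
  results <- tibble::tibble(
    statistic = names(rows),
    observed = vapply(rows, `[[`, numeric(1), "observed"),
    null_mean = vapply(rows, `[[`, numeric(1), "null_mean"),
    null_sd = vapply(rows, `[[`, numeric(1), "null_sd"),
    z = vapply(rows, `[[`, numeric(1), "z"),
    p_value = vapply(rows, `[[`, numeric(1), "p")
  )
  list(results = results, statewise = statewise)
}

# epsilon-smoothed Kullback-Leibler divergence D(p || q)
kld <- function(p, q, eps = 1e-6) {
  p <- p + eps; p <- p / sum(p)
  q <- q + eps; q <- q / sum(q)
  sum(p * log(p / q))
}

#' @export
print.sdo_significance <- function(x, ...) {
  cat(sprintf(
    "<sdo_significance> %d spikes vs %d %s surrogates (alpha %g / %d)\n",
    x$n_spikes, x$n_shuffles, x$shuffle_method, x$alpha, x$n_corrections))
  print(as.data.frame(x$results), digits = 3)
  cat(sprintf("spike effect: %s;  state tuning: %s\n",
              x$effect_significant, x$tuning_significant))
  invisible(x)
}

#' Combine SDO significance results into an overall decision
#'
#' A spike-triggered SDO is deemed significant if any *effect* statistic
#' passes the Bonferroni-corrected threshold. The state-tuning divergence
#' flags tuning, not effect, and is reported separately.
#'
#' @param results Tibble of statistic rows (from [sdo_significance()]).
#' @param alpha Significance level.
#' @param n_corrections Bonferroni divisor (number of states).
#' @param effect_tests Statistics counted as effect tests.
#' @return A list with logical `effect` and `tuning`.
#' @export
decide_significance <- function(results, alpha = 0.05, n_corrections = 20,
                                effect_tests = c("element_sse", "matrix_sse",
                                                 "joint_sse", "total_bias")) {
  stopifnot(nrow(results) > 0)
  thr <- alpha / n_corrections
  eff <- results$statistic %in% effect_tests
  tun <- results$statistic == "state_tuning_kld"
  list(effect = any(results$p_value[eff] < thr, na.rm = TRUE),
       tuning = any(results$p_value[tun] < thr, na.rm = TRUE))
}

#' Low-level five-feature statistic battery
#'
#' Computes the significance statistics from pre-assembled rescaled
#' operators, for callers that build their own null ensembles. Most users
#' should call [sdo_significance()].
#'
#' @param L_obs Observed rescaled operator (matrix).
#' @param L_null_set List (or `n^2 x S` matrix) of rescaled null operators.
#' @param joint_obs,joint_nulls Optional joint distributions, same shapes.
#' @param p_at_spike_obs,p_at_spike_nulls Optional state-at-spike
#'   distributions (vector; `n x S` matrix).
#' @param alpha,n_corrections Decision parameters.
#' @return Tibble of statistic rows (see [sdo_significance()]).
#' @export
sdo_test_statistics <- function(L_obs, L_null_set, joint_obs = NULL,
                                joint_nulls = NULL, p_at_spike_obs = NULL,
                                p_at_spike_nulls = NULL, alpha = 0.05,
                                n_corrections = NULL) {
  if (is.list(L_null_set)) {
    L_null_set <- vapply(L_null_set, function(m) as.vector(as.matrix(m)),
                         numeric(length(as.matrix(L_obs))))
  }
  if (is.matrix(L_obs)) L_obs <- as.vector(L_obs)
  n <- as.integer(sqrt(length(L_obs)))
  S <- ncol(L_null_set)
  if (S < 2) stop("need at least 2 null operators", call. = FALSE)
  n_corrections <- n_corrections %||% n
  if (is.null(joint_obs)) { joint_obs <- L_obs; joint_nulls <- L_null_set }
  if (is.matrix(joint_obs)) joint_obs <- as.vector(joint_obs)
  if (is.null(p_at_spike_obs)) {
    p_at_spike_obs <- rep(1 / n, n)
    p_at_spike_nulls <- matrix(1 / n, n, S)
  }
  stack <- list(
    L = cbind(L_obs, L_null_set),
    joint = cbind(joint_obs, joint_nulls),
    p_at_spike = cbind(p_at_spike_obs, p_at_spike_nulls),
    p0_bar = matrix(1, n, S + 1)   # already rescaled: no further scaling
  )
  res <- battery_statistics(stack, n, alpha, n_corrections)
  res$results$significant <- res$results$p_value < alpha / n_corrections
  res$results
}
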