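#' Hypothesis matrices H1-H7
#'
#' Seven predictor matrices, each applied through the common update
#' `p_hat(x1) = p(x0) + M p(x0)` and each satisfying the four SDO
#' constraints. They embody competing statistical models of the
#' spike-signal relationship:
#'
#' * **H1** no effect, no drift (zero matrix);
#' * **H2** no effect, random drift (Gaussian diffusion of the prior);
#' * **H3** the classical STA in state space (every prior maps to the mean
#'   post-spike distribution);
#' * **H4** background dynamics only (operator estimated over all time
#'   points, conditional form);
#' * **H5** Markov transition dynamics estimated in the pre-spike windows,
#'   iterated and averaged over the post window;
#' * **H6** background dynamics plus a state-independent STA-like shift;
#' * **H7** the spike-triggered SDO (conditional form).
#'
#' @name hypotheses
NULL

#' @describeIn hypotheses Null hypothesis: zero change operator.
#' @param n_states Number of states.
#' @export
h1_null <- function(n_states) {
  new_sdo_matrix(matrix(0, n_states, n_states), form = "normalized",
                 h_id = "H1")
}

#' @describeIn hypotheses Diffusion: `M = G - I` where `G` is the identity
#'   convolved column-wise with a Gaussian kernel of width `sigma` states
#'   (edge columns renormalized after truncation).
#' @param sigma Gaussian kernel width in states.
#' @export
h2_diffusion <- function(n_states, sigma = 1) {
  stopifnot(sigma > 0)
  G <- gaussian_band_matrix(n_states, sigma)
  new_sdo_matrix(G - diag(n_states), form = "normalized", h_id = "H2")
}

# column-stochastic band matrix: column j is a discretized Gaussian at j
gaussian_band_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  G <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  sweep(G, 2, colSums(G), `/`)
}

#' @describeIn hypotheses Classical STA in state space:
#'   `M = P1_bar 1' - I`, which maps every prior to `P1_bar`.
#' @param P1_bar Average post-spike state distribution.
#' @export
h3_sta <- function(P1_bar) {
  P1_bar <- as.numeric(P1_bar)
  stopifnot(abs(sum(P1_bar) - 1) < 1e-6, all(P1_bar >= -1e-12))
  n <- length(P1_bar)
  M <- matrix(P1_bar, n, n) - diag(n)
  new_sdo_matrix(M, form = "normalized", h_id = "H3")
}

#' @describeIn hypotheses Background operator: the linear SDO estimated
#'   with every valid time index treated as an event, returned in
#'   conditional (normalized) form.
#' @param states A [state_series()].
#' @param pre_bins,post_bins Window lengths in bins.
#' @export
h4_background <- function(states, pre_bins = 20, post_bins = 20) {
  stopifnot(inherits(states, "state_series"))
  T_len <- length(states$states)
  if (T_len <= pre_bins + post_bins) {
    stop("state series shorter than pre + post windows", call. = FALSE)
  }
  centers <- seq.int(pre_bins, T_len - post_bins)
  ens <- perievent_distributions(states, centers, pre_bins, post_bins)
  L <- estimate_sdo_linear(ens)
  out <- normalize_sdo(L)
  out$h_id <- "H4"
  class(out) <- c("sdo_hypothesis", "sdo_matrix")
  out
}

#' @describeIn hypotheses Markov dynamics: a first-order left-stochastic
#'   transition matrix `M0` is estimated from successive state pairs inside
#'   the pre-spike windows; the change operator is
#'   `mean(M0^t, t = 1..T) - I` with `T = post_bins`. Source states with no
#'   observed transitions keep an identity column (self-transition).
#' @param ens An [perievent_distributions()] ensemble (for its spike bins
#'   and window geometry).
#' @export
h5_markov <- function(states, ens, post_bins = ens$post_bins) {
  stopifnot(inherits(states, "state_series"))
  st <- states$states
  n <- states$n_states
  pre <- ens$pre_bins
  # successive pairs strictly inside each pre-spike window (s - pre, s]
  from <- unlist(lapply(ens$spike_bins, function(s) st[(s - pre + 1L):(s - 1L)]))
  to <- unlist(lapply(ens$spike_bins, function(s) st[(s - pre + 2L):s]))
  if (length(from) == 0L) stop("no transitions in pre-spike windows", call. = FALSE)
  M0 <- transition_matrix(from, to, n)
  Mavg <- markov_window_average(M0, post_bins)
  new_sdo_matrix(Mavg - diag(n), form = "normalized", h_id = "H5")
}

# counts -> left-stochastic matrix (columns = source state, sum to 1);
# unobserved source columns fall back to self-transition
transition_matrix <- function(from, to, n) {
  counts <- matrix(tabulate(to + (from - 1L) * n, nbins = n * n), nrow = n)
  cs <- colSums(counts)
  M <- matrix(0, n, n)
  obs <- cs > 0
  M[, obs] <- sweep(counts[, obs, drop = FALSE], 2, cs[obs], `/`)
  if (any(!obs)) diag(M)[!obs] <- 1
  M
}

# (1/T) * sum_{t=1..T} M0^t
markov_window_average <- function(M0, T_steps) {
  acc <- matrix(0, nrow(M0), ncol(M0))
  Mp <- diag(nrow(M0))
  for (t in seq_len(T_steps)) {
    Mp <- M0 %*% Mp
    acc <- acc + Mp
  }
  acc / T_steps
}

#' @describeIn hypotheses Background plus STA: the conditional background
#'   operator plus a rank-one column-constant term adding the mean
#'   spike-triggered change `dP_bar`. If the sum violates the operator
#'   constraints it is projected back (off-diagonal clipped at zero,
#'   columns rebalanced); the repair magnitude is recorded in the
#'   `repair_l1` attribute.
#' @param LB The H4 background hypothesis (normalized form).
#' @param dP_bar Mean over spikes of `p(x1) - p(x0)`.
#' @export
h6_background_plus_sta <- function(LB, dP_bar) {
  stopifnot(inherits(LB, "sdo_matrix"))
  n <- nrow(LB$L)
  dP_bar <- as.numeric(dP_bar)
  stopifnot(length(dP_bar) == n, abs(sum(dP_bar)) < 1e-6)
  M <- LB$L + matrix(dP_bar, n, n)
  proj <- project_to_sdo(M)
  out <- new_sdo_matrix(proj$M, form = "normalized", h_id = "H6")
  attr(out, "repair_l1") <- proj$repair_l1
  out
}

# clip to the constraint set; report total absolute adjustment
project_to_sdo <- function(M) {
  n <- nrow(M)
  W <- M; diag(W) <- 0
  W_clip <- pmax(W, 0)
  cs <- colSums(W_clip)
  over <- cs > 1
  if (any(over)) W_clip[, over] <- sweep(W_clip[, over, drop = FALSE], 2,
                                         cs[over], `/`)
  out <- W_clip
  diag(out) <- -colSums(W_clip)
  list(M = out, repair_l1 = sum(abs(out - M)))
}

#' @describeIn hypotheses Spike-triggered SDO: the direct linear (or
#'   constrained) estimate of the perievent ensemble, in conditional form.
#' @param method `"linear"` (default) or `"optim"`.
#' @export
h7_spike_sdo <- function(ens, method = c("linear", "optim")) {
  method <- match.arg(method)
  L <- if (method == "linear") estimate_sdo_linear(ens) else estimate_sdo_optim(ens)
  out <- normalize_sdo(L)
  out$h_id <- "H7"
  class(out) <- c("sdo_hypothesis", "sdo_matrix")
  out
}

#' Fit all seven hypothesis matrices
#'
#' Convenience wrapper building H1-H7 from one state series and spike
#' train, sharing a single perievent ensemble.
#'
#' @inheritParams perievent_distributions
#' @param sigma_h2 Kernel width for H2, in states.
#' @param sdo_method Estimator for H7 (`"linear"` or `"optim"`).
#' @return Named list `H1`..`H7` of hypothesis matrices, with the training
#'   ensemble attached as attribute `ensemble`.
#' @export
fit_hypotheses <- function(states, spikes, pre_bins = 20, post_bins = 20,
                           sigma_h2 = 1, sdo_method = "linear") {
  ens <- if (inherits(spikes, "sdo_ensemble")) spikes else
    perievent_distributions(states, spikes, pre_bins, post_bins)
  n <- ens$n_states
  LB <- h4_background(states, ens$pre_bins, ens$post_bins)
  hyps <- list(
    H1 = h1_null(n),
    H2 = h2_diffusion(n, sigma_h2),
    H3 = h3_sta(rowMeans(ens$P1)),
    H4 = LB,
    H5 = h5_markov(states, ens),
    H6 = h6_background_plus_sta(LB, rowMeans(ens$dP)),
    H7 = h7_spike_sdo(ens, method = sdo_method)
  )
  attr(hyps, "ensemble") <- ens
  hyps
}
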