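#' Per-spike predictions under the hypothesis matrices
#'
#' Applies each hypothesis through the common update
#' `p_hat(x1) = p(x0) + M p(x0)` on an event-wise basis, and scores the
#' prediction against the observed post-spike distribution and its peak
#' state. The "single best state" is the argmax of the distribution
#' (lowest index on ties).
#'
#' @param hyps Named list of hypothesis matrices (see [fit_hypotheses()]),
#'   or a single `sdo_matrix`.
#' @param ens Evaluation ensemble from [perievent_distributions()]; should
#'   be disjoint from the training spikes when train/test hygiene is
#'   configured.
#' @return A tibble of class `sdo_predictions` with one row per
#'   (hypothesis, spike): `hypothesis`, `spike`, `x1_obs`, `x1_hat`, `e0`
#'   (miss indicator), `e1` (absolute state error), `e2` (squared), `kld`
#'   (divergence of observed from predicted), `loglik`.
#' @export
predict_all <- function(hyps, ens) {
  if (inherits(hyps, "sdo_matrix")) hyps <- list(H = hyps)
  stopifnot(inherits(ens, "sdo_ensemble") || (!is.null(ens$P0) && !is.null(ens$P1)))
  P0 <- ens$P0; P1 <- ens$P1
  n <- nrow(P0); k <- ncol(P0)
  x1_obs <- max.col(t(P1), ties.method = "first")
  out <- purrr::imap(hyps, function(h, name) {
    M <- if (inherits(h, "sdo_matrix")) h$L else as.matrix(h)
    if (ncol(M) != n) stop("hypothesis/ensemble state-count mismatch",
                           call. = FALSE)
    P1_hat <- P0 + M %*% P0
    P1_hat[P1_hat < 0 & P1_hat > -1e-9] <- 0
    x1_hat <- max.col(t(P1_hat), ties.method = "first")
    tibble::tibble(
      hypothesis = name, spike = seq_len(k),
      x1_obs = x1_obs, x1_hat = x1_hat,
      e0 = as.integer(x1_hat != x1_obs),
      e1 = abs(x1_hat - x1_obs),
      e2 = (x1_hat - x1_obs)^2,
      kld = kld_cols(P1, P1_hat),
      loglik = log_pred_lik(P1_hat, x1_obs)
    )
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("sdo_predictions", class(res))
  res
}

# column-wise epsilon-smoothed D(observed || predicted)
kld_cols <- function(P_obs, P_hat, eps = 1e-6) {
  P <- sweep(P_obs + eps, 2, colSums(P_obs + eps), `/`)
  Q <- sweep(P_hat + eps, 2, colSums(P_hat + eps), `/`)
  colSums(P * log(P / Q))
}

log_pred_lik <- function(P_hat, x1_obs, eps = 1e-6) {
  Q <- sweep(P_hat + eps, 2, colSums(P_hat + eps), `/`)
  log(Q[cbind(x1_obs, seq_along(x1_obs))])
}

#' Summarize prediction errors per hypothesis
#'
#' Cumulative single-state errors (`e0`, `e1`, `e2`) and mean
#' distribution-level scores (`kld`, `loglik`) over spikes.
#'
#' @param pred An [predict_all()] result.
#' @return A tibble with one row per hypothesis.
#' @export
score_predictions <- function(pred) {
  dplyr::summarise(
    dplyr::group_by(pred, hypothesis),
    k = dplyr::n(),
    e0 = sum(.data$e0), e1 = sum(.data$e1), e2 = sum(.data$e2),
    kld_mean = mean(.data$kld), loglik_mean = mean(.data$loglik),
    .groups = "drop"
  )
}

#' Bootstrap confidence interval of a cumulative error
#'
#' Because single-state errors are integers with awkward distributions,
#' model comparisons use the cumulative error and a bootstrap of its
#' sampling distribution: spikes are resampled with replacement and the
#' cumulative sum recomputed.
#'
#' @param per_spike_errors Numeric vector of per-spike errors.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return A list with `estimate` (observed cumulative error), `lower`,
#'   `upper`, and `boot` (the bootstrap distribution).
#' @export
bootstrap_ci <- function(per_spike_errors, n_boot = 1000, conf = 0.95) {
  k <- length(per_spike_errors)
  stopifnot(k >= 2)
  boot <- vapply(seq_len(n_boot), function(b) {
    sum(per_spike_errors[sample.int(k, k, replace = TRUE)])
  }, numeric(1))
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(estimate = sum(per_spike_errors), lower = qs[1], upper = qs[2],
       boot = boot)
}

#' Cohen's d between two bootstrap distributions
#'
#' `(mean(a) - mean(b)) / pooled SD`. A zero pooled SD with unequal means
#' returns signed infinity.
#'
#' @param a,b Numeric vectors (e.g. bootstrap cumulative errors).
#' @return Effect size (numeric scalar).
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  na <- length(a); nb <- length(b)
  pooled <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) /
                   max(na + nb - 2, 1))
  dm <- mean(a) - mean(b)
  if (!is.finite(pooled) || pooled == 0) {
    return(sign(dm) * Inf * (dm != 0))
  }
  dm / pooled
}

#' Compare hypothesis models on a common evaluation set
#'
#' Bootstraps the cumulative absolute single-state error (`e1`) and the
#' cumulative distribution divergence (`kld`) per hypothesis; the best fit
#' per metric is the hypothesis minimizing the cumulative error, and two
#' hypotheses are deemed significantly different when their bootstrap
#' confidence intervals do not overlap.
#'
#' @param pred An [predict_all()] result (all hypotheses on the same
#'   spikes).
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @return A list of class `sdo_model_comparison`: `table` (per-hypothesis
#'   tibble with estimates and CIs for both metrics), `best_state`
#'   (hypothesis minimizing cumulative `e1`), `best_distribution`
#'   (minimizing cumulative `kld`), `cohens_d` (tibble of pairwise effect
#'   sizes on `e1` against the best hypothesis), `overlap` (pairwise CI
#'   overlap matrix for `e1`).
#' @export
compare_models <- function(pred, n_boot = 1000, conf = 0.95) {
  hyp_names <- unique(pred$hypothesis)
  stopifnot(length(hyp_names) >= 1)
  per_hyp <- lapply(hyp_names, function(h) pred[pred$hypothesis == h, ])
  names(per_hyp) <- hyp_names
  ci_e1 <- lapply(per_hyp, function(d) bootstrap_ci(d$e1, n_boot, conf))
  ci_kld <- lapply(per_hyp, function(d) bootstrap_ci(d$kld, n_boot, conf))
  tab <- tibble::tibble(
    hypothesis = hyp_names,
    e1 = vapply(ci_e1, `[[`, numeric(1), "estimate"),
    e1_lower = vapply(ci_e1, `[[`, numeric(1), "lower"),
    e1_upper = vapply(ci_e1, `[[`, numeric(1), "upper"),
    kld = vapply(ci_kld, `[[`, numeric(1), "estimate"),
    kld_lower = vapply(ci_kld, `[[`, numeric(1), "lower"),
    kld_upper = vapply(ci_kld, `[[`, numeric(1), "upper")
  )
  best_state <- hyp_names[which.min(tab$e1)]
  best_distribution <- hyp_names[which.min(tab$kld)]
  overlap <- outer(seq_along(hyp_names), seq_along(hyp_names),
                   Vectorize(function(i, j) {
                     tab$e1_lower[i] <= tab$e1_upper[j] &&
                       tab$e1_lower[j] <= tab$e1_upper[i]
                   }))
  dimnames(overlap) <- list(hyp_names, hyp_names)
  dtab <- tibble::tibble(
    hypothesis = hyp_names,
    d_vs_best = vapply(hyp_names, function(h) {
      cohens_d(ci_e1[[h]]$boot, ci_e1[[best_state]]$boot)
    }, numeric(1))
  )
  structure(list(table = tab, best_state = best_state,
                 best_distribution = best_distribution,
                 cohens_d = dtab, overlap = overlap, conf = conf),
            class = "sdo_model_comparison")
}

#' @export
print.sdo_model_comparison <- function(x, ...) {
  cat(sprintf("<sdo_model_comparison> best (state): %s; best (distribution): %s\n",
              x$best_state, x$best_distribution))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Train/test split of an ensemble by spike
#'
#' @param ens An [perievent_distributions()] ensemble.
#' @param train_frac Fraction (or count if `> 1`) of spikes used for
#'   training.
#' @return List with `train` and `test` ensembles (disjoint spikes).
#' @export
split_ensemble <- function(ens, train_frac = 0.4) {
  k <- ens$k
  n_train <- if (train_frac > 1) as.integer(train_frac)
             else as.integer(round(train_frac * k))
  stopifnot(n_train >= 1, n_train < k)
  idx <- sample.int(k, n_train)
  take <- function(cols) {
    out <- ens
    out$P0 <- ens$P0[, cols, drop = FALSE]
    out$P1 <- ens$P1[, cols, drop = FALSE]
    out$dP <- ens$dP[, cols, drop = FALSE]
    out$spike_bins <- ens$spike_bins[cols]
    out$k <- length(cols)
    out
  }
  list(train = take(sort(idx)), test = take(sort(setdiff(seq_len(k), idx))))
}
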