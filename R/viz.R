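#' Spike-triggered impulse response probability distribution (STIRPD)
#'
#' The probabilistic analogue of the STA: for every time bin relative to
#' the spike, the distribution of signal states across spikes. Columns
#' (time bins) each sum to 1. Averaging the pre-window columns reproduces
#' the ensemble mean pre-spike distribution `p(x0)`.
#'
#' @param states A [state_series()].
#' @param spikes A [spike_train()] or integer spike bins.
#' @param pre_bins,post_bins Window extents in bins (the pre window
#'   includes the spike bin as its final element).
#' @return An object of class `sdo_stirpd`: list with `matrix`
#'   (`n_states` x `(pre_bins + post_bins)`), `lags` (bin offsets),
#'   `overlay_mean` (mean state per time bin), `k`, `n_dropped`.
#' @export
compute_stirpd <- function(states, spikes, pre_bins = 20, post_bins = 20) {
  stopifnot(inherits(states, "state_series"))
  st <- states$states
  n <- states$n_states
  bins <- if (is.numeric(spikes) && !inherits(spikes, "spike_train")) {
    as.integer(spikes)
  } else {
    spike_bins(spikes, states$fs)
  }
  offsets <- seq.int(-pre_bins + 1L, post_bins)
  keep <- bins + offsets[1] >= 1L & bins + post_bins <= length(st)
  n_dropped <- sum(!keep)
  bins <- bins[keep]
  if (length(bins) == 0L) stop("no spikes with complete windows", call. = FALSE)
  k <- length(bins)
  M <- vapply(offsets, function(o) tabulate(st[bins + o], n) / k, numeric(n))
  structure(list(matrix = M, lags = offsets,
                 overlay_mean = colSums(M * seq_len(n)),
                 k = k, n_dropped = n_dropped,
                 pre_bins = pre_bins, post_bins = post_bins, fs = states$fs),
            class = "sdo_stirpd")
}

#' @export
print.sdo_stirpd <- function(x, ...) {
  cat(sprintf("<sdo_stirpd> %d states x %d lags, %d spikes\n",
              nrow(x$matrix), ncol(x$matrix), x$k))
  invisible(x)
}

#' Shear an SDO matrix to align the diagonal horizontally
#'
#' Element `(i, j)` maps to row `i - j + n` of column `j` in a
#' `(2n - 1) x n` array, so row `n` carries the original diagonal,
#' rows above it transitions toward higher states, rows below toward
#' lower states.
#'
#' @param L Square matrix or `sdo_matrix`.
#' @return A `(2n - 1) x n` matrix; attribute `n_states` records `n`.
#' @export
shear_sdo <- function(L) {
  if (inherits(L, "sdo_matrix")) L <- L$L
  n <- nrow(L)
  out <- matrix(0, 2 * n - 1, n)
  ij <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  out[cbind(ij[, 1] - ij[, 2] + n, ij[, 2])] <- L[ij]
  attr(out, "n_states") <- n
  out
}

#' Invert [shear_sdo()]
#' @param S A sheared `(2n - 1) x n` matrix.
#' @return The original `n x n` matrix.
#' @export
unshear_sdo <- function(S) {
  n <- attr(S, "n_states") %||% ((nrow(S) + 1) / 2)
  L <- matrix(0, n, n)
  ij <- which(matrix(TRUE, n, n), arr.ind = TRUE)
  L[ij] <- S[cbind(ij[, 1] - ij[, 2] + n, ij[, 2])]
  L
}

#' Coarse directional summary ("quiver") of an SDO
#'
#' For each input state `j`: the summed probability mass flowing toward
#' higher states (`up_mass`, rows `i > j`), toward lower states
#' (`down_mass`, rows `i < j`), and the diagonal element. For a raw SDO
#' these three sum to the column sum, i.e. zero.
#'
#' @param L Square matrix or `sdo_matrix`.
#' @return A tibble with columns `state`, `up_mass`, `down_mass`,
#'   `diag_value`.
#' @export
quiver_summary <- function(L) {
  if (inherits(L, "sdo_matrix")) L <- L$L
  n <- nrow(L)
  up <- vapply(seq_len(n), function(j) sum(L[seq_len(n) > j, j]), numeric(1))
  down <- vapply(seq_len(n), function(j) sum(L[seq_len(n) < j, j]), numeric(1))
  tibble::tibble(state = seq_len(n), up_mass = up, down_mass = down,
                 diag_value = diag(L))
}

#' Heuristic motif classification of an SDO
#'
#' Scores the operator's positive off-diagonal mass against nine
#' qualitative geometry classes (step up/down, convergence, divergence,
#' increase, decrease, stabilize, destabilize, diffusion). A motif wins if
#' its score reaches `threshold` and exceeds the runner-up by `margin`;
#' otherwise the label is `"unclassified"`. The classifier is advisory —
#' the classes are qualitative by nature and the scores are heuristic.
#'
#' @param L A normalized `sdo_matrix` (or plain matrix).
#' @param threshold Winning score threshold.
#' @param margin Required lead over the runner-up.
#' @return A list of class `sdo_motif`: `label`, `scores` (named, in
#'   `[0, 1]`).
#' @export
classify_motif <- function(L, threshold = 0.6, margin = 0.1) {
  M <- if (inherits(L, "sdo_matrix")) L$L else as.matrix(L)
  n <- nrow(M)
  pos <- pmax(M, 0); diag(pos) <- 0
  tot <- sum(pos)
  scores <- c(step_up = 0, step_down = 0, convergence = 0, divergence = 0,
              increase = 0, decrease = 0, stabilize = 0, destabilize = 0,
              diffusion = 0)
  if (tot > 1e-12) {
    ij <- which(pos > 0, arr.ind = TRUE)
    w <- pos[ij] / tot
    delta <- ij[, 1] - ij[, 2]
    # column-wise direction balance
    up <- vapply(seq_len(n), function(j) sum(pos[seq_len(n) > j, j]), numeric(1))
    dn <- vapply(seq_len(n), function(j) sum(pos[seq_len(n) < j, j]), numeric(1))
    colw <- up + dn
    occ <- colw > 1e-12
    dirj <- ifelse(occ, (up - dn) / pmax(colw, 1e-12), 0)
    occw <- colw[occ] / sum(colw[occ])
    scores["increase"] <- sum(occw * pmax(dirj[occ], 0))
    scores["decrease"] <- sum(occw * pmax(-dirj[occ], 0))
    scores["diffusion"] <- sum(occw * 2 * pmin(up, dn)[occ] /
                                 pmax(colw[occ], 1e-12))
    # stabilize / destabilize: direction reverses around a set point
    if (sum(occ) >= 2) {
      states_occ <- which(occ)
      setpt <- sum(states_occ * occw)
      toward <- sign(setpt - states_occ)
      scores["stabilize"] <- sum(occw * pmax(dirj[occ] * toward, 0))
      scores["destabilize"] <- sum(occw * pmax(-dirj[occ] * toward, 0))
    }
    # convergence: positive mass concentrated on one destination row band
    rowmass <- vapply(seq_len(n), function(i) sum(pos[i, ]), numeric(1)) / tot
    r <- which.max(rowmass)
    band <- sum(rowmass[max(1, r - 1):min(n, r + 1)])
    col_spread <- sum(colw > tot * 0.02)
    scores["convergence"] <- band * min(1, col_spread / 3)
    # divergence: mass flees a source band to both sides
    scores["divergence"] <- scores["diffusion"] *
      min(1, mean(abs(delta) > 2))
    # a single-destination band is convergence, not a feedback controller:
    # damp the stabilize/destabilize reading when one row dominates
    scores["stabilize"] <- scores["stabilize"] * (1 - scores["convergence"])
    scores["destabilize"] <- scores["destabilize"] * (1 - scores["convergence"])
    # step: mass concentrated on one off-diagonal offset band
    dpos <- delta[delta > 0]; wpos <- w[delta > 0]
    dneg <- -delta[delta < 0]; wneg <- w[delta < 0]
    band_frac <- function(d, wt) {
      if (!length(d)) return(0)
      vapply(sort(unique(d)), function(c0) sum(wt[abs(d - c0) <= 1]),
             numeric(1)) |> max()
    }
    scores["step_up"] <- band_frac(dpos, wpos) * sum(wpos) *
      (1 - scores["convergence"])
    scores["step_down"] <- band_frac(dneg, wneg) * sum(wneg) *
      (1 - scores["convergence"])
  }
  scores <- pmin(pmax(scores, 0), 1)
  ord <- order(scores, decreasing = TRUE)
  label <- if (scores[ord[1]] >= threshold &&
               (length(scores) < 2 || scores[ord[1]] - scores[ord[2]] >= margin)) {
    names(scores)[ord[1]]
  } else "unclassified"
  structure(list(label = label, scores = scores), class = "sdo_motif")
}

#' @export
print.sdo_motif <- function(x, ...) {
  cat(sprintf("<sdo_motif> %s\n", x$label))
  print(round(sort(x$scores, decreasing = TRUE), 3))
  invisible(x)
}

#' Plot methods
#'
#' `autoplot()` methods render an SDO heatmap (destination state vs input
#' state), a STIRPD raster with the mean-state overlay, and a quiver-style
#' directional summary.
#'
#' @param object An `sdo_matrix` or `sdo_stirpd`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name sdo-plots
NULL

#' @rdname sdo-plots
#' @importFrom ggplot2 autoplot
#' @export
autoplot.sdo_matrix <- function(object, ...) {
  L <- object$L
  df <- tidyr::expand_grid(x1 = seq_len(nrow(L)), x0 = seq_len(ncol(L)))
  df$value <- L[cbind(df$x1, df$x0)]
  lim <- max(abs(L))
  ggplot2::ggplot(df, ggplot2::aes(.data$x0, .data$x1, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B",
                                  limits = c(-lim, lim)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         linewidth = 0.3) +
    ggplot2::labs(x = "input state x0", y = "output state x1",
                  fill = expression(Delta * p),
                  title = sprintf("SDO (%s form)", object$form)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @rdname sdo-plots
#' @export
autoplot.sdo_stirpd <- function(object, ...) {
  M <- object$matrix
  df <- tidyr::expand_grid(state = seq_len(nrow(M)),
                           lag = object$lags)
  df$prob <- as.vector(M[cbind(df$state, match(df$lag, object$lags))])
  ov <- tibble::tibble(lag = object$lags, mean_state = object$overlay_mean)
  ggplot2::ggplot(df, ggplot2::aes(.data$lag, .data$state)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$prob)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::geom_line(data = ov,
                       ggplot2::aes(.data$lag, .data$mean_state),
                       color = "white", linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2, color = "red") +
    ggplot2::labs(x = "time bin relative to spike", y = "state",
                  fill = "p(state | t)", title = "STIRPD") +
    ggplot2::theme_minimal()
}

#' @rdname sdo-plots
#' @param L Square matrix or `sdo_matrix` for the quiver summary.
#' @export
plot_quiver <- function(L) {
  q <- quiver_summary(L)
  ggplot2::ggplot(q, ggplot2::aes(x = .data$state)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$state, y = 0,
                                       yend = .data$up_mass),
                          color = "#E08214", linewidth = 1) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$state, y = 0,
                                       yend = -.data$down_mass),
                          color = "#8073AC", linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$diag_value), linetype = 3) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "input state", y = expression(sum(Delta * p)),
                  title = "Quiver summary (orange: up, purple: down)") +
    ggplot2::theme_minimal()
}

#' Render a run report
#'
#' Runs estimation, significance and prediction on one (signal, spike
#' train) pair and writes deterministic artifacts to a directory: the SDO
#' heatmap, shear and quiver views, the STIRPD, prediction error summary,
#' and a JSON manifest. Figures are skipped (and listed) if their inputs
#' are missing (e.g. too few spikes for significance).
#'
#' @param states A [state_series()].
#' @param spikes A [spike_train()] or spike bins.
#' @param dir Output directory (created if needed).
#' @param pre_bins,post_bins Window lengths.
#' @param n_shuffles Shuffles for the significance battery (`0` skips it).
#' @param render_figures Render PNG figures (requires a PNG device).
#' @return Invisibly, a character vector of written file paths.
#' @export
sdo_report <- function(states, spikes, dir, pre_bins = 20, post_bins = 20,
                       n_shuffles = 0, render_figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  skipped <- character()
  ens <- perievent_distributions(states, spikes, pre_bins, post_bins)
  sdo <- estimate_sdo_linear(ens)
  save_plot <- function(p, name) {
    path <- file.path(dir, name)
    if (!render_figures) {
      skipped <<- c(skipped, basename(path))
      return(invisible(NULL))
    }
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 120)
    written <<- c(written, path)
  }
  save_plot(autoplot(sdo), "sdo_matrix.png")
  save_plot(plot_quiver(sdo), "sdo_quiver.png")
  stirpd <- compute_stirpd(states, spikes, pre_bins, post_bins)
  save_plot(autoplot(stirpd), "stirpd.png")

  hyps <- fit_hypotheses(states, spikes, pre_bins, post_bins)
  pred <- predict_all(hyps, attr(hyps, "ensemble"))
  sc <- score_predictions(pred)
  utils::write.csv(sc, file.path(dir, "prediction_scores.csv"),
                   row.names = FALSE)
  written <- c(written, file.path(dir, "prediction_scores.csv"))

  sig_summary <- NULL
  if (n_shuffles >= 2) {
    sig <- sdo_significance(states, spikes, pre_bins, post_bins,
                            n_shuffles = n_shuffles)
    utils::write.csv(sig$results, file.path(dir, "significance.csv"),
                     row.names = FALSE)
    written <- c(written, file.path(dir, "significance.csv"))
    sig_summary <- list(effect = sig$effect_significant,
                        tuning = sig$tuning_significant)
  } else {
    skipped <- c(skipped, "significance.csv (n_shuffles < 2)")
  }
  manifest <- list(
    n_states = states$n_states, n_spikes = ens$k,
    n_dropped_boundary = ens$n_dropped,
    pre_bins = pre_bins, post_bins = post_bins, n_shuffles = n_shuffles,
    motif = classify_motif(normalize_sdo(sdo))$label,
    significance = sig_summary, skipped = skipped,
    files = basename(written)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(written, file.path(dir, "manifest.json")))
}
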