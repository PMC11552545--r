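#' Perievent state distribution ensemble
#'
#' For each spike, the pre-event distribution is the state histogram over
#' the `pre_bins` time bins ending at (and including) the bin containing
#' the spike timestamp, `(s - pre_bins, s]`; the post-event distribution is
#' the histogram over the `post_bins` bins after it, `(s, s + post_bins]`.
#' Spikes whose windows would cross a trial boundary are dropped and
#' counted (padding would bias the distributions).
#'
#' @param states A [state_series()].
#' @param spikes A [spike_train()] (times in seconds) or an integer vector
#'   of spike sample bins (1-based).
#' @param pre_bins,post_bins Window lengths in time bins (default 20 bins,
#'   i.e. 10 ms at 2 kHz).
#' @return An object of class `sdo_ensemble`: list with `P0`, `P1`, `dP`
#'   (`n_states` x `k` matrices of per-spike distributions), `spike_bins`,
#'   `n_states`, `k`, `n_dropped`, `pre_bins`, `post_bins`, `fs`.
#' @examples
#' ss <- state_series(rep(1:4, each = 4), fs = 8, n_states = 4)
#' perievent_distributions(ss, spikes = 8L, pre_bins = 4, post_bins = 4)$P0
#' @export
perievent_distributions <- function(states, spikes, pre_bins = 20,
                                    post_bins = 20) {
  stopifnot(inherits(states, "state_series"), pre_bins >= 1, post_bins >= 1)
  st <- states$states
  n <- states$n_states
  bins <- if (is.numeric(spikes) && !inherits(spikes, "spike_train")) {
    as.integer(spikes)
  } else {
    spike_bins(spikes, states$fs)
  }
  keep <- bins - pre_bins + 1L >= 1L & bins + post_bins <= length(st)
  n_dropped <- sum(!keep)
  bins <- bins[keep]
  k <- length(bins)
  if (k == 0L) stop("no spikes with complete perievent windows", call. = FALSE)

  P0 <- window_histograms(st, n, bins, (-pre_bins + 1L):0L) / pre_bins
  P1 <- window_histograms(st, n, bins, 1L:post_bins) / post_bins
  structure(
    list(P0 = P0, P1 = P1, dP = P1 - P0, spike_bins = bins, n_states = n,
         k = k, n_dropped = n_dropped, pre_bins = as.integer(pre_bins),
         post_bins = as.integer(post_bins), fs = states$fs),
    class = "sdo_ensemble"
  )
}

# counts of each state over windows centers+offsets; returns n x k matrix
window_histograms <- function(st, n, centers, offsets) {
  k <- length(centers)
  idx <- rep(centers, times = length(offsets)) +
    rep(offsets, each = k)                       # column-major k x w
  vals <- st[idx]
  bin <- vals + (rep.int(seq_len(k), length(offsets)) - 1L) * n
  matrix(tabulate(bin, nbins = n * k), nrow = n)
}

#' @export
print.sdo_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sdo_ensemble> %d states, %d spikes (%d dropped at boundaries), windows %d/%d bins\n",
    x$n_states, x$k, x$n_dropped, x$pre_bins, x$post_bins))
  invisible(x)
}

new_sdo_matrix <- function(L, form = c("raw", "normalized", "rescaled"),
                           n_spikes = NA_integer_, p0_bar = NULL, h_id = NULL) {
  form <- match.arg(form)
  structure(list(L = unname(as.matrix(L)), form = form,
                 n_spikes = n_spikes, p0_bar = p0_bar, h_id = h_id),
            class = if (is.null(h_id)) "sdo_matrix"
                    else c("sdo_hypothesis", "sdo_matrix"))
}

#' @export
print.sdo_matrix <- function(x, ...) {
  cat(sprintf("<sdo_matrix%s> %dx%d, form '%s', %s spikes\n",
              if (!is.null(x$h_id)) paste0(" ", x$h_id) else "",
              nrow(x$L), ncol(x$L), x$form,
              if (is.na(x$n_spikes)) "?" else x$n_spikes))
  viol <- check_sdo_constraints(x$L)
  if (x$form == "raw" && length(viol)) {
    cat("  constraint violations:", paste(viol, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Direct linear SDO estimator
#'
#' Estimates the stochastic dynamic operator from a perievent ensemble as
#' the spike-average of the per-spike construction
#' `L_s = p(x1)_s p(x0)_s' - diag(p(x0)_s)`, i.e.
#' `L = (1/k) (P1 %*% t(P0) - diag(rowSums(P0)))`. The result satisfies the
#' four SDO constraints for any input distributions: nonpositive diagonal,
#' nonnegative off-diagonal, zero column sums, and per-column positive mass
#' at most 1.
#'
#' @param ens An [perievent_distributions()] ensemble (or any list with
#'   `P0`, `P1` matrices whose columns are probability distributions).
#' @return An `sdo_matrix` in `"raw"` form with `p0_bar` set to the
#'   ensemble-average pre-spike distribution.
#' @examples
#' P0 <- diag(3)[, c(1, 2)]
#' P1 <- diag(3)[, c(2, 3)]
#' estimate_sdo_linear(list(P0 = P0, P1 = P1))$L
#' @export
estimate_sdo_linear <- function(ens) {
  P0 <- ens$P0; P1 <- ens$P1
  k <- ncol(P0)
  stopifnot(k >= 1, nrow(P0) == nrow(P1), ncol(P0) == ncol(P1))
  L <- (P1 %*% t(P0) - diag(rowSums(P0), nrow = nrow(P0))) / k
  new_sdo_matrix(L, form = "raw", n_spikes = k, p0_bar = rowMeans(P0))
}

#' Constrained least-squares SDO estimator
#'
#' Seeks the constraint-satisfying operator minimizing the mean squared
#' prediction error `mean(|| dP_col - L P0_col ||^2)` over spikes, by
#' projected gradient descent (FISTA) over the off-diagonal entries. The
#' diagonal is implied by the zero-column-sum constraint, and each column's
#' off-diagonal mass is projected onto `{w >= 0, sum(w) <= 1}`.
#'
#' The direct linear estimate is used as the starting iterate, so the
#' returned objective is never worse than the linear estimator's.
#'
#' @inheritParams estimate_sdo_linear
#' @param tol Relative objective-improvement tolerance for convergence.
#' @param max_iter Maximum iterations.
#' @return An `sdo_matrix` in `"raw"` form, with attributes `objective`
#'   (final mean squared error), `objective_linear` (at the linear
#'   estimate), and `converged`.
#' @export
estimate_sdo_optim <- function(ens, tol = 1e-10, max_iter = 2000) {
  P0 <- ens$P0; P1 <- ens$P1
  dP <- P1 - P0
  n <- nrow(P0); k <- ncol(P0)
  obj <- function(L) sum((dP - L %*% P0)^2) / k

  off_diag <- function(L) { diag(L) <- 0; L }
  rebuild <- function(W) { diag(W) <- 0; diag(W) <- -colSums(W); W }
  project_cols <- function(W) {
    W <- pmax(W, 0)
    cs <- colSums(W)
    over <- which(cs > 1)
    for (j in over) W[, j] <- simplex_project(W[, j], 1)
    W
  }

  L_lin <- estimate_sdo_linear(ens)$L
  f_lin <- obj(L_lin)
  W <- off_diag(L_lin)
  G0 <- P0 %*% t(P0)
  lip <- 8 * max(1e-12, norm(G0, "2")) / k  # safe bound incl. diagonal coupling
  step <- 1 / lip
  Z <- W; t_acc <- 1; f_prev <- f_lin
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Lz <- rebuild(Z)
    R <- (Lz %*% P0 - dP) %*% t(P0) * (2 / k)   # gradient wrt full L
    Gw <- R - matrix(diag(R), n, n, byrow = TRUE) # chain rule through diagonal
    diag(Gw) <- 0
    W_new <- project_cols(Z - step * Gw)
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    Z <- W_new + ((t_acc - 1) / t_new) * (W_new - W)
    W <- W_new; t_acc <- t_new
    f_cur <- obj(rebuild(W))
    if (it %% 10 == 0) {
      if (abs(f_prev - f_cur) <= tol * max(1, f_prev)) { converged <- TRUE; break }
      f_prev <- f_cur
    }
  }
  L_opt <- rebuild(W)
  f_opt <- obj(L_opt)
  if (f_opt > f_lin) {     # keep the better iterate; flag non-improvement
    warning("constrained optimizer did not improve on the linear estimate",
            call. = FALSE)
    L_opt <- L_lin; f_opt <- f_lin
  }
  if (!converged && f_opt > f_lin + tol) {
    warning("constrained SDO optimizer did not converge; best iterate returned",
            call. = FALSE)
  }
  out <- new_sdo_matrix(L_opt, form = "raw", n_spikes = k,
                        p0_bar = rowMeans(P0))
  attr(out, "objective") <- f_opt
  attr(out, "objective_linear") <- f_lin
  attr(out, "converged") <- converged
  out
}

# Euclidean projection of v onto {w >= 0, sum(w) = s}
simplex_project <- function(v, s = 1) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - s
  rho <- max(which(u - css / seq_along(u) > 0))
  theta <- css[rho] / rho
  pmax(v - theta, 0)
}

#' Check the four SDO operator constraints
#'
#' A valid operator must have (1) nonpositive diagonal, (2) nonnegative
#' off-diagonal, (3) columns summing to zero, and (4) per-column positive
#' mass no greater than 1.
#'
#' @param L A square matrix or `sdo_matrix`.
#' @param tol Numerical tolerance.
#' @return Character vector of violation descriptions; empty if valid.
#' @export
check_sdo_constraints <- function(L, tol = 1e-9) {
  if (inherits(L, "sdo_matrix")) L <- L$L
  stopifnot(is.matrix(L), nrow(L) == ncol(L))
  out <- character()
  if (any(diag(L) > tol)) out <- c(out, "diagonal not nonpositive")
  off <- L; diag(off) <- 0
  if (any(off < -tol)) out <- c(out, "off-diagonal not nonnegative")
  if (any(abs(colSums(L)) > tol)) out <- c(out, "column sums not zero")
  if (any(colSums(pmax(L, 0)) > 1 + tol)) {
    out <- c(out, "per-column positive mass exceeds 1")
  }
  out
}

#' Normalize an SDO to conditional form
#'
#' Scales each column `j` of a raw operator by `1 / p0_bar[j]`, converting
#' the joint-weighted change `dp(x1 = i, x0 = j)` into the conditional
#' change `dp(x1 = i | x0 = j)`. Columns for never-observed input states
#' (`p0_bar[j] = 0`) are set to zero and flagged in the `zero_columns`
#' attribute. The conditional form is the one used for prediction.
#'
#' @param L An `sdo_matrix` in `"raw"` form (or a plain matrix).
#' @param p0_bar Ensemble-average pre-spike distribution; defaults to the
#'   one stored in `L`.
#' @return An `sdo_matrix` in `"normalized"` form.
#' @export
normalize_sdo <- function(L, p0_bar = NULL) {
  obj <- if (inherits(L, "sdo_matrix")) L else new_sdo_matrix(L, "raw")
  if (obj$form != "raw") stop("normalize_sdo expects a raw-form SDO", call. = FALSE)
  p0_bar <- p0_bar %||% obj$p0_bar
  stopifnot(!is.null(p0_bar), length(p0_bar) == ncol(obj$L))
  scale <- ifelse(p0_bar > 0, 1 / p0_bar, 0)
  Ln <- sweep(obj$L, 2, scale, `*`)
  out <- new_sdo_matrix(Ln, form = "normalized", n_spikes = obj$n_spikes,
                        p0_bar = p0_bar, h_id = obj$h_id)
  attr(out, "zero_columns") <- which(p0_bar == 0)
  out
}

#' Rescale a conditional SDO by a target pre-spike distribution
#'
#' Multiplies column `j` of a normalized operator by `p0_target[j]`. Used
#' to place spike-triggered, shuffled and background operators on the
#' common footing of the observed spike-triggered pre-spike distribution
#' before computing similarity statistics. Rescaling by the operator's own
#' `p0_bar` reproduces the raw spike-triggered operator.
#'
#' @param L_norm An `sdo_matrix` in `"normalized"` form.
#' @param p0_target Target pre-spike distribution.
#' @return An `sdo_matrix` in `"rescaled"` form.
#' @export
rescale_sdo <- function(L_norm, p0_target) {
  stopifnot(inherits(L_norm, "sdo_matrix"))
  if (L_norm$form != "normalized") {
    stop("rescale_sdo expects a normalized-form SDO", call. = FALSE)
  }
  stopifnot(length(p0_target) == ncol(L_norm$L))
  Lr <- sweep(L_norm$L, 2, p0_target, `*`)
  new_sdo_matrix(Lr, form = "rescaled", n_spikes = L_norm$n_spikes,
                 p0_bar = p0_target, h_id = L_norm$h_id)
}

#' Predict the post-event state distribution
#'
#' Applies the common update `p_hat(x1) = p(x0) + M p(x0)`. `M` must
#' satisfy the four SDO constraints, which guarantee the result is a valid
#' probability distribution.
#'
#' @param M An `sdo_matrix`/hypothesis matrix (conditional form) or plain
#'   constraint-satisfying matrix.
#' @param p0 Pre-event state distribution (sums to 1).
#' @return Numeric probability vector `p_hat(x1)`.
#' @examples
#' predict_post(h1_null(4), c(0.25, 0.25, 0.25, 0.25))
#' @export
predict_post <- function(M, p0) {
  Lm <- if (inherits(M, "sdo_matrix")) M$L else as.matrix(M)
  viol <- check_sdo_constraints(Lm, tol = 1e-7)
  if (length(viol)) {
    stop("matrix violates SDO constraints: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  p0 <- as.numeric(p0)
  stopifnot(length(p0) == ncol(Lm))
  if (abs(sum(p0) - 1) > 1e-6 || any(p0 < -1e-12)) {
    stop("p0 must be a probability distribution", call. = FALSE)
  }
  p1 <- p0 + drop(Lm %*% p0)
  p1[p1 < 0 & p1 > -1e-9] <- 0
  s <- sum(p1)
  if (abs(s - 1) > 1e-12 && abs(s - 1) <= 1e-9) p1 <- p1 / s
  p1
}

#' Classical least-squares estimate (reference oracle)
#'
#' Solves `L = Rxy %*% solve(Rxx)` with `Rxx = P0 P0'`, `Rxy = dP P0'`.
#' This route is frequently ill-posed (singular `Rxx` whenever the
#' pre-spike distributions do not span all states), in which case a failure
#' flag is returned. It is retained as a small-instance cross-check of the
#' direct linear estimator's residuals, not as a production estimator.
#'
#' @inheritParams estimate_sdo_linear
#' @return A list with `ok` (logical), `L` (matrix or `NULL`), and
#'   `reason` when `ok` is `FALSE`.
#' @export
solve_sdo_lsq_oracle <- function(ens) {
  P0 <- ens$P0; P1 <- ens$P1
  dP <- P1 - P0
  Rxx <- P0 %*% t(P0)
  Rxy <- dP %*% t(P0)
  rc <- rcond(Rxx)
  if (!is.finite(rc) || rc < 1e-10) {
    return(list(ok = FALSE, L = NULL, reason = "singular Rxx"))
  }
  list(ok = TRUE, L = Rxy %*% solve(Rxx), reason = NULL)
}
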