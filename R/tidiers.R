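#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns a tibble of per-component
#' values, `glance()` a one-row model summary.
#'
#' @param x A fitted object (`sdo_matrix`, `sdo_significance`,
#'   `sdo_model_comparison`, `sdo_stirpd`).
#' @param ... Unused.
#' @return A tibble.
#' @name sdo-tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname sdo-tidiers
#' @export
tidy.sdo_matrix <- function(x, ...) {
  n <- nrow(x$L)
  out <- tidyr::expand_grid(x1 = seq_len(n), x0 = seq_len(n))
  out$value <- x$L[cbind(out$x1, out$x0)]
  out
}

#' @rdname sdo-tidiers
#' @export
glance.sdo_matrix <- function(x, ...) {
  viol <- check_sdo_constraints(x$L)
  q <- quiver_summary(x$L)
  tibble::tibble(
    n_states = nrow(x$L), form = x$form, n_spikes = x$n_spikes,
    valid = length(viol) == 0,
    total_up_mass = sum(q$up_mass), total_down_mass = sum(q$down_mass)
  )
}

#' @rdname sdo-tidiers
#' @export
tidy.sdo_significance <- function(x, ...) x$results

#' @rdname sdo-tidiers
#' @export
glance.sdo_significance <- function(x, ...) {
  tibble::tibble(
    n_spikes = x$n_spikes, n_shuffles = x$n_shuffles,
    shuffle_method = x$shuffle_method, alpha = x$alpha,
    n_corrections = x$n_corrections,
    effect_significant = x$effect_significant,
    tuning_significant = x$tuning_significant
  )
}

#' @rdname sdo-tidiers
#' @export
tidy.sdo_model_comparison <- function(x, ...) x$table

#' @rdname sdo-tidiers
#' @export
glance.sdo_model_comparison <- function(x, ...) {
  tibble::tibble(best_state = x$best_state,
                 best_distribution = x$best_distribution, conf = x$conf)
}

#' @rdname sdo-tidiers
#' @export
tidy.sdo_stirpd <- function(x, ...) {
  out <- tidyr::expand_grid(state = seq_len(nrow(x$matrix)),
                            lag = x$lags)
  out$prob <- x$matrix[cbind(out$state, match(out$lag, x$lags))]
  out
}
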