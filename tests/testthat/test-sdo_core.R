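test_that("perievent windows follow the stated indexing convention", {
  # states [1,1,2,2 | spike | 3,3,4,4] with the spike bin as the final
  # pre-window element
  ss <- state_series(c(1, 1, 2, 2, 3, 3, 4, 4), fs = 8, n_states = 4)
  ens <- perievent_distributions(ss, spikes = 4L, pre_bins = 4, post_bins = 4)
  expect_equal(ens$P0[, 1], c(0.5, 0.5, 0, 0))
  expect_equal(ens$P1[, 1], c(0, 0, 0.5, 0.5))
  expect_equal(ens$dP, ens$P1 - ens$P0)
})

test_that("constant state around a spike gives zero distribution change", {
  ss <- state_series(rep(3, 50), fs = 10, n_states = 5)
  ens <- perievent_distributions(ss, spikes = 25L, pre_bins = 10, post_bins = 10)
  expect_equal(ens$P0[, 1], c(0, 0, 1, 0, 0))
  expect_equal(ens$dP[, 1], rep(0, 5))
})

test_that("boundary spikes are dropped and counted", {
  ss <- state_series(rep(1:2, 25), fs = 10, n_states = 2)
  ens <- perievent_distributions(ss, spikes = c(3L, 25L, 49L),
                                 pre_bins = 5, post_bins = 5)
  expect_equal(ens$k, 1L)
  expect_equal(ens$n_dropped, 2L)
  expect_error(perievent_distributions(ss, spikes = 2L, 10, 10), "no spikes")
})

test_that("direct linear estimator equals the brute-force state summation", {
  set.seed(10)
  for (rep in 1:5) {
    ens <- r_ensemble(n = 8, k = 10)
    L <- estimate_sdo_linear(ens)
    expect_equal(L$L, brute_force_sdo(ens$P0, ens$P1), tolerance = 1e-12)
    expect_length(check_sdo_constraints(L), 0)
  }
})

test_that("single-spike estimates follow the outer-product construction", {
  # p0 = e1, p1 = e2: all mass moves from state 1 to state 2
  P0 <- matrix(c(1, 0, 0), 3)
  P1 <- matrix(c(0, 1, 0), 3)
  L <- estimate_sdo_linear(list(P0 = P0, P1 = P1))
  expect_equal(L$L, matrix(c(-1, 1, 0, 0, 0, 0, 0, 0, 0), 3))
  # no change: identical indicator pre/post
  L0 <- estimate_sdo_linear(list(P0 = P0, P1 = P0))
  expect_equal(L0$L, matrix(0, 3, 3))
})

test_that("single-spike estimates satisfy the update equation on binary priors", {
  # exact distribution-change fidelity holds when the prior is an
  # indicator (the outer-product construction); general priors mix the
  # per-state terms and fidelity holds only on average
  set.seed(11)
  for (j in 1:6) {
    p0 <- numeric(6); p0[j] <- 1
    p1 <- r_simplex(6)
    L <- estimate_sdo_linear(list(P0 = cbind(p0), P1 = cbind(p1)))
    expect_equal(drop(L$L %*% p0), p1 - p0, tolerance = 1e-12)
  }
})

test_that("estimation is linear in ensembles (k-weighted average)", {
  set.seed(12)
  a <- r_ensemble(6, 7); b <- r_ensemble(6, 13)
  Lab <- estimate_sdo_linear(list(P0 = cbind(a$P0, b$P0),
                                  P1 = cbind(a$P1, b$P1)))
  La <- estimate_sdo_linear(a); Lb <- estimate_sdo_linear(b)
  expect_equal(Lab$L, (7 * La$L + 13 * Lb$L) / 20, tolerance = 1e-12)
})

test_that("constraint checker flags each violation", {
  expect_length(check_sdo_constraints(matrix(0, 4, 4)), 0)
  bad_diag <- diag(0.5, 3); bad_diag[2, 1] <- -0.5
  v <- check_sdo_constraints(bad_diag)
  expect_true(any(grepl("diagonal", v)))
  expect_true(any(grepl("off-diagonal", v)))
  expect_true(any(grepl("column sums", v)))
  big <- matrix(2, 2, 2); diag(big) <- -2
  expect_true(any(grepl("positive mass", check_sdo_constraints(big))))
})

test_that("estimator outputs pass constraints over a random sweep", {
  set.seed(13)
  for (rep in 1:20) {
    ens <- r_ensemble(n = sample(3:20, 1), k = sample(1:40, 1))
    expect_length(check_sdo_constraints(estimate_sdo_linear(ens)), 0)
  }
})

test_that("normalize/rescale round-trips and handles empty columns", {
  set.seed(14)
  ens <- r_ensemble(10, 20)
  L <- estimate_sdo_linear(ens)
  Ln <- normalize_sdo(L)
  expect_equal(rescale_sdo(Ln, L$p0_bar)$L, L$L, tolerance = 1e-12)
  # uniform p0 -> normalized is n * L
  Lu <- new_sdo <- estimate_sdo_linear(ens)
  Lu$p0_bar <- rep(1 / 10, 10)
  expect_equal(normalize_sdo(Lu)$L, 10 * Lu$L)
  # never-observed input state -> zeroed column, flagged
  L2 <- L; L2$p0_bar[3] <- 0
  Ln2 <- normalize_sdo(L2)
  expect_equal(Ln2$L[, 3], rep(0, 10))
  expect_equal(attr(Ln2, "zero_columns"), 3L)
  # rescaling to an indicator keeps only that column
  Lr <- rescale_sdo(Ln, c(1, rep(0, 9)))
  expect_true(all(Lr$L[, -1] == 0))
})

test_that("prediction conserves probability and honors constraints", {
  set.seed(15)
  for (rep in 1:200) {
    n <- sample(3:15, 1)
    M <- r_valid_sdo(n, mass = runif(1))
    p1 <- predict_post(M, r_simplex(n))
    expect_equal(sum(p1), 1, tolerance = 1e-9)
    expect_true(all(p1 >= 0))
  }
  expect_equal(predict_post(matrix(0, 3, 3), c(0.2, 0.3, 0.5)),
               c(0.2, 0.3, 0.5))
  M <- matrix(c(-1, 1, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_equal(predict_post(M, c(1, 0, 0)), c(0, 1, 0))
  bad <- diag(3)
  expect_error(predict_post(bad, c(1, 0, 0)), "constraints")
})

test_that("constrained optimizer matches or beats the linear estimate", {
  set.seed(16)
  # exactly linear data: dP = A p0 for a valid operator A -> recover A
  n <- 6
  A <- r_valid_sdo(n, 0.6)
  P0 <- replicate(40, r_simplex(n))
  P1 <- P0 + A %*% P0
  ens <- list(P0 = P0, P1 = P1)
  fit <- estimate_sdo_optim(ens, max_iter = 5000)
  expect_lt(attr(fit, "objective"), 1e-8)
  expect_length(check_sdo_constraints(fit$L, tol = 1e-7), 0)

  # generic ensemble: objective never worse than the linear estimator's
  ens2 <- r_ensemble(8, 30)
  fit2 <- estimate_sdo_optim(ens2)
  expect_lte(attr(fit2, "objective"), attr(fit2, "objective_linear") + 1e-10)

  # single binary-prior spike: the outer-product solution is optimal
  p1 <- r_simplex(4)
  ens3 <- list(P0 = cbind(c(1, 0, 0, 0)), P1 = cbind(p1))
  fit3 <- estimate_sdo_optim(ens3, max_iter = 3000)
  lin3 <- estimate_sdo_linear(ens3)
  expect_equal(fit3$L, lin3$L, tolerance = 1e-4)
})

test_that("classical least-squares oracle behaves as documented", {
  set.seed(17)
  n <- 4
  # binary priors covering all states -> invertible, matches construction
  P0 <- diag(n)[, rep(1:n, 3)]
  A <- r_valid_sdo(n, 0.5)
  P1 <- P0 + A %*% P0
  sol <- solve_sdo_lsq_oracle(list(P0 = P0, P1 = P1))
  expect_true(sol$ok)
  expect_equal(sol$L, A, tolerance = 1e-9)

  # identical columns -> singular
  P0c <- matrix(r_simplex(n), n, 6)
  expect_false(solve_sdo_lsq_oracle(list(P0 = P0c, P1 = P0c))$ok)
  # rank-deficient k < n
  ens <- r_ensemble(8, 3)
  expect_false(solve_sdo_lsq_oracle(ens)$ok)
})

test_that("where the oracle succeeds its residual is never worse", {
  set.seed(18)
  n <- 5
  P0 <- diag(n)[, sample(1:n, 60, replace = TRUE)]
  P1 <- replicate(60, r_simplex(n))
  ens <- list(P0 = P0, P1 = P1)
  sol <- solve_sdo_lsq_oracle(ens)
  skip_if_not(sol$ok)
  dP <- P1 - P0
  res <- function(L) sum((dP - L %*% P0)^2)
  expect_lte(res(sol$L), res(estimate_sdo_linear(ens)$L) + 1e-9)
})

test_that("C++ perievent stack agrees with the R reference route", {
  set.seed(19)
  ss <- sine_state_series()
  bins <- sort(sample(200:5800, 80))
  ens <- perievent_distributions(ss, bins, 20, 20)
  L_r <- estimate_sdo_linear(ens)
  stack <- sdotools:::perievent_stack_cpp(ss$states, cbind(as.integer(bins)),
                                          ss$n_states, 20L, 20L)
  expect_equal(matrix(stack$L[, 1], ss$n_states), L_r$L, tolerance = 1e-12)
  expect_equal(stack$p0_bar[, 1], L_r$p0_bar, tolerance = 1e-12)
  expect_equal(stack$k_used[1], ens$k)
})
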