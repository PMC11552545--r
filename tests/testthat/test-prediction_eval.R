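test_that("event-wise predictions follow the common update", {
  set.seed(60)
  n <- 8
  ens <- r_ensemble(n, 30)
  hyps <- list(H1 = h1_null(n), H3 = h3_sta(rowMeans(ens$P1)))
  pred <- predict_all(hyps, ens)
  expect_equal(nrow(pred), 60)
  # H1 predicts the prior: its peak is the prior's peak
  p1 <- pred[pred$hypothesis == "H1", ]
  expect_equal(p1$x1_hat, max.col(t(ens$P0), ties.method = "first"))
  # H3 predicts the same distribution for every spike
  p3 <- pred[pred$hypothesis == "H3", ]
  expect_length(unique(p3$x1_hat), 1)
  # state-count mismatch errors
  expect_error(predict_all(list(H1 = h1_null(5)), ens), "mismatch")
})

test_that("scoring has the stated closed forms and identities", {
  n <- 6
  # perfect prediction: indicator ensembles, null hypothesis
  P <- diag(n)[, c(1, 3, 5)]
  ens <- list(P0 = P, P1 = P)
  pred <- predict_all(list(H1 = h1_null(n)), ens)
  sc <- score_predictions(pred)
  expect_equal(sc$e0, 0); expect_equal(sc$e1, 0); expect_equal(sc$e2, 0)
  expect_lt(sc$kld_mean, 1e-4)

  # uniform prediction vs indicator observation: KLD -> log(n)
  ens2 <- list(P0 = matrix(1 / n, n, 1), P1 = cbind(c(1, rep(0, n - 1))))
  pred2 <- predict_all(list(H1 = h1_null(n)), ens2)
  expect_equal(pred2$kld, log(n), tolerance = 1e-2)
  expect_equal(pred2$loglik, log(1 / n), tolerance = 1e-2)

  # e2 is the square of e1, spike-wise
  set.seed(61)
  ens3 <- r_ensemble(n, 25)
  pred3 <- predict_all(list(H1 = h1_null(n)), ens3)
  expect_equal(pred3$e2, pred3$e1^2)
})

test_that("cumulative squared error obeys the Cauchy-Schwarz bound", {
  set.seed(62)
  ens <- r_ensemble(10, 40)
  pred <- predict_all(list(H2 = h2_diffusion(10)), ens)
  sc <- score_predictions(pred)
  expect_gte(sc$e2, sc$e1^2 / sc$k)
})

test_that("the fitted spike operator beats the null on its training set", {
  set.seed(63)
  ss <- sine_state_series()
  sp <- sort(sample(300L:5700L, 150))
  ens <- perievent_distributions(ss, sp, 15, 15)
  hyps <- list(H1 = h1_null(ss$n_states), H7 = h7_spike_sdo(ens))
  sc <- score_predictions(predict_all(hyps, ens))
  expect_lte(sc$kld_mean[sc$hypothesis == "H7"],
             sc$kld_mean[sc$hypothesis == "H1"])
})

test_that("bootstrap confidence intervals behave and reproduce", {
  # constant errors: a degenerate interval at c * k
  ci <- bootstrap_ci(rep(2, 50), n_boot = 100)
  expect_equal(ci$estimate, 100)
  expect_equal(ci$lower, 100); expect_equal(ci$upper, 100)
  # relative width shrinks roughly as 1/sqrt(k)
  set.seed(64)
  e_small <- rpois(100, 2); e_big <- rpois(1600, 2)
  w <- function(e) { ci <- bootstrap_ci(e, 400)
    (ci$upper - ci$lower) / ci$estimate }
  expect_gt(w(e_small), 2 * w(e_big))
  set.seed(65); a <- bootstrap_ci(e_small, 200)
  set.seed(65); b <- bootstrap_ci(e_small, 200)
  expect_identical(a, b)
  expect_error(bootstrap_ci(1), "k >= 2")
})

test_that("Cohen's d matches hand arithmetic and edge cases", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # means differ by one pooled SD
  a <- c(0, 1, -1, 2, -2); b <- a + sd(a)
  expect_equal(abs(cohens_d(a, b)), 1, tolerance = 1e-12)
  # hand computation on 3-point samples
  a3 <- c(1, 2, 3); b3 <- c(2, 4, 6)
  pooled <- sqrt((2 * var(a3) + 2 * var(b3)) / 4)
  expect_equal(cohens_d(a3, b3), (2 - 4) / pooled)
  expect_true(is.infinite(cohens_d(c(1, 1), c(2, 2))))
})

test_that("model comparison picks minimizers and reports overlap", {
  set.seed(66)
  ss <- sine_state_series()
  sp <- sort(sample(300L:5700L, 200))
  ens <- perievent_distributions(ss, sp, 15, 15)
  hyps <- fit_hypotheses(ss, ens)
  pred <- predict_all(hyps[c("H1", "H3", "H7")], ens)
  cmp <- compare_models(pred, n_boot = 300)
  expect_equal(cmp$best_state,
               cmp$table$hypothesis[which.min(cmp$table$e1)])
  expect_true(all(diag(cmp$overlap)))
  expect_equal(nrow(cmp$cohens_d), 3)
  # single hypothesis: trivially best
  cmp1 <- compare_models(predict_all(hyps["H1"], ens), n_boot = 50)
  expect_equal(cmp1$best_state, "H1")
})

test_that("train/test splits are disjoint and exhaustive", {
  set.seed(67)
  ss <- sine_state_series()
  ens <- perievent_distributions(ss, sort(sample(300L:5700L, 100)), 15, 15)
  sp <- split_ensemble(ens, train_frac = 0.4)
  expect_equal(sp$train$k, 40)
  expect_equal(sp$test$k, 60)
  expect_length(intersect(sp$train$spike_bins, sp$test$spike_bins), 0)
  expect_setequal(c(sp$train$spike_bins, sp$test$spike_bins), ens$spike_bins)
})

test_that("on state-independent data the operator matches the STA model", {
  # post distribution independent of pre: H7 converges to H3's prediction
  set.seed(68)
  n <- 6
  base <- r_simplex(n)
  k <- 4000
  P0 <- replicate(k, r_simplex(n))
  draws <- sample(n, k, replace = TRUE, prob = base)
  P1 <- diag(n)[, draws]
  ens <- list(P0 = P0, P1 = P1)
  h7 <- h7_spike_sdo(ens)
  h3 <- h3_sta(rowMeans(P1))
  p0 <- r_simplex(n)
  expect_equal(predict_post(h7, p0), predict_post(h3, p0), tolerance = 0.1)
})
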