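test_that("H1 is the identity map and vacuously valid", {
  h <- h1_null(6)
  expect_length(check_sdo_constraints(h$L), 0)
  p <- r_simplex(6)
  expect_equal(predict_post(h, p), p)
})

test_that("H2 diffuses symmetrically and raises variance", {
  h <- h2_diffusion(20, sigma = 1.5)
  expect_length(check_sdo_constraints(h$L, tol = 1e-9), 0)
  # tiny kernel collapses toward the null
  h_small <- h2_diffusion(20, sigma = 1e-3)
  expect_lt(max(abs(h_small$L)), 1e-6)
  # indicator at the center spreads symmetrically
  p <- numeric(20); p[10] <- 1
  out <- predict_post(h, p)
  expect_equal(out[10 + 1:5], out[10 - 1:5], tolerance = 1e-9)
  # variance grows, mean fixed, for interior mass
  set.seed(20)
  p2 <- numeric(20); p2[8:12] <- r_simplex(5)
  out2 <- predict_post(h, p2)
  m <- function(p) sum(p * seq_along(p))
  v <- function(p) sum(p * seq_along(p)^2) - m(p)^2
  expect_equal(m(out2), m(p2), tolerance = 1e-6)
  expect_gt(v(out2), v(p2))
})

test_that("H3 maps every prior to the mean post-spike distribution", {
  set.seed(21)
  P1_bar <- r_simplex(10)
  h <- h3_sta(P1_bar)
  expect_length(check_sdo_constraints(h$L), 0)
  for (rep in 1:5) {
    expect_equal(predict_post(h, r_simplex(10)), P1_bar, tolerance = 1e-12)
  }
  # the mean itself is a fixed point
  expect_equal(predict_post(h, P1_bar), P1_bar, tolerance = 1e-12)
})

test_that("H4 background operator reflects signal dynamics", {
  ss_const <- state_series(rep(4, 200), fs = 100, n_states = 8)
  h0 <- h4_background(ss_const, 10, 10)
  expect_equal(h0$L, matrix(0, 8, 8))

  # i.i.d. uniform states: near-symmetric up/down mass
  set.seed(22)
  ss <- state_series(sample(1:10, 20000, replace = TRUE), fs = 1000,
                     n_states = 10)
  h <- h4_background(ss, 10, 10)
  q <- quiver_summary(h$L)
  expect_equal(sum(q$up_mass), sum(q$down_mass), tolerance = 0.05)
  expect_length(check_sdo_constraints(h$L, tol = 1e-9), 0)
})

test_that("H4 on stabilizing dynamics pushes above-setpoint states down", {
  set.seed(23)
  sp <- gen_spike_train(100, 10, 1000)
  spec <- generator_spec("Y4", fs = 1000, duration = 10)
  real <- simulate_generator(spec, sp)
  ss <- quantize(real$signal, build_quantizer(real$signal, 20))
  h <- h4_background(ss, 20, 20)
  q <- quiver_summary(normalize_sdo(estimate_sdo_linear(
    perievent_distributions(ss, seq(20, 9980), 20, 20)))$L)
  hi <- q$state >= 15 & (q$up_mass + q$down_mass) > 0
  expect_true(all((q$up_mass - q$down_mass)[hi] < 0))
})

test_that("H5 averages Markov transition powers correctly", {
  # M0 = I -> change operator is zero
  ss <- state_series(rep(2, 100), fs = 10, n_states = 3)
  ens <- perievent_distributions(ss, spikes = c(30L, 60L), 10, 10)
  h <- h5_markov(ss, ens)
  expect_equal(h$L, matrix(0, 3, 3))

  # 2-state alternator: averaged over T = 2 gives the uniform mixer
  M0 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(sdotools:::markov_window_average(M0, 2),
               matrix(0.5, 2, 2))

  # random 5-state chain vs term-by-term power sum
  set.seed(24)
  C <- matrix(rexp(25), 5)
  M0 <- sweep(C, 2, colSums(C), `/`)
  acc <- M0 %*% diag(5)
  P <- M0
  for (t in 2:4) { P <- M0 %*% P; acc <- acc + P }
  expect_equal(sdotools:::markov_window_average(M0, 4), acc / 4,
               tolerance = 1e-12)
  # columns of the averaged matrix each sum to 1
  expect_equal(colSums(sdotools:::markov_window_average(M0, 4)), rep(1, 5))
})

test_that("H5 estimated from data satisfies constraints and conventions", {
  set.seed(25)
  ss <- sine_state_series()
  bins <- sort(sample(200L:5800L, 60))
  ens <- perievent_distributions(ss, bins, 20, 20)
  h <- h5_markov(ss, ens)
  expect_length(check_sdo_constraints(h$L, tol = 1e-9), 0)
})

test_that("H6 combines background and mean shift as specified", {
  set.seed(26)
  LB <- h4_background(sine_state_series(), 10, 10)
  n <- nrow(LB$L)
  # zero mean-shift: identical to H4
  h0 <- h6_background_plus_sta(LB, rep(0, n))
  expect_equal(h0$L, LB$L, tolerance = 1e-9)
  # zero background: prediction is p0 + dP_bar up to the logged
  # constraint-repair magnitude (the rank-one term generically violates
  # off-diagonal nonnegativity and is clipped back)
  dp <- r_simplex(n) - r_simplex(n)
  hz <- h6_background_plus_sta(h1_null(n), dp)
  p0 <- r_simplex(n)
  expect_lte(sum(abs(predict_post(hz, p0) - (p0 + dp))),
             attr(hz, "repair_l1") + 1e-9)
  expect_length(check_sdo_constraints(hz$L, tol = 1e-7), 0)
})

test_that("H7 equals the direct linear estimate in conditional form", {
  set.seed(27)
  ss <- sine_state_series()
  bins <- sort(sample(200L:5800L, 50))
  ens <- perievent_distributions(ss, bins, 20, 20)
  h <- h7_spike_sdo(ens)
  expect_identical(h$L, normalize_sdo(estimate_sdo_linear(ens))$L)
})

test_that("all seven fitted hypotheses satisfy the operator constraints", {
  set.seed(28)
  ss <- sine_state_series()
  sp <- sort(sample(200L:5800L, 80))
  hyps <- fit_hypotheses(ss, sp, 15, 15)
  expect_named(hyps, paste0("H", 1:7))
  for (h in hyps) expect_length(check_sdo_constraints(h$L, tol = 1e-7), 0)
})

test_that("H3 predictions are constant in the prior; H7's are not", {
  set.seed(29)
  ss <- sine_state_series()
  sp <- sort(sample(200L:5800L, 120))
  hyps <- fit_hypotheses(ss, sp, 15, 15)
  ens <- attr(hyps, "ensemble")
  pred3 <- hyps$H3$L %*% ens$P0 + ens$P0
  expect_lt(max(apply(pred3, 1, var)), 1e-20)
  pred7 <- hyps$H7$L %*% ens$P0 + ens$P0
  expect_gt(max(apply(pred7, 1, var)), 1e-6)
})
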