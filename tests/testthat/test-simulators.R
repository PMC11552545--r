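test_that("spike trains respect bounds, gaps and rate", {
  expect_equal(gen_spike_train(0)$k, 0L)
  set.seed(50)
  tr <- gen_spike_train(500, duration = 60, fs = 2000, min_gap = 0.01)
  expect_equal(tr$k, 500)
  expect_true(all(tr$times > 0 & tr$times < 60))
  expect_true(all(diff(tr$times) >= 0.01 - 1e-9))
  expect_error(gen_spike_train(10000, duration = 10, fs = 2000,
                               min_gap = 0.01), "infeasible")
  # average rate over seeds is n / duration
  rates <- vapply(1:30, function(i) {
    mean(gen_spike_train(200, 30, 2000)$times) }, numeric(1))
  expect_equal(mean(rates), 15, tolerance = 1)
})

test_that("stabilizing dynamics converge geometrically without noise", {
  # start away from the fixed point with no drive: |y[t]| = (1-k)^t |y0|
  y1 <- rep(5, 100)   # constant drive differential = 0, start at 5
  y <- sdotools:::stabilized_series(y1, k = 0.1, x0 = 0)
  expect_equal(y, 5 * (1 - 0.1)^(0:99), tolerance = 1e-12)
  y2 <- sdotools:::stabilized_series(rep(2, 50), k = 0.3, x0 = 2)
  expect_equal(y2[50], 2, tolerance = 1e-9)
})

test_that("the Markov kernel is column-stochastic and near-diagonal", {
  P <- markov_kernel_matrix(100, 2)
  expect_equal(colSums(P), rep(1, 100), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_gt(min(diag(P)), 0.15)
})

test_that("generator invariants: stationarity and spike-effect locality", {
  set.seed(51)
  sp <- gen_spike_train(300, 30, 2000)
  long_mean <- function(g) {
    mean(simulate_generator(generator_spec(g, duration = 30), sp)$signal$samples)
  }
  expect_lt(abs(long_mean("Y1")), 0.05)
  expect_lt(abs(long_mean("Y8")), 0.2)
  expect_lt(abs(long_mean("Y5")), 3)

  # Y2's statistics outside the effect windows match background noise
  real <- simulate_generator(generator_spec("Y2", duration = 30), sp)
  bins <- sdotools:::spike_bins(sp, 2000)
  w <- unique(unlist(lapply(bins, function(s) s + 1:20)))
  outside <- setdiff(seq_len(60000), unlist(lapply(bins, function(s) s + 0:25)))
  expect_gt(sd(real$signal$samples[w]), 2 * sd(real$signal$samples[outside]))
  expect_lt(abs(mean(real$signal$samples[outside])), 0.05)
})

test_that("Y3's post-spike mean shift equals the injected impulse mean", {
  set.seed(52)
  sp <- gen_spike_train(600, 60, 2000)
  spec <- generator_spec("Y3")
  real <- simulate_generator(spec, sp)
  bins <- sdotools:::spike_bins(sp, 2000)
  post <- rowMeans(matrix(real$signal$samples[
    rep(bins, each = 20) + rep(1:20, times = 600)], nrow = 600, byrow = TRUE))
  pre <- rowMeans(matrix(real$signal$samples[
    rep(bins, each = 20) - rep(19:0, times = 600)], nrow = 600, byrow = TRUE))
  # injected half-sine has mean peak * mean(sin(pi * (1:20) / 21)), with
  # peak scaled by the realization's background SD (estimated away from
  # the effect windows)
  shape_mean <- mean(sin(pi * seq_len(20) / 21))
  outside <- setdiff(seq_len(120000),
                     unlist(lapply(bins, function(s) s + 0:25)))
  bg_sd <- sd(real$signal$samples[outside])
  expect_equal(mean(post - pre) / (spec$impulse_peak * bg_sd * shape_mean),
               1, tolerance = 0.15)
})

test_that("Y7 pulls post-spike windows toward the spike set point", {
  set.seed(53)
  sp <- gen_spike_train(500, 60, 2000)
  spec <- generator_spec("Y7", k_spike = 0.3, x0_spike = 1)
  real <- simulate_generator(spec, sp)
  y <- real$signal$samples
  bins <- sdotools:::spike_bins(sp, 2000)
  in_w <- unlist(lapply(bins, function(s) s + 1:20))
  matched <- unlist(lapply(bins, function(s) s - 60:41))  # pre-spike control
  expect_gt(mean(y[in_w]), mean(y[matched]))
})

test_that("ARMA branch validates stationarity and mean-levels", {
  expect_error(generator_spec("Y8", ar = c(1.2, 0, 0)), "stationary")
  set.seed(54)
  sp <- gen_spike_train(50, 10, 2000)
  real <- simulate_generator(generator_spec("Y8", duration = 10), sp)
  expect_equal(mean(real$signal$samples), 0, tolerance = 1e-9)
})

test_that("the validation study returns a tidy, reproducible table", {
  set.seed(55)
  res <- run_validation_study(n_sims = 2, generators = c("Y1", "Y3"),
                              n_spikes = 120, n_shuffles = 40,
                              spec_overrides = list(duration = 15))
  expect_true(all(c("sim", "gen_id", "basis", "test", "significant",
                    "truth", "correct") %in% names(res)))
  expect_setequal(unique(res$gen_id), c("Y1", "Y3"))
  expect_true(all(res$truth[res$gen_id == "Y3"]))
  expect_false(any(res$truth[res$gen_id == "Y1"]))
  # STA rows are not analyzed below the 500-spike floor; SDO rows are
  expect_true(all(is.na(res$significant[res$basis == "STA"])))
  expect_true(all(!is.na(res$significant[res$basis == "SDO"])))
  set.seed(55)
  res2 <- run_validation_study(n_sims = 2, generators = c("Y1", "Y3"),
                               n_spikes = 120, n_shuffles = 40,
                               spec_overrides = list(duration = 15))
  expect_identical(res, res2)
})
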