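test_that("scenario validation rejects impossible designs", {
  expect_error(trial_scenario("continuous", 1, 0.5), "n_per_arm")
  expect_error(trial_scenario("continuous", 50, 0.5, sd_outcome = 0), "positive")
  expect_error(trial_scenario("binary", 50, 0.5), "control_rate")
  expect_error(trial_scenario("binary", 50, 0.5, control_rate = 1.2),
               "control_rate")
})

test_that("simulated summaries are reproducible and well-formed", {
  scn <- trial_scenario("continuous", 50, 0, sd_outcome = 1)
  a <- simulate_trial_summary(scn, seed = 123)
  b <- simulate_trial_summary(scn, seed = 123)
  expect_identical(a$value, b$value)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
  # null sampling: the estimate is within a few SEs of zero
  expect_lt(abs(a$value), 4 * a$se)

  bscn <- trial_scenario("binary", 200, 0, control_rate = 0.3)
  bs <- simulate_trial_summary(bscn, seed = 5)
  expect_identical(attr(bs, "resamples"), 0L)
  # log-OR estimates are centred near 0 under the null
  set.seed(99)
  reps <- replicate(300, simulate_trial_summary(bscn)$value)
  expect_lt(abs(mean(reps)), 0.05)
})

test_that("a very large trial recovers the true mean difference", {
  scn <- trial_scenario("continuous", 1e6, 0.5, sd_outcome = 1)
  est <- simulate_trial_summary(scn, seed = 7)
  expect_lt(abs(est$value - 0.5), 0.01)
})

test_that("operating characteristics partition the simulation runs", {
  scn <- trial_scenario("continuous", 100, 0.2, sd_outcome = 1)
  oc <- operating_characteristics(scn, prior_halfnormal(0.3),
                                  n_reps = 300, seed = 2)
  expect_equal(oc$p_bf_above_3 + oc$p_bf_below_third + oc$p_insensitive, 1,
               tolerance = 1e-12)
  expect_length(oc$bf, 300)
  oc2 <- operating_characteristics(scn, prior_halfnormal(0.3),
                                   n_reps = 300, seed = 2)
  expect_identical(oc$bf, oc2$bf)
  expect_error(operating_characteristics(scn, prior_halfnormal(0.3),
                                         n_reps = 0), "at least 100")
})

test_that("under the null, futility crossings dominate and the median BF is below 1", {
  scn <- trial_scenario("continuous", 500, 0, sd_outcome = 1)
  # typical SE ~ sqrt(2/500) ~ 0.063; prior sd well above 2x that
  oc <- operating_characteristics(scn, prior_halfnormal(0.5),
                                  n_reps = 2000, seed = 31)
  expect_gt(oc$p_bf_below_third, oc$p_bf_above_3)
  expect_lt(median(oc$bf), 1)
})

test_that("with a true effect at the prior scale, evidence accumulates with n", {
  prior <- prior_halfnormal(0.5)
  oc_small <- operating_characteristics(
    trial_scenario("continuous", 50, 0.5), prior, n_reps = 400, seed = 8)
  oc_big <- operating_characteristics(
    trial_scenario("continuous", 400, 0.5), prior, n_reps = 400, seed = 8)
  expect_gt(oc_big$p_bf_above_3, oc_small$p_bf_above_3)
  expect_gt(oc_big$p_bf_above_3, 0.95)
})

test_that("sequential monitoring stops for the right reasons", {
  prior <- prior_halfnormal(1)
  # strong true effect: most runs stop early for efficacy
  eff <- vapply(1:40, function(s)
    sequential_bf_monitor(trial_scenario("continuous", 2, 1), prior,
                          batch = 25, max_n = 200, seed = s)$stop_reason,
    character(1))
  expect_gt(mean(eff == "efficacy"), 0.5)
  # null effect: futility stops dominate efficacy stops
  nul <- vapply(1:40, function(s)
    sequential_bf_monitor(trial_scenario("continuous", 2, 0), prior,
                          batch = 50, max_n = 500, seed = s)$stop_reason,
    character(1))
  expect_gt(sum(nul == "futility"), sum(nul == "efficacy"))
})

test_that("a single-batch schedule takes exactly one look", {
  res <- sequential_bf_monitor(trial_scenario("continuous", 2, 0.5),
                               prior_halfnormal(0.5), batch = 30, max_n = 30,
                               seed = 4)
  expect_identical(nrow(res$looks), 1L)
  expect_identical(res$n_at_stop, 30)
  res2 <- sequential_bf_monitor(trial_scenario("continuous", 2, 0.5),
                                prior_halfnormal(0.5), batch = 30, max_n = 30,
                                seed = 4)
  expect_identical(res$looks, res2$looks)
  expect_error(sequential_bf_monitor(trial_scenario("continuous", 2, 0),
                                     prior_halfnormal(1), batch = 10,
                                     max_n = 5), "at least batch")
})

test_that("binary sequential monitoring handles early zero-cell looks", {
  res <- sequential_bf_monitor(
    trial_scenario("binary", 2, log(3), control_rate = 0.05),
    prior_halfnormal(log(3)), batch = 10, max_n = 400, seed = 21)
  expect_true(res$stop_reason %in% c("efficacy", "futility", "max_n"))
  expect_true(all(is.finite(res$looks$bf)))
})
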