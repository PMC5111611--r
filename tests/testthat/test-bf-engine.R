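test_that("likelihood at the null is the normal density of the estimate", {
  expect_equal(likelihood_at_null(effect_estimate(0, 1)), 0.3989423,
               tolerance = 1e-6)
  expect_equal(likelihood_at_null(1.00, 0.56), 0.1446399, tolerance = 1e-6)
  expect_equal(likelihood_at_null(4.82, 2.23), 0.0173036, tolerance = 1e-5)
  expect_error(likelihood_at_null(1, 0), "se")
  expect_error(likelihood_at_null(1, -2), "se")
})

test_that("half-normal closed form matches its frozen values", {
  expect_equal(bf_halfnormal_closed(1.4, sd = 4.97, se = 0.49), 11.15230,
               tolerance = 1e-4)
  # observed effect at the null collapses to se / sqrt(se^2 + sd^2)
  expect_equal(bf_halfnormal_closed(0, sd = 1, se = 1), 0.70711,
               tolerance = 1e-5)
  expect_equal(bf_halfnormal_closed(0.058269, sd = 0.652325, se = 0.15),
               0.3118, tolerance = 1e-3)
})

test_that("quadrature reproduces the published half-normal Bayes factors", {
  cases <- list(list(v = 1.00, se = 0.56, sd = 4.65, bf = 1.1),
                list(v = 4.82, se = 2.23, sd = 4.65, bf = 5.6),
                list(v = 20.20, se = 5.74, sd = 8.00, bf = 69.8))
  for (cs in cases) {
    res <- bayes_factor(effect_estimate(cs$v, cs$se, oriented = TRUE),
                        prior_halfnormal(cs$sd))
    expect_equal(res$bf, cs$bf, tolerance = 0.01)
    expect_equal(res$bf, res$numerator / res$denominator)
    expect_identical(res$method, "quadrature")
  }
})

test_that("quadrature and closed-form half-normal agree over random triples", {
  tr <- random_triples(1000, seed = 42)
  for (i in seq_len(nrow(tr))) {
    est <- effect_estimate(tr$value[i], tr$se[i], oriented = TRUE)
    q <- bayes_factor(est, prior_halfnormal(tr$sd[i]))$log_bf
    cf <- bf_halfnormal_closed(est, tr$sd[i], log = TRUE)
    # |BF_q/BF_cf - 1|, evaluated in logs so it stays defined when the BF
    # itself exceeds double range
    expect_lt(abs(expm1(q - cf)), 1e-6)
  }
})

test_that("the Bayes factor is invariant under common rescaling", {
  base <- bf_halfnormal_closed(1.7, sd = 2.3, se = 0.8)
  for (c_ in c(1e-3, 0.5, 7, 1e4)) {
    scaled_cf <- bf_halfnormal_closed(1.7 * c_, sd = 2.3 * c_, se = 0.8 * c_)
    scaled_q <- bayes_factor(
      effect_estimate(1.7 * c_, 0.8 * c_, oriented = TRUE),
      prior_halfnormal(2.3 * c_))$bf
    expect_lt(abs(scaled_cf - base) / base, 1e-9)
    expect_lt(abs(scaled_q - base) / base, 1e-6)
  }
  u <- bf_uniform_closed(2, 0, 4, se = 1)
  expect_lt(abs(bf_uniform_closed(20, 0, 40, se = 10) - u) / u, 1e-9)
})

test_that("a vanishing prior SD pulls the Bayes factor to 1", {
  est <- effect_estimate(0.8, 1.3, oriented = TRUE)
  bfs <- vapply(c(1e-2, 1e-4, 1e-6),
                function(s) bayes_factor(est, prior_halfnormal(s))$bf,
                numeric(1))
  expect_true(all(diff(abs(bfs - 1)) < 0))
  expect_lt(abs(bfs[3] - 1), 1e-5)
})

test_that("the half-normal BF increases with the oriented effect", {
  vals <- seq(0, 5, by = 0.25)
  bfs <- vapply(vals, function(v) bf_halfnormal_closed(v, sd = 2, se = 1),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  # and equals se/sqrt(se^2+sd^2) exactly at the null point
  expect_equal(bf_halfnormal_closed(0, sd = 2, se = 1), 1 / sqrt(5), tolerance = 1e-14)
})

test_that("uniform-prior Bayes factors match the closed form", {
  expect_equal(bf_uniform_closed(2, 0, 4, se = 1), 4.41972, tolerance = 1e-5)
  expect_equal(bf_uniform_closed(0, 0, 2, se = 1), 0.59816, tolerance = 1e-4)
  # symmetric prior around a null-centred observation: BF < 1, -> 1 as a -> 0
  a <- c(2, 1, 0.1, 0.001)
  bfs <- vapply(a, function(x) bf_uniform_closed(0, -x, x, se = 1), numeric(1))
  expect_true(all(bfs < 1))
  expect_true(all(diff(bfs) > 0))
  expect_lt(abs(bfs[4] - 1), 1e-6)
  # quadrature path agrees
  for (x in list(c(2, 0, 4), c(0, 0, 2), c(-1, -3, 5))) {
    q <- bayes_factor(effect_estimate(x[1], 1), prior_uniform(x[2], x[3]))$bf
    expect_equal(q, bf_uniform_closed(x[1], x[2], x[3], se = 1),
                 tolerance = 1e-8)
  }
})

test_that("normal-prior quadrature matches the convolution closed form", {
  set.seed(7)
  for (i in 1:25) {
    v <- rnorm(1); se <- runif(1, 0.1, 3); m <- rnorm(1); s <- runif(1, 0.1, 3)
    q <- bayes_factor(effect_estimate(v, se), prior_normal(m, s))$bf
    cf <- dnorm(v, m, sqrt(se^2 + s^2)) / dnorm(v, 0, se)
    expect_equal(q, cf, tolerance = 1e-7)
  }
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(effect_estimate(1, 0), "se")
  expect_error(effect_estimate(-1, 1, oriented = TRUE), "oriented")
  expect_error(prior_halfnormal(0), "sd")
  expect_error(prior_uniform(2, 2), "upper > lower")
  expect_error(bayes_factor(effect_estimate(1, 1), "not a prior"), "prior")
  # half-normal requires an oriented estimate
  expect_error(bayes_factor(effect_estimate(1, 1), prior_halfnormal(1)),
               "oriented")
})
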