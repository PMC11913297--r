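# Importance weights, ACE, normalizing-constant estimators, CIC arithmetic.

test_that("importance weights follow r / q and flag degenerate input", {
  expect_equal(importance_weights(c(2, 2), c(0, 0)), c(2, 2))
  expect_error(importance_weights(c(-1, 1), c(0, 0)), class = "cic_invalid_target")
  expect_error(importance_weights(c(0, 0), c(0, 0)), class = "cic_degenerate_support")
  # sampling from the normalized target itself gives constant weights = rho
  qs <- two_comp_params()
  tgt <- make_gmm_target(qs, rho = 7)
  X <- rgmm(qs, 200, 5)
  w <- importance_weights(target_eval(tgt, X), dgmm(qs, X))
  expect_equal(w, rep(7, 200), tolerance = 1e-12)
})

test_that("stage records store weights consistent with r and the proposal", {
  prop <- wide_proposal_1d()
  tgt <- make_gmm_target(two_comp_params(), 3)
  arch <- one_stage_archive(tgt, prop, 300, 11)
  st <- arch$stages[[1]]
  expect_equal(st$weights, st$r_values * exp(-st$proposal_log_density),
               tolerance = 1e-12)
  expect_error(add_stage(arch, stage_record(st$points, st$r_values,
                                            st$proposal_log_density, 5L)),
               class = "cic_invalid_argument")
})

test_that("single-point and zero-log-density ACE values are exact", {
  # one point at the standard normal mode with weight 2: ACE = log(2*pi)
  st <- stage_record(matrix(0), 2 * dnorm(0), dnorm(0, log = TRUE), 0L)
  arch <- add_stage(sample_archive(list(), 1), st)
  expect_equal(ace(arch, gmm_params(1, 0, 1)), log(2 * pi), tolerance = 1e-12)
  # candidate with log-density zero at every point scores zero whatever the
  # weights: N(0, 1/(2*pi)) has log-density 0 at its mode
  cand <- gmm_params(1, 0, 1 / (2 * pi))
  st2 <- stage_record(matrix(c(0, 0)), c(3, 5), c(0, 0), 0L)
  arch2 <- add_stage(sample_archive(list(), 1), st2)
  expect_equal(ace(arch2, cand), 0, tolerance = 1e-12)
})

test_that("ACE estimates the quadrature cross-entropy within Monte-Carlo error", {
  prop <- gmm_params(1, 0, 1)
  tgt <- make_gmm_target(gmm_params(1, 0, 1), rho = 2)
  cand <- gmm_params(1, 0.3, 1.2)
  arch <- one_stage_archive(tgt, prop, 200, 21)
  est <- ace(arch, cand)
  truth <- quad_cross_entropy(function(x) 2 * dnorm(x), cand)
  st <- arch$stages[[1]]
  se <- sd(-st$weights * dgmm(cand, st$points)) / sqrt(st$n)
  expect_lt(abs(est - truth), 4 * se)
})

test_that("ACE returns +Inf when a candidate misses positively weighted support", {
  st <- stage_record(matrix(c(0, 1e200)), c(1, 1), c(0, 0), 0L)
  arch <- add_stage(sample_archive(list(), 1), st)
  expect_identical(ace(arch, gmm_params(1, 0, 1)), Inf)
})

test_that("normalizing-constant estimator pools stages per the exclusion rule", {
  mk <- function(w, s) stage_record(matrix(seq_along(w)), w, rep(0, length(w)), s)
  arch1 <- add_stage(sample_archive(list(), 1), mk(c(3, 3, 3), 0L))
  expect_identical(rho_hat(arch1), 3)
  arch2 <- add_stage(sample_archive(list(), 1), mk(c(1, 3), 0L))
  expect_identical(rho_hat(arch2), 2)
  arch3 <- add_stage(add_stage(sample_archive(list(), 1), mk(c(10, 10), 0L)),
                     mk(c(2, 2), 1L))
  expect_identical(rho_hat(arch3, include_initial = FALSE), 2)
  expect_equal(rho_hat(arch3, include_initial = TRUE), 6)
})

test_that("rho_hat has zero variance when the proposal equals the target", {
  qs <- two_comp_params()
  tgt <- make_gmm_target(qs, rho = 3)
  for (seed in 1:5) {
    arch <- one_stage_archive(tgt, qs, 100, seed)
    expect_equal(rho_hat(arch), 3, tolerance = 1e-13)
  }
})

test_that("CIC arithmetic penalizes dimension at rate rho/n", {
  expect_equal(cic_value(1.0, 2.0, 5, 100), 1.1)
  expect_equal(cic_value(0.7, 2.0, 0, 100), 0.7)
  for (a in c(-2, 0, 3.5)) {
    expect_equal(cic_value(a, 1.8, 17, 1000), a + 0.017 * 1.8, tolerance = 1e-14)
  }
  vals <- vapply(0:10, function(d) cic_value(1, 2, d, 50), 0)
  expect_true(all(diff(vals) > 0))
  expect_error(cic_value(1, 0, 2, 10), class = "cic_invalid_argument")
  expect_error(cic_value(1, -1, 2, 10), class = "cic_invalid_argument")
})

test_that("effective sample size follows the (sum w)^2 / sum w^2 formula", {
  expect_equal(ess(rep(0.37, 10)), 10)
  expect_equal(ess(c(1, 0, 0, 0)), 1)
  expect_equal(ess(c(1, 1, 2)), 16 / 6)
  expect_error(ess(c(0, 0)), class = "cic_degenerate_support")
})
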