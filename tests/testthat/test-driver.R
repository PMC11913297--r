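# Iterative driver: staging, CIC-based selection, end-to-end bookkeeping.

test_that("dimension selection minimizes the CIC with small-k tie-breaks", {
  expect_identical(select_dimension(c(`1` = 3.0, `2` = 2.0, `3` = 2.5)), 2L)
  expect_identical(select_dimension(c(`1` = 2.0, `2` = 2.0)), 1L)
  expect_identical(select_dimension(c(`1` = Inf, `2` = 1.0)), 2L)
  expect_error(select_dimension(c(`1` = Inf, `2` = Inf)), class = "cic_fit_failed")
})

test_that("each stage adds exactly n rows and n target evaluations", {
  tgt <- make_gmm_target(two_comp_params(), 3)
  cfg <- run_config(wide_proposal_1d(), tau = 2, n_initial = 150, n_stage = 120,
                    k_grid = 1:2, seed = 3)
  arch <- sample_archive(list(), 1)
  s1 <- run_stage(tgt, arch, cfg$initial_params, cfg, 1)
  expect_identical(length(s1$archive$stages), 1L)
  expect_identical(s1$archive$stages[[1]]$n, 150L)
  expect_identical(n_evaluations(tgt), 150L)
  s2 <- run_stage(tgt, s1$archive, s1$report$selected_params, cfg, 2)
  expect_identical(length(s2$archive$stages), 2L)
  expect_identical(s2$archive$stages[[2]]$n, 120L)
  expect_identical(n_evaluations(tgt), 270L)
  expect_true(s2$report$selected_k %in% 1:2)
  expect_equal(s2$report$cic_by_k[[as.character(s2$report$selected_k)]],
               min(s2$report$cic_by_k))
})

test_that("with the proposal at the target the CIC equals rho times the AIC", {
  qs <- two_comp_params()
  tgt <- make_gmm_target(qs, rho = 3)
  cfg <- run_config(qs, tau = 1, n_initial = 400, k_grid = 2L, seed = 9,
                    em_options = em_options(seed = 1, rel_tol = 1e-9))
  s1 <- run_stage(tgt, sample_archive(list(), 1), qs, cfg, 1)
  rec <- s1$report$records[["2"]]
  X <- s1$archive$stages[[1]]$points
  # single-stage ACE at the fitted parameter equals -(rho/n) sum log q
  expect_equal(rec$ace, -(3 / 400) * sum(dgmm(rec$params, X)), tolerance = 1e-12)
  expect_equal(s1$report$rho_estimate, 3, tolerance = 1e-13)
  expect_equal(rec$cic, 3 * gmm_aic(rec$params, X), tolerance = 1e-12)
})

test_that("a one-iteration run composes run_stage with the final rho sample", {
  tgt1 <- make_gmm_target(two_comp_params(), 3)
  tgt2 <- make_gmm_target(two_comp_params(), 3)
  cfg <- run_config(wide_proposal_1d(), tau = 1, n_initial = 300, n_stage = 200,
                    k_grid = 1:2, seed = 77)
  fit <- cic_approximate(tgt1, cfg)
  s1 <- run_stage(tgt2, sample_archive(list(), 1), cfg$initial_params, cfg, 1)
  expect_equal(fit$params, s1$report$selected_params)
  expect_identical(fit$r_evaluations, 500L) # n_0 + final n_1
  expect_identical(length(fit$archive$stages), 2L)
  # final rho excludes the initial stage
  expect_equal(fit$rho, mean(fit$archive$stages[[2]]$weights), tolerance = 1e-13)
})

test_that("identical configuration and seed reproduce a run exactly", {
  cfg <- run_config(wide_proposal_1d(), tau = 2, n_initial = 250, n_stage = 250,
                    k_grid = 1:3, seed = 13)
  a <- cic_approximate(make_gmm_target(two_comp_params(), 3), cfg)
  b <- cic_approximate(make_gmm_target(two_comp_params(), 3), cfg)
  expect_identical(a$rho_trajectory, b$rho_trajectory)
  expect_identical(a$selected_k, b$selected_k)
  expect_identical(a$params, b$params)
})

test_that("a proposal that misses the target support raises a degenerate error", {
  tgt <- make_indicator_target(1, b = 60) # essentially unreachable region
  cfg <- run_config(gmm_params(1, 0, 1), tau = 1, n_initial = 50, k_grid = 1L,
                    seed = 2)
  expect_error(cic_approximate(tgt, cfg), class = "cic_degenerate_support")
})

test_that("failed component counts are skipped rather than fatal", {
  # k = 4 cannot be supported by the tiny effective sample; k = 1 remains
  tgt <- make_indicator_target(1, b = 2)
  cfg <- run_config(gmm_params(1, 0, 4), tau = 1, n_initial = 100,
                    k_grid = c(1L, 4L), seed = 21)
  s1 <- suppressWarnings(run_stage(tgt, sample_archive(list(), 1),
                                   cfg$initial_params, cfg, 1))
  expect_true(is.finite(s1$report$cic_by_k[["1"]]))
  expect_identical(s1$report$selected_k, 1L)
})

test_that("warm starts can only improve the fit and early stop truncates the grid", {
  tgt <- make_gmm_target(two_comp_params(), 3)
  arch <- one_stage_archive(tgt, wide_proposal_1d(), 800, 29)
  cold <- fit_mce(arch, 3, em_options(seed = 4))
  warm <- fit_mce(arch, 3, em_options(seed = 4),
                  extra_starts = list(two_comp_params_padded()))
  expect_lte(warm$ace, cold$ace + 1e-12)

  cfg <- run_config(wide_proposal_1d(), tau = 1, n_initial = 800,
                    k_grid = 1:8, seed = 5, early_stop = TRUE)
  s1 <- suppressWarnings(run_stage(tgt, sample_archive(list(), 1),
                                   cfg$initial_params, cfg, 1))
  evaluated <- as.integer(names(s1$report$cic_by_k))
  expect_true(length(evaluated) <= 8)
  expect_identical(evaluated, seq_along(evaluated)) # a prefix of the grid
  expect_identical(s1$report$selected_k, select_dimension(s1$report$cic_by_k))
})
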