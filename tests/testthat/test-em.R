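# Weighted EM for the minimum cross-entropy estimator.

test_that("k = 1 initialization equals the weighted mean and covariance", {
  set.seed(4)
  X <- matrix(rnorm(200), ncol = 2)
  w <- runif(100)
  p <- init_gmm(X, w, 1, seed = 3)
  mu <- colSums(X * w) / sum(w)
  xc <- sweep(X, 2, mu)
  S <- crossprod(xc * w, xc) / sum(w)
  expect_equal(drop(p$means), mu, tolerance = 1e-12)
  expect_equal(p$covariances[[1]], S, tolerance = 1e-10)
})

test_that("initialization is seed-deterministic and needs k supported points", {
  set.seed(8)
  X <- matrix(rnorm(60), ncol = 1)
  w <- runif(60)
  a <- init_gmm(X, w, 3, seed = 5)
  b <- init_gmm(X, w, 3, seed = 5)
  expect_identical(a, b)
  w2 <- c(1, 1, rep(0, 58))
  expect_error(init_gmm(X, w2, 3, seed = 1), class = "cic_insufficient_support")
})

test_that("a single em step solves k = 1 in closed form and stays there", {
  set.seed(10)
  X <- matrix(rnorm(150, 2, 3), ncol = 1)
  w <- rexp(150)
  start <- gmm_params(1, -5, 0.1)
  stepped <- em_step(start, X, w)
  mu <- sum(X * w) / sum(w)
  S <- sum(w * (X - mu)^2) / sum(w)
  expect_equal(drop(stepped$means), mu, tolerance = 1e-10)
  expect_equal(stepped$covariances[[1]][1, 1], S, tolerance = 1e-10)
  again <- em_step(stepped, X, w)
  expect_equal(again$means, stepped$means, tolerance = 1e-12)
  expect_equal(again$covariances, stepped$covariances, tolerance = 1e-10)
})

test_that("exactly symmetric components remain symmetric under em steps", {
  set.seed(11)
  X <- matrix(c(rnorm(100, -1), rnorm(100, 1)), ncol = 1)
  w <- rep(1, 200)
  twin <- gmm_params(c(0.5, 0.5), c(0, 0), c(2, 2))
  stepped <- em_step(twin, X, w)
  expect_equal(stepped$means[1, ], stepped$means[2, ], tolerance = 1e-12)
  expect_equal(stepped$covariances[[1]], stepped$covariances[[2]], tolerance = 1e-12)
  expect_equal(stepped$weights, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("em steps never increase the ACE on random weighted instances", {
  for (rep in 1:100) {
    set.seed(rep)
    n <- 80
    X <- matrix(rnorm(n, sample(-3:3, 1), runif(1, 0.5, 3)), ncol = 1)
    w <- rexp(n, rate = runif(1, 0.2, 2))
    k <- sample(1:3, 1)
    params <- init_gmm(X, w, k, seed = rep)
    arch <- add_stage(sample_archive(list(), 1),
                      stage_record(X, w, rep(0, n), 0L))
    before <- ace(arch, params)
    stepped <- em_step(params, X, w)
    expect_lte(ace(arch, stepped), before + 1e-9)
  }
})

test_that("EM trace objectives are non-increasing and restarts pick the best", {
  tgt <- make_gmm_target(two_comp_params(), 3)
  arch <- one_stage_archive(tgt, wide_proposal_1d(), 500, 17)
  fit <- fit_mce(arch, 2, em_options(seed = 2, n_restarts = 4))
  expect_true(all(diff(fit$trace$objective_path) <= 1e-9))
  expect_equal(fit$ace, ace(arch, fit$params), tolerance = 1e-12)
})

test_that("constant weights reduce the MCE to maximum likelihood", {
  skip_if_not_installed("mclust")
  set.seed(3)
  x <- c(rnorm(300, -3), rnorm(200, 3, 1.5))
  X <- matrix(x, ncol = 1)
  rho <- 2.5
  lq <- dnorm(x, 0, 4, log = TRUE)
  arch <- add_stage(sample_archive(list(), 1),
                    stage_record(X, rho * exp(lq), lq, 0L))
  fit <- fit_mce(arch, 2, em_options(seed = 9, rel_tol = 1e-10))
  # ACE relates to the mean negative log-likelihood by the factor rho
  expect_equal(fit$ace, rho * (-mean(dgmm(fit$params, X))), tolerance = 1e-10)
  # our optimum is a fixed point of an independent unweighted EM (mclust)
  p0 <- sort_components(fit$params)
  pm <- list(pro = p0$weights, mean = drop(p0$means),
             variance = list(modelName = "V", d = 1, G = 2,
                             sigmasq = vapply(p0$covariances, function(S) S[1, 1], 0)))
  oracle <- mclust::emV(data = x, parameters = pm,
                       control = mclust::emControl(tol = 1e-10))
  expect_equal(fit$ace, -rho * oracle$loglik / length(x), tolerance = 1e-6)
})

test_that("well-separated in-family targets are recovered by the MCE", {
  truth <- gmm_params(c(0.5, 0.5), c(-4, 4), c(1, 1))
  tgt <- make_gmm_target(truth, 5)
  arch <- one_stage_archive(tgt, wide_proposal_1d(5), 2000, 31)
  fit <- fit_mce(arch, 2, em_options(seed = 6))
  got <- sort_components(fit$params)
  expect_lt(max(abs(drop(got$means) - c(-4, 4))), 0.15)
})

test_that("label permutations of a start converge to the same sorted fit", {
  tgt <- make_gmm_target(two_comp_params(), 3)
  arch <- one_stage_archive(tgt, wide_proposal_1d(), 600, 23)
  st <- arch$stages[[1]]
  start <- gmm_params(c(0.4, 0.6), c(-1, 1), c(4, 4))
  perm <- gmm_params(c(0.6, 0.4), c(1, -1), c(4, 4))
  run <- function(p0) {
    for (i in 1:200) p0 <- em_step(p0, st$points, st$weights)
    sort_components(p0)
  }
  a <- run(start); b <- run(perm)
  expect_equal(a$means, b$means, tolerance = 1e-8)
  expect_equal(a$weights, b$weights, tolerance = 1e-8)
})

test_that("overparameterized fits are refused when support is too thin", {
  # 6 positively weighted points cannot support k = 3 (d = 8) at half the
  # effective sample size
  X <- matrix(seq(-2.5, 2.5, length.out = 40), ncol = 1)
  w <- c(rep(1, 6), rep(0, 34))
  arch <- add_stage(sample_archive(list(), 1), stage_record(X, w, rep(0, 40), 0L))
  expect_error(fit_mce(arch, 3, em_options(seed = 1)),
               class = "cic_insufficient_support")
})
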