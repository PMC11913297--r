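# Shared fixtures and independent oracles used across the suite.

# Direct summation mixture density: deliberately naive, no log-sum-exp.
brute_force_dgmm <- function(params, x) {
  vapply(x, function(xi) {
    sum(vapply(seq_len(params$k), function(j)
      params$weights[j] *
        stats::dnorm(xi, params$means[j, 1], sqrt(params$covariances[[j]][1, 1])),
      0))
  }, 0)
}

# Quadrature of -integral r log q_theta for 1-D targets, independent of the
# package's oracle_cross_entropy (plain integrate on a fixed window).
quad_cross_entropy <- function(r_fun, params, lower = -40, upper = 40) {
  stats::integrate(function(x) {
    r <- r_fun(x)
    out <- -r * dgmm(params, matrix(x, ncol = 1))
    out[r == 0] <- 0
    out
  }, lower, upper, abs.tol = 1e-10, subdivisions = 1000L)$value
}

# The standard well-separated two-component test mixture and its target.
two_comp_params <- function() gmm_params(c(0.5, 0.5), c(-3, 3), c(1, 1))

wide_proposal_1d <- function(sd = 5) gmm_params(1, 0, sd^2)

# Build a one-stage archive by sampling from `proposal` and evaluating `target`.
one_stage_archive <- function(target, proposal, n, seed) {
  X <- rgmm(proposal, n, seed)
  r <- target_eval(target, X)
  lq <- dgmm(proposal, X)
  add_stage(sample_archive(list(), target$p), stage_record(X, r, lq, 0L))
}

# A 3-component start near the two-component truth, for warm-start tests.
two_comp_params_padded <- function() {
  gmm_params(c(0.45, 0.45, 0.1), c(-3, 3, 0), c(1, 1, 4))
}
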