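# Weighted EM for the minimum cross-entropy estimator (MCE): the Gaussian
# mixture minimizing the (cumulative) approximate cross-entropy over
# importance-weighted samples.

#' Options controlling the weighted EM fit
#'
#' @param max_iters maximum EM iterations per restart.
#' @param rel_tol stopping threshold on the relative ACE change between
#'   iterations.
#' @param n_restarts independent random initializations; the restart with
#'   the lowest final ACE wins, ties broken by the lowest restart index.
#' @param seed integer seed; all restart randomness derives from it.
#' @param cov_floor covariance eigenvalue floor, relative to the weighted
#'   data scale. Weighted M-steps can produce singular covariances when few
#'   points carry positive weight (the norm in rare-event targets), so
#'   every M-step covariance has its eigenvalues clipped from below.
#' @return an object of class `em_options`.
#' @export
em_options <- function(max_iters = 500L, rel_tol = 1e-6, n_restarts = 4L,
                       seed = 1L, cov_floor = 1e-6) {
  if (max_iters < 1 || rel_tol <= 0 || n_restarts < 1 || cov_floor <= 0)
    stop_invalid("max_iters, n_restarts >= 1 and rel_tol, cov_floor > 0 required")
  structure(
    list(max_iters = as.integer(max_iters), rel_tol = rel_tol,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         cov_floor = cov_floor),
    class = "em_options"
  )
}

# Absolute eigenvalue floor for this dataset: cov_floor times the average
# marginal variance of the positively weighted points.
cov_floor_abs <- function(points, weights, cov_floor) {
  mu <- colSums(points * weights) / sum(weights)
  xc <- sweep(points, 2L, mu, "-")
  scale2 <- sum(weights * rowSums(xc^2)) / (sum(weights) * ncol(points))
  cov_floor * max(scale2, .Machine$double.eps)
}

floor_cov <- function(S, floor_abs) {
  if (nrow(S) == 1L) return(matrix(max(S[1L, 1L], floor_abs), 1L, 1L))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor_abs)
  e$vectors %*% (vals * t(e$vectors))
}

min_eigenvalue <- function(S) {
  if (nrow(S) == 1L) return(S[1L, 1L])
  min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
}

#' Initialize mixture parameters on weighted points
#'
#' Means are chosen by weighted k-means++-style seeding restricted to
#' points with positive weight: the first center is drawn with probability
#' proportional to the weights, subsequent centers with probability
#' proportional to weight times squared distance to the nearest chosen
#' center. Covariances start at the global weighted covariance (floored)
#' and component weights at \eqn{1/k}. Deterministic given `seed`.
#'
#' @param points \eqn{n \times p} matrix.
#' @param weights nonnegative importance weights.
#' @param k component count; requires at least `k` positively weighted points.
#' @param seed integer seed.
#' @param cov_floor relative covariance eigenvalue floor.
#' @return a [gmm_params] object.
#' @export
init_gmm <- function(points, weights, k, seed, cov_floor = 1e-6) {
  points <- as.matrix(points)
  pos <- which(weights > 0)
  if (length(pos) < k)
    cic_error("cic_insufficient_support",
              sprintf("need at least %d positively weighted points, have %d",
                      k, length(pos)))
  p <- ncol(points)
  floor_abs <- cov_floor_abs(points, weights, cov_floor)
  wpos <- weights[pos]
  xpos <- points[pos, , drop = FALSE]
  if (k == 1L) {
    # closed form: the weighted mean is the exact k = 1 minimizer
    mu <- colSums(points * weights) / sum(weights)
    xc <- sweep(points, 2L, mu, "-")
    S <- floor_cov(crossprod(xc * weights, xc) / sum(weights), floor_abs)
    return(gmm_params(1, matrix(mu, 1L), list(S)))
  }
  centers <- with_local_seed(seed, {
    ctr <- matrix(0, k, p)
    first <- sample.int(length(pos), 1L, prob = wpos)
    ctr[1L, ] <- xpos[first, ]
    if (k > 1L) {
      d2 <- rowSums(sweep(xpos, 2L, ctr[1L, ], "-")^2)
      for (j in 2L:k) {
        prob <- wpos * d2
        if (all(prob == 0)) prob <- wpos
        pick <- sample.int(length(pos), 1L, prob = prob)
        ctr[j, ] <- xpos[pick, ]
        d2 <- pmin(d2, rowSums(sweep(xpos, 2L, ctr[j, ], "-")^2))
      }
    }
    ctr
  })
  mu <- colSums(points * weights) / sum(weights)
  xc <- sweep(points, 2L, mu, "-")
  S <- crossprod(xc * weights, xc) / sum(weights)
  S <- floor_cov(S, floor_abs)
  gmm_params(rep(1 / k, k), centers, rep(list(S), k))
}

# E-step: responsibilities and the ACE of `params` on (points, weights).
# Returns log gamma (n x k) and the weighted negative mean log-density.
e_step <- function(params, points, weights, n_denom) {
  L <- component_log_dens(params, points)
  lw <- log(params$weights)
  for (j in seq_len(params$k)) L[, j] <- L[, j] + lw[j]
  lse <- row_logsumexp(L)
  deg <- lse == -Inf
  aceval <- if (any(weights > 0 & deg)) Inf else {
    contrib <- weights * lse
    contrib[weights == 0] <- 0
    -sum(contrib) / n_denom
  }
  lse[deg] <- 0
  lg <- L - lse # column recycling: normalize each row
  if (any(deg)) lg[deg, ] <- log(1 / params$k)
  list(log_gamma = lg, ace = aceval)
}

#' One weighted EM step
#'
#' E-step: responsibilities \eqn{\gamma_{ij} \propto \pi_j N(x_i; \mu_j,
#' \Sigma_j)}. M-step with combined masses \eqn{m_{ij} = w_i \gamma_{ij}}:
#' \eqn{\pi_j = \sum_i m_{ij} / \sum_i w_i}, \eqn{\mu_j} and \eqn{\Sigma_j}
#' the mass-weighted mean and covariance, with covariance eigenvalues
#' floored. Each step does not increase the ACE (up to flooring effects).
#'
#' @param params current [gmm_params].
#' @param points \eqn{n \times p} matrix.
#' @param weights nonnegative importance weights with positive sum.
#' @param cov_floor relative covariance eigenvalue floor.
#' @return the updated [gmm_params].
#' @export
em_step <- function(params, points, weights, cov_floor = 1e-6) {
  points <- as_points_matrix(points, params$p)
  if (sum(weights) <= 0) stop_degenerate("weights must have positive sum")
  floor_abs <- cov_floor_abs(points, weights, cov_floor)
  es <- e_step(params, points, weights, n_denom = nrow(points))
  m_step(params, points, weights, es$log_gamma, floor_abs)$params
}

# M-step shared by em_step and fit_mce. Returns updated params plus a flag
# vector of collapsed components (mass below 1e-12 of total weight).
m_step <- function(params, points, weights, log_gamma, floor_abs) {
  k <- params$k; p <- params$p
  gam <- exp(log_gamma) * weights
  mass <- colSums(gam)
  total <- sum(weights)
  collapsed <- mass < 1e-12 * total
  pi_new <- mass / total
  means <- matrix(0, k, p)
  covs <- vector("list", k)
  for (j in seq_len(k)) {
    if (collapsed[j]) {
      means[j, ] <- params$means[j, ]
      covs[[j]] <- params$covariances[[j]]
      next
    }
    mj <- colSums(points * gam[, j]) / mass[j]
    xc <- points - matrix(mj, nrow(points), p, byrow = TRUE)
    Sj <- crossprod(xc * gam[, j], xc) / mass[j]
    means[j, ] <- mj
    covs[[j]] <- floor_cov(Sj, floor_abs)
  }
  if (any(collapsed)) {
    # keep weights a valid simplex even with collapsed components
    pi_new[collapsed] <- 1e-12
    pi_new <- pi_new / sum(pi_new)
  }
  list(params = gmm_params(pi_new, means, covs), collapsed = collapsed)
}

#' Fit the minimum cross-entropy estimator for a fixed component count
#'
#' Minimizes the cumulative ACE over the archive's pooled, importance-
#' weighted points by weighted EM with multiple random restarts. Each
#' restart runs [init_gmm()] seeding followed by EM steps until the
#' relative ACE change drops below `rel_tol` or `max_iters` is reached; the
#' restart with the lowest final ACE is returned.
#'
#' A component whose mass vanishes (or sits on the covariance floor) for
#' three consecutive iterations is reinitialized at the positively weighted
#' point the current model explains worst; after two such rescues the
#' restart is aborted. If every restart aborts, a fit-failure error is
#' raised so the caller can skip this component count.
#'
#' @param archive a [sample_archive].
#' @param k component count.
#' @param options an [em_options] object.
#' @param stages stage subset to fit on (default: all stages, the
#'   cumulative estimator).
#' @param extra_starts optional list of [gmm_params] used as additional EM
#'   starting points (e.g. the previous iteration's fit when warm-starting).
#' @return a list with `params` (the fitted [gmm_params]), `ace` (its
#'   cumulative ACE) and `trace` (an `em_trace` with the per-iteration
#'   objective path, iteration count, convergence flag and winning restart
#'   index).
#' @export
fit_mce <- function(archive, k, options = em_options(), stages = NULL,
                    extra_starts = list()) {
  idx <- stage_subset(archive, stages)
  pts <- do.call(rbind, lapply(idx, function(s) archive$stages[[s + 1L]]$points))
  w <- unlist(lapply(idx, function(s) archive$stages[[s + 1L]]$weights))
  n <- nrow(pts)
  d <- param_dimension(k, archive$p)
  if (d >= 0.5 * ess(w))
    cic_error("cic_insufficient_support",
              sprintf("free-parameter dimension d = %d exceeds half the effective sample size %.1f",
                      d, ess(w)))
  floor_abs <- cov_floor_abs(pts, w, options$cov_floor)
  best <- NULL
  n_starts <- options$n_restarts + length(extra_starts)
  for (rs in seq_len(n_starts)) {
    res <- tryCatch({
      start <- if (rs <= options$n_restarts)
        init_gmm(pts, w, k, derive_seed(options$seed, k, rs), options$cov_floor)
      else extra_starts[[rs - options$n_restarts]]
      em_run(pts, w, start, options, floor_abs, rs)
    },
    cic_insufficient_support = function(e) e,
    cic_fit_failed = function(e) e
    )
    if (inherits(res, "cic_insufficient_support")) stop(res)
    if (inherits(res, "condition")) next
    if (is.null(best) || res$ace < best$ace) best <- res
  }
  if (is.null(best))
    cic_error("cic_fit_failed",
              sprintf("all %d starts collapsed for k = %d", n_starts, k))
  best
}

em_run <- function(pts, w, params, options, floor_abs, restart_index) {
  k <- params$k
  n <- nrow(pts)
  path <- numeric(options$max_iters)
  prev <- Inf
  n_done <- 0L
  converged <- FALSE
  stuck <- integer(k) # consecutive iterations collapsed or on the floor
  reinits <- 0L
  es <- e_step(params, pts, w, n_denom = n)
  for (it in seq_len(options$max_iters)) {
    ms <- m_step(params, pts, w, es$log_gamma, floor_abs)
    floored <- vapply(ms$params$covariances, function(S)
      min_eigenvalue(S) <= floor_abs * (1 + 1e-9), logical(1))
    stuck <- ifelse(ms$collapsed | floored, stuck + 1L, 0L)
    params <- ms$params
    if (any(stuck >= 3L)) {
      if (reinits >= 2L)
        cic_error("cic_fit_failed", "restart aborted after repeated component collapse")
      j <- which.max(stuck)
      params <- reseed_component(params, pts, w, j, floor_abs)
      stuck[j] <- 0L
      reinits <- reinits + 1L
    }
    es <- e_step(params, pts, w, n_denom = n) # ACE of updated params; reused next iter
    cur <- es$ace
    n_done <- it
    path[it] <- cur
    if (is.finite(prev) && abs(prev - cur) <= options$rel_tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- cur
  }
  path <- path[seq_len(n_done)]
  trace <- structure(
    list(objective_path = path, n_iters = n_done, converged = converged,
         restart_index = restart_index),
    class = "em_trace"
  )
  list(params = params, ace = path[n_done], trace = trace)
}

# Move component j to the positively weighted point the model explains
# worst (largest w_i / q(x_i)), with the global floored covariance.
reseed_component <- function(params, pts, w, j, floor_abs) {
  lq <- dgmm(params, pts)
  score <- ifelse(w > 0, log(w) - lq, -Inf)
  pick <- which.max(score)
  means <- params$means
  means[j, ] <- pts[pick, ]
  covs <- params$covariances
  mu <- colSums(pts * w) / sum(w)
  xc <- sweep(pts, 2L, mu, "-")
  covs[[j]] <- floor_cov(crossprod(xc * w, xc) / sum(w), floor_abs)
  wt <- params$weights
  wt[j] <- max(wt[j], 1 / params$k)
  gmm_params(wt / sum(wt), means, covs)
}
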