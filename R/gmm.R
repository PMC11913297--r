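# Gaussian mixture approximating family: construction, density, sampling,
# free-parameter dimension, canonical ordering, JSON round-trip.

#' Construct a Gaussian mixture parameter object
#'
#' The approximating family used throughout the package is the
#' \eqn{k}-component Gaussian mixture on \eqn{R^p} with unconstrained means
#' and covariances. A `gmm_params` object holds one member of that family.
#'
#' @param weights numeric vector of \eqn{k} nonnegative component weights
#'   summing to 1.
#' @param means a \eqn{k \times p} matrix of component means (a vector is
#'   taken as \eqn{p = 1}).
#' @param covariances a list of \eqn{k} symmetric positive-definite
#'   \eqn{p \times p} matrices, or a numeric vector of variances when
#'   \eqn{p = 1}.
#' @param cov_floor smallest admissible covariance eigenvalue; components are
#'   rejected below it.
#' @return an object of class `gmm_params` with elements `k`, `p`, `weights`,
#'   `means`, `covariances`.
#' @examples
#' gmm_params(c(0.3, 0.7), c(-1, 2), c(1, 4))
#' @export
gmm_params <- function(weights, means, covariances, cov_floor = 1e-12) {
  weights <- as.numeric(weights)
  k <- length(weights)
  if (k < 1L) stop_invalid("at least one component is required")
  if (is.null(dim(means))) means <- matrix(as.numeric(means), nrow = k)
  means <- as.matrix(means)
  p <- ncol(means)
  if (nrow(means) != k) stop_invalid("`means` must have one row per component")
  if (!is.list(covariances)) {
    if (p != 1L) stop_invalid("`covariances` must be a list of p x p matrices")
    covariances <- lapply(as.numeric(covariances), function(v) matrix(v, 1L, 1L))
  }
  if (length(covariances) != k)
    stop_invalid("`covariances` must have one matrix per component")
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    if (!all(dim(S) == p)) stop_invalid("covariance dimension mismatch")
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop_invalid("covariances must be symmetric")
    (S + t(S)) / 2
  })
  if (any(!is.finite(weights)) || any(weights < 0))
    stop_invalid("weights must be nonnegative and finite")
  if (abs(sum(weights) - 1) > 1e-12)
    stop_invalid("weights must sum to 1 within 1e-12")
  for (S in covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < cov_floor)
      stop_invalid("covariance has an eigenvalue below the configured floor")
  }
  if (!all(is.finite(means))) stop_invalid("means must be finite")
  structure(
    list(k = k, p = p, weights = weights, means = means,
         covariances = covariances),
    class = "gmm_params"
  )
}

#' @export
print.gmm_params <- function(x, ...) {
  cat(sprintf("Gaussian mixture: k = %d components on R^%d (d = %d free parameters)\n",
              x$k, x$p, param_dimension(x$k, x$p)))
  cat("weights:", format(x$weights, digits = 4), "\n")
  for (j in seq_len(x$k)) {
    cat(sprintf("  comp %d: mean = (%s)  cov diag = (%s)\n", j,
                paste(format(x$means[j, ], digits = 4), collapse = ", "),
                paste(format(diag(x$covariances[[j]]), digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Free-parameter dimension of a Gaussian mixture
#'
#' For a \eqn{k}-component mixture on \eqn{R^p} with unconstrained means and
#' covariances, the number of free parameters is
#' \deqn{d = (k - 1) + k\,\{p + p(p+1)/2\},}
#' counting \eqn{k - 1} free weights, \eqn{kp} mean coordinates and
#' \eqn{k\,p(p+1)/2} covariance entries. This \eqn{d} is the model dimension
#' penalized by the cross-entropy information criterion.
#'
#' @param k positive integer component count.
#' @param p positive integer support dimension.
#' @return integer \eqn{d}.
#' @examples
#' param_dimension(3, 2) # 17
#' @export
param_dimension <- function(k, p) {
  if (length(k) != 1L || length(p) != 1L || !is.finite(k) || !is.finite(p) ||
      k < 1 || p < 1 || k != round(k) || p != round(p))
    stop_invalid("`k` and `p` must be positive integers")
  k <- as.integer(k); p <- as.integer(p)
  (k - 1L) + k * (p + (p * (p + 1L)) %/% 2L)
}

# Per-component Gaussian log-densities: n x k matrix of log N(x_i; mu_j, S_j).
component_log_dens <- function(params, points) {
  n <- nrow(points); p <- params$p
  out <- matrix(0, n, params$k)
  c0 <- p * log(2 * pi)
  for (j in seq_len(params$k)) {
    if (p == 1L) {
      s2 <- params$covariances[[j]][1L, 1L]
      xc <- points[, 1L] - params$means[j, 1L]
      out[, j] <- -0.5 * (c0 + log(s2) + xc * xc / s2)
    } else {
      R <- chol(params$covariances[[j]])
      xc <- points - matrix(params$means[j, ], n, p, byrow = TRUE)
      y <- t(backsolve(R, t(xc), transpose = TRUE))
      out[, j] <- -0.5 * (c0 + 2 * sum(log(diag(R))) + rowSums(y * y))
    }
  }
  out
}

#' Log-density of a Gaussian mixture
#'
#' Evaluates \eqn{\log q_\theta(x_i)} at each row of `points` via a
#' log-sum-exp over per-component log-densities computed from Cholesky
#' factors, so components whose weights span many orders of magnitude (as
#' they do in rare-event targets) are combined without underflow.
#'
#' @param params a [gmm_params] object.
#' @param points an \eqn{n \times p} matrix (or a vector when \eqn{p = 1}).
#' @param log if `FALSE`, return the density itself.
#' @return numeric vector of length \eqn{n}.
#' @export
dgmm <- function(params, points, log = TRUE) {
  points <- as_points_matrix(points, params$p)
  L <- component_log_dens(params, points)
  L <- sweep(L, 2L, log(params$weights), "+")
  out <- row_logsumexp(L)
  if (log) out else exp(out)
}

#' Sample from a Gaussian mixture
#'
#' Draws component labels from the mixture weights, then Gaussian deviates
#' through the component Cholesky factors. The draw is deterministic given
#' `seed` and leaves the caller's RNG state untouched.
#'
#' @param params a [gmm_params] object.
#' @param n number of draws.
#' @param seed integer seed for this draw.
#' @return an \eqn{n \times p} matrix whose rows are i.i.d. from the mixture.
#' @export
rgmm <- function(params, n, seed) {
  if (length(n) != 1L || n < 1 || n != round(n)) stop_invalid("`n` must be a positive integer")
  n <- as.integer(n)
  with_local_seed(seed, {
    labels <- sample.int(params$k, n, replace = TRUE, prob = params$weights)
    z <- matrix(stats::rnorm(n * params$p), n, params$p)
    out <- matrix(0, n, params$p)
    for (j in seq_len(params$k)) {
      idx <- which(labels == j)
      if (!length(idx)) next
      R <- chol(params$covariances[[j]])
      out[idx, ] <- z[idx, , drop = FALSE] %*% R +
        matrix(params$means[j, ], length(idx), params$p, byrow = TRUE)
    }
    out
  })
}

#' Canonically order mixture components
#'
#' Mixture likelihoods are invariant under component relabelling; for
#' reporting and comparisons the components are sorted by their first mean
#' coordinate. Never applied during fitting.
#'
#' @param params a [gmm_params] object.
#' @return the same mixture with components sorted.
#' @export
sort_components <- function(params) {
  ord <- order(params$means[, 1L])
  gmm_params(params$weights[ord], params$means[ord, , drop = FALSE],
             params$covariances[ord])
}

#' Serialize / deserialize mixture parameters as JSON
#'
#' @param params a [gmm_params] object.
#' @return `gmm_to_json()` returns a JSON string with fields `weights`,
#'   `means`, `covariances`; `gmm_from_json()` inverts it.
#' @export
gmm_to_json <- function(params) {
  jsonlite::toJSON(
    list(weights = params$weights, means = params$means,
         covariances = params$covariances),
    digits = NA, auto_unbox = FALSE
  )
}

#' @rdname gmm_to_json
#' @param json a JSON string produced by `gmm_to_json()`.
#' @export
gmm_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  covs <- x$covariances
  if (is.array(covs) && length(dim(covs)) == 3L) {
    covs <- lapply(seq_len(dim(covs)[1L]), function(j) covs[j, , , drop = TRUE])
    covs <- lapply(covs, function(S) as.matrix(S))
  }
  gmm_params(x$weights, as.matrix(x$means), covs)
}
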