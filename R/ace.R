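# Importance weights, the approximate cross-entropy (ACE) in single-stage
# and cumulative forms, normalizing-constant estimators, the CIC value, and
# the stage/archive containers they operate on.

#' Importance weights for an unnormalized target
#'
#' Given evaluations \eqn{r(x_i) \ge 0} of the unnormalized target and the
#' log-density of the proposal each point was drawn from, returns the
#' importance weights \eqn{w_i = r(x_i) / q_\eta(x_i)}. When the proposal
#' equals the normalized target \eqn{q^* = r/\rho}, every weight equals
#' \eqn{\rho} exactly — the zero-variance optimum of importance sampling.
#'
#' @param r_values nonnegative finite numeric vector.
#' @param proposal_log_density finite numeric vector, same length.
#' @return nonnegative numeric weights.
#' @export
importance_weights <- function(r_values, proposal_log_density) {
  if (length(r_values) != length(proposal_log_density))
    stop_invalid("`r_values` and `proposal_log_density` must have equal length")
  if (any(!is.finite(r_values)) || any(r_values < 0))
    cic_error("cic_invalid_target",
              "target evaluations must be nonnegative and finite")
  if (any(!is.finite(proposal_log_density)))
    stop_invalid("`proposal_log_density` must be finite")
  w <- r_values * exp(-proposal_log_density)
  if (all(w == 0))
    stop_degenerate("all importance weights are zero: the proposal misses the support of the target")
  w
}

#' One stage of importance-sampled evaluations
#'
#' A stage bundles the points drawn from one proposal, the (expensive)
#' target evaluations \eqn{r(x_i)} made exactly once at those points, the
#' proposal log-density, and the resulting importance weights. Weights are
#' computed here, once, and reused by every candidate model considered
#' later: no downstream operation re-evaluates \eqn{r}.
#'
#' @param points \eqn{n \times p} matrix of sampled points.
#' @param r_values evaluations of the unnormalized target at `points`.
#' @param proposal_log_density log proposal density at `points`.
#' @param stage_index nonnegative integer stage label.
#' @return an object of class `stage_record`.
#' @export
stage_record <- function(points, r_values, proposal_log_density, stage_index = 0L) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (length(r_values) != n || length(proposal_log_density) != n)
    stop_invalid("row counts of `points`, `r_values`, `proposal_log_density` must agree")
  if (stage_index < 0 || stage_index != round(stage_index))
    stop_invalid("`stage_index` must be a nonnegative integer")
  w <- importance_weights(r_values, proposal_log_density)
  structure(
    list(stage_index = as.integer(stage_index), points = points,
         r_values = as.numeric(r_values),
         proposal_log_density = as.numeric(proposal_log_density),
         weights = w, n = n),
    class = "stage_record"
  )
}

#' Ordered archive of sampling stages
#'
#' Holds stages \eqn{s = 0, \dots, t-1} with contiguous indices and a common
#' dimension, supporting the cumulative cross-entropy estimator and the
#' cumulative normalizing-constant estimator.
#'
#' @param stages list of [stage_record] objects (may be empty).
#' @param p support dimension.
#' @return an object of class `sample_archive`.
#' @export
sample_archive <- function(stages = list(), p) {
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (!inherits(st, "stage_record")) stop_invalid("stages must be stage_record objects")
    if (st$stage_index != i - 1L) stop_invalid("stage indices must be contiguous from 0")
    if (ncol(st$points) != p) stop_invalid("all stages must share dimension p")
  }
  structure(list(stages = stages, p = as.integer(p)), class = "sample_archive")
}

#' @rdname sample_archive
#' @param archive an existing archive.
#' @param stage a [stage_record] whose index must equal the archive length.
#' @export
add_stage <- function(archive, stage) {
  stopifnot(inherits(archive, "sample_archive"))
  if (stage$stage_index != length(archive$stages))
    stop_invalid("new stage index must continue the archive")
  if (ncol(stage$points) != archive$p) stop_invalid("stage dimension mismatch")
  archive$stages <- c(archive$stages, list(stage))
  archive
}

#' @export
print.sample_archive <- function(x, ...) {
  ns <- vapply(x$stages, function(s) s$n, 0L)
  cat(sprintf("Sample archive: %d stage(s), %d points total, p = %d\n",
              length(x$stages), sum(ns), x$p))
  invisible(x)
}

n_points <- function(archive, stages = NULL) {
  idx <- stage_subset(archive, stages)
  sum(vapply(archive$stages[idx + 1L], function(s) s$n, 0L))
}

stage_subset <- function(archive, stages) {
  all_idx <- vapply(archive$stages, function(s) s$stage_index, 0L)
  if (is.null(stages)) return(all_idx)
  stages <- as.integer(stages)
  if (!all(stages %in% all_idx)) stop_invalid("requested stage does not exist")
  stages
}

#' Approximate cross-entropy (ACE)
#'
#' The importance-sampling estimator of the cross-entropy
#' \eqn{C(\theta) = -\int r \log q_\theta \, d\mu} from a candidate mixture
#' to the target, pooled over the requested stages:
#' \deqn{\bar C = -\frac{\sum_s \sum_i w_i^{(s)} \log q_\theta(x_i^{(s)})}{\sum_s n_s}.}
#' With a single stage this is the per-stage estimator; with all stages it
#' is the cumulative estimator, each observation weighted equally.
#'
#' If the candidate assigns zero density (log-density \eqn{-\infty} after
#' underflow) to a point carrying positive weight, the absolute-continuity
#' requirement behind the KL divergence is violated there and `+Inf` is
#' returned — a well-defined worst score so model search ranks such a
#' candidate last — rather than an error.
#'
#' @param archive a [sample_archive].
#' @param candidate a [gmm_params] candidate model.
#' @param stages integer vector of stage indices, or `NULL` for all.
#' @return the ACE value (may be `+Inf`).
#' @export
ace <- function(archive, candidate, stages = NULL) {
  idx <- stage_subset(archive, stages)
  if (!length(idx)) stop_invalid("at least one stage is required")
  if (candidate$p != archive$p) stop_invalid("candidate dimension mismatch")
  num <- 0; n_tot <- 0L
  for (s in idx) {
    st <- archive$stages[[s + 1L]]
    lq <- dgmm(candidate, st$points)
    if (any(st$weights > 0 & lq == -Inf)) return(Inf)
    contrib <- st$weights * lq
    contrib[st$weights == 0] <- 0
    num <- num + sum(contrib)
    n_tot <- n_tot + st$n
  }
  -num / n_tot
}

#' Importance-sampling estimator of the normalizing constant
#'
#' Pools the stored importance weights into the estimator
#' \eqn{\hat\rho = \sum_s \sum_i w_i^{(s)} / \sum_s n_s}. With a single
#' stage this is the plain importance-sampling estimator; over several
#' stages the initial stage \eqn{s = 0} is excluded when
#' `include_initial = FALSE`, because points drawn from a poorly chosen
#' initial proposal can inflate the estimator's variance.
#'
#' @param archive a [sample_archive].
#' @param include_initial include stage 0 in the pool?
#' @param stages optional explicit stage subset overriding the rule above.
#' @return a single positive number.
#' @export
rho_hat <- function(archive, include_initial = TRUE, stages = NULL) {
  if (is.null(stages)) {
    stages <- stage_subset(archive, NULL)
    if (!include_initial) stages <- stages[stages >= 1L]
  }
  if (!length(stages))
    stop_invalid("no stages available for the normalizing-constant estimate")
  w <- unlist(lapply(stages, function(s) archive$stages[[s + 1L]]$weights))
  if (all(w == 0)) stop_degenerate("all pooled weights are zero")
  sum(w) / length(w)
}

#' @rdname rho_hat
#' @details `rho_se()` returns the Monte-Carlo standard error of the pooled
#'   mean of weights (treating pooled weights as i.i.d., which is exact per
#'   stage and an approximation across stages).
#' @export
rho_se <- function(archive, include_initial = TRUE, stages = NULL) {
  if (is.null(stages)) {
    stages <- stage_subset(archive, NULL)
    if (!include_initial) stages <- stages[stages >= 1L]
  }
  w <- unlist(lapply(stages, function(s) archive$stages[[s + 1L]]$weights))
  stats::sd(w) / sqrt(length(w))
}

#' Cross-entropy information criterion (CIC)
#'
#' The bias-corrected cross-entropy estimate used for model selection:
#' \deqn{CIC = \bar C(\hat\theta) + \hat\rho\, d / n,}
#' where \eqn{\bar C(\hat\theta)} is the (cumulative) ACE at the fitted
#' model, \eqn{d} the free-parameter dimension, \eqn{n} the total number of
#' observations underlying the ACE, and \eqn{\hat\rho} a consistent
#' estimate of the normalizing constant. The penalty corrects the
#' asymptotic downward bias \eqn{-\rho d/n} incurred by evaluating the ACE
#' at the parameter that minimizes it. When sampling happens directly from
#' the target, the CIC reduces to \eqn{\rho} times the AIC.
#'
#' @param ace_value ACE at the fitted parameter.
#' @param rho_estimate positive estimate of the normalizing constant.
#' @param d nonnegative integer free-parameter dimension.
#' @param n_total positive integer sample count underlying `ace_value`.
#' @return the CIC value.
#' @export
cic_value <- function(ace_value, rho_estimate, d, n_total) {
  if (!is.finite(rho_estimate) || rho_estimate <= 0)
    stop_invalid("`rho_estimate` must be positive")
  if (d < 0 || d != round(d)) stop_invalid("`d` must be a nonnegative integer")
  if (n_total < 1 || n_total != round(n_total))
    stop_invalid("`n_total` must be a positive integer")
  ace_value + rho_estimate * d / n_total
}

#' Effective sample size of importance weights
#'
#' The standard diagnostic \eqn{(\sum w)^2 / \sum w^2} for weight
#' degeneracy; equals \eqn{n} for equal weights and 1 when a single weight
#' dominates.
#'
#' @param weights nonnegative weights, at least one positive.
#' @return a value in \eqn{(0, n]}.
#' @export
ess <- function(weights) {
  if (any(!is.finite(weights)) || any(weights < 0))
    stop_invalid("weights must be nonnegative and finite")
  if (all(weights == 0)) stop_degenerate("all weights are zero")
  sum(weights)^2 / sum(weights^2)
}

#' AIC of a mixture fit on directly observed data
#'
#' The Akaike information criterion, scaled per observation:
#' \eqn{-(1/n)\sum_i \log q_\theta(x_i) + d/n}. Used as the reference in the
#' identity that the CIC equals \eqn{\hat\rho} times the AIC when the
#' proposal coincides with the normalized target.
#'
#' @param params a fitted [gmm_params] object.
#' @param points the \eqn{n \times p} data matrix.
#' @return the per-observation AIC.
#' @export
gmm_aic <- function(params, points) {
  points <- as_points_matrix(points, params$p)
  n <- nrow(points)
  d <- param_dimension(params$k, params$p)
  -mean(dgmm(params, points)) + d / n
}
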