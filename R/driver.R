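# Iterative CIC-based approximation driver. One iteration samples from the
# current model, evaluates r once per point, refits each candidate
# component count on the archived (cumulative) sample, and keeps the
# mixture minimizing the CIC. The non-cumulative variant (fixed family,
# newest stage only) is the classical cross-entropy-method iteration.

#' Configuration for an approximation run
#'
#' @param initial_params a [gmm_params] object: the initial proposal
#'   \eqn{\eta}, chosen to cover the support where \eqn{r} is expected to
#'   be nonzero.
#' @param tau number of iterations.
#' @param n_initial sample size \eqn{n_0} of the initial stage.
#' @param n_stage sample size \eqn{n_t} of each later stage (and of the
#'   final normalizing-constant sample); either a single value or a vector
#'   of length `tau`.
#' @param k_grid strictly increasing candidate component counts. With
#'   `cumulative = FALSE` the grid must be a single value: that variant
#'   performs no model selection.
#' @param cumulative if `TRUE` (default), every candidate is refit on all
#'   archived stages and the CIC uses the cumulative estimators; if
#'   `FALSE`, fits and the normalizing-constant estimate use only the
#'   newest stage.
#' @param seed root seed; all stage/fit/restart randomness derives from it.
#' @param em_options an [em_options] object (its seed field is overridden
#'   by streams derived from `seed`).
#' @param warm_start if `TRUE`, each refit of a component count also tries
#'   the previous iteration's fit of the same count as an extra EM start
#'   (in addition to, never instead of, the fresh restarts). Off by
#'   default: every count is refit from scratch on the cumulative sample,
#'   which matches the definition of the cumulative estimator and avoids
#'   path dependence.
#' @param early_stop if `TRUE`, the grid search stops after the criterion
#'   increases for two consecutive counts. Off by default: the search is
#'   exhaustive.
#' @return an object of class `run_config`.
#' @export
run_config <- function(initial_params, tau = 7L, n_initial = 1000L,
                       n_stage = 1000L, k_grid = 1:10, cumulative = TRUE,
                       seed = 1L, em_options = cicapprox::em_options(),
                       warm_start = FALSE, early_stop = FALSE) {
  if (tau < 1 || tau != round(tau)) stop_invalid("`tau` must be a positive integer")
  tau <- as.integer(tau)
  if (length(n_stage) == 1L) n_stage <- rep(as.integer(n_stage), tau)
  if (length(n_stage) != tau) stop_invalid("`n_stage` must have length 1 or tau")
  if (n_initial < 1 || any(n_stage < 1)) stop_invalid("sample sizes must be >= 1")
  k_grid <- as.integer(k_grid)
  if (!length(k_grid) || any(k_grid < 1) || is.unsorted(k_grid, strictly = TRUE))
    stop_invalid("`k_grid` must be a nonempty strictly increasing set of counts >= 1")
  if (!cumulative && length(k_grid) != 1L)
    stop_invalid("the non-cumulative (fixed-family) variant requires a single k")
  structure(
    list(initial_params = initial_params, tau = tau,
         n_initial = as.integer(n_initial), n_stage = n_stage,
         k_grid = k_grid, cumulative = isTRUE(cumulative),
         seed = as.integer(seed), em_options = em_options,
         warm_start = isTRUE(warm_start), early_stop = isTRUE(early_stop)),
    class = "run_config"
  )
}

#' One iteration: sample, weight, refit candidates, select by CIC
#'
#' Executes iteration `t`: draws the stage-\eqn{(t-1)} sample of size
#' \eqn{n_{t-1}} from the current model, evaluates \eqn{r} exactly once per
#' point, appends the stage to the archive, and — in cumulative mode —
#' refits every `k` in the grid on all archived stages, scoring each with
#' \deqn{\overline{CIC}^{(t)}(k) = \bar C(\hat\theta_k) +
#'   \hat\rho\, d_k / \textstyle\sum_s n_s.}
#' The normalizing-constant estimate inside the penalty does not depend on
#' `k`, so it is computed once per stage: from the initial stage at
#' \eqn{t = 1}, and from stages \eqn{s \ge 1} thereafter. Component counts
#' whose fit fails are excluded from selection (score `+Inf`).
#'
#' In non-cumulative mode the single grid entry is refit on the newest
#' stage only and \eqn{\hat\rho} is that stage's mean weight.
#'
#' @param target an [unnorm_target].
#' @param archive the [sample_archive] accumulated so far (stages
#'   \eqn{0..t-2}; empty at \eqn{t = 1}).
#' @param current the current proposal [gmm_params] (\eqn{\eta} at
#'   \eqn{t = 1}).
#' @param config a [run_config].
#' @param t iteration number, \eqn{\ge 1}.
#' @param previous the previous iteration's `fit_report`, used only when
#'   `config$warm_start` is on.
#' @return list with the extended `archive` and a `fit_report` holding
#'   per-k records, the selected k and parameters, the stage's
#'   normalizing-constant estimate, and effective sample sizes.
#' @export
run_stage <- function(target, archive, current, config, t, previous = NULL) {
  if (t < 1 || t != round(t)) stop_invalid("`t` must be >= 1")
  s_new <- length(archive$stages) # stage index being generated = t - 1
  n_s <- if (t == 1L) config$n_initial else config$n_stage[t - 1L]
  X <- rgmm(current, n_s, derive_seed(config$seed, t, 0L, 1L))
  r_vals <- target_eval(target, X)
  lq <- dgmm(current, X)
  stage <- stage_record(X, r_vals, lq, stage_index = s_new)
  archive <- add_stage(archive, stage)

  fit_stages <- if (config$cumulative) NULL else s_new
  rho_stages <- if (config$cumulative) {
    if (t == 1L) 0L else setdiff(stage_subset(archive, NULL), 0L)
  } else s_new
  rho <- rho_hat(archive, stages = rho_stages)
  rho_stderr <- rho_se(archive, stages = rho_stages)
  n_tot <- n_points(archive, fit_stages)

  records <- list()
  n_increases <- 0L
  last_finite <- Inf
  for (k in config$k_grid) {
    opts <- config$em_options
    opts$seed <- derive_seed(config$seed, t, k, 2L)
    extra <- list()
    if (config$warm_start && !is.null(previous)) {
      prev_rec <- previous$records[[as.character(k)]]
      if (!is.null(prev_rec) && !prev_rec$failed)
        extra <- list(prev_rec$params)
    }
    rec <- tryCatch({
      fit <- fit_mce(archive, k, opts, stages = fit_stages, extra_starts = extra)
      d <- param_dimension(k, archive$p)
      list(k = k, d = d, ace = fit$ace,
           cic = cic_value(fit$ace, rho, d, n_tot),
           params = fit$params, trace = fit$trace, failed = FALSE)
    },
    cic_fit_failed = function(e)
      list(k = k, d = param_dimension(k, archive$p), ace = Inf, cic = Inf,
           params = NULL, trace = NULL, failed = TRUE,
           reason = conditionMessage(e)),
    cic_insufficient_support = function(e)
      list(k = k, d = param_dimension(k, archive$p), ace = Inf, cic = Inf,
           params = NULL, trace = NULL, failed = TRUE,
           reason = conditionMessage(e))
    )
    records[[as.character(k)]] <- rec
    if (config$early_stop && is.finite(rec$cic)) {
      if (is.finite(last_finite)) {
        n_increases <- if (rec$cic > last_finite) n_increases + 1L else 0L
      }
      last_finite <- rec$cic
      if (n_increases >= 2L) break
    }
  }
  cic_by_k <- vapply(records, function(r) r$cic, 0)
  names(cic_by_k) <- vapply(records, function(r) as.character(r$k), "")
  sel <- tryCatch(select_dimension(cic_by_k), cic_fit_failed = function(e) e)
  if (inherits(sel, "condition"))
    cic_error("cic_fit_failed", sprintf("every component count failed at iteration %d", t))
  selected <- records[[as.character(sel)]]

  # weight degeneracy of the newly selected model on its own stage
  lq_sel <- dgmm(selected$params, stage$points)
  w_sel <- ifelse(is.finite(lq_sel), stage$r_values * exp(-lq_sel),
                  ifelse(stage$r_values > 0, Inf, 0))
  ess_sel <- if (all(w_sel == 0) || any(!is.finite(w_sel))) 0 else ess(w_sel)
  if (ess_sel < 5)
    warning(sprintf("iteration %d: selected model has effective sample size %.2f (< 5) on its own stage",
                    t, ess_sel), call. = FALSE)

  report <- structure(
    list(t = t, records = records, cic_by_k = cic_by_k,
         selected_k = selected$k, selected_params = selected$params,
         rho_estimate = rho, rho_se = rho_stderr,
         ess_stage = ess(stage$weights), ess_selected = ess_sel,
         n_total = n_tot),
    class = "fit_report"
  )
  list(archive = archive, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("Iteration %d: selected k = %d, rho_hat = %.6g (ESS %.1f)\n",
              x$t, x$selected_k, x$rho_estimate, x$ess_stage))
  tab <- data.frame(
    k = vapply(x$records, function(r) r$k, 0L),
    d = vapply(x$records, function(r) r$d, 0L),
    ace = vapply(x$records, function(r) r$ace, 0),
    cic = vapply(x$records, function(r) r$cic, 0)
  )
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the component count minimizing the CIC
#'
#' @param cic_by_k named numeric vector of CIC values indexed by `k`.
#' @return the selected integer `k`; ties broken by the smallest `k`, and
#'   `+Inf` entries (failed fits) never selected. All-`Inf` input raises a
#'   fit-failure error.
#' @export
select_dimension <- function(cic_by_k) {
  if (!length(cic_by_k)) stop_invalid("empty CIC table")
  ks <- as.integer(names(cic_by_k))
  if (any(is.na(ks))) stop_invalid("`cic_by_k` must be named by integer k")
  ord <- order(ks)
  ks <- ks[ord]; v <- as.numeric(cic_by_k)[ord]
  if (all(!is.finite(v))) cic_error("cic_fit_failed", "no finite CIC value")
  ks[which.min(v)]
}

#' Approximate an unnormalized density and its normalizing constant
#'
#' Runs the full iterative procedure: iterations \eqn{t = 1..\tau} of
#' [run_stage()], each sampling from the previously selected model, then a
#' final sample of \eqn{n_\tau} points from the output model from which the
#' definitive normalizing-constant estimate \eqn{\hat\rho^{(\tau)}} is
#' formed over stages \eqn{1..\tau} (the initial stage is excluded, since
#' a poor initial proposal would inflate its variance).
#'
#' @param target an [unnorm_target].
#' @param config a [run_config].
#' @return an object of class `cic_fit`: `params` (the selected mixture),
#'   `rho` and `rho_se` (final estimate of the normalizing constant and its
#'   standard error), `rho_trajectory` (per-iteration estimates, final one
#'   last), `reports` (per-iteration [run_stage()] reports), `archive`,
#'   `r_evaluations`, `seed`.
#' @examples
#' tgt <- make_gmm_target(gmm_params(1, 0, 1), rho = 2)
#' cfg <- run_config(gmm_params(1, 0, 4), tau = 2, n_initial = 300,
#'                   n_stage = 300, k_grid = 1:2, seed = 7)
#' fit <- cic_approximate(tgt, cfg)
#' fit$rho
#' @export
cic_approximate <- function(target, config) {
  if (config$initial_params$p != target$p)
    stop_invalid("initial proposal dimension must match the target")
  archive <- sample_archive(list(), p = target$p)
  current <- config$initial_params
  reports <- vector("list", config$tau)
  prev_report <- NULL
  for (t in seq_len(config$tau)) {
    step <- run_stage(target, archive, current, config, t, previous = prev_report)
    archive <- step$archive
    reports[[t]] <- step$report
    prev_report <- step$report
    current <- step$report$selected_params
  }
  # final sample from the output model, used only for rho estimation
  n_final <- config$n_stage[config$tau]
  Xf <- rgmm(current, n_final, derive_seed(config$seed, config$tau + 1L, 0L, 1L))
  rf <- target_eval(target, Xf)
  lqf <- dgmm(current, Xf)
  archive <- add_stage(archive, stage_record(Xf, rf, lqf,
                                             stage_index = length(archive$stages)))
  final_stages <- setdiff(stage_subset(archive, NULL), 0L)
  rho_final <- rho_hat(archive, stages = final_stages)
  rho_stderr <- rho_se(archive, stages = final_stages)
  structure(
    list(params = current, rho = rho_final, rho_se = rho_stderr,
         rho_trajectory = c(vapply(reports, function(r) r$rho_estimate, 0), rho_final),
         selected_k = vapply(reports, function(r) r$selected_k, 0L),
         reports = reports, archive = archive,
         r_evaluations = n_evaluations(target), seed = config$seed),
    class = "cic_fit"
  )
}

#' @export
print.cic_fit <- function(x, ...) {
  cat("CIC-based density approximation\n")
  cat(sprintf("  iterations: %d   r evaluations: %d\n",
              length(x$reports), x$r_evaluations))
  cat(sprintf("  selected k per iteration: %s\n",
              paste(x$selected_k, collapse = " ")))
  cat(sprintf("  rho_hat = %.6g (se %.3g)\n", x$rho, x$rho_se))
  invisible(x)
}
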