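# Configuration parsing, result persistence and the command-line entry
# point (a thin wrapper installed as exec/cicapprox).

config_defaults <- list(
  tau = 7L, n_initial = 1000L, n_stage = 1000L, k_grid = 1:10,
  cumulative = TRUE, seed = 1L,
  em = list(max_iters = 500L, rel_tol = 1e-6, n_restarts = 4L, cov_floor = 1e-6)
)

#' Parse a run configuration from YAML or JSON
#'
#' Reads a configuration file (or literal text) describing the target
#' fixture and the run settings, validates it against the schema, fills
#' defaults (`tau = 7`, `n_initial = n_stage = 1000`, `k_grid = 1..10`,
#' `cumulative = true`, EM defaults) and rejects unknown keys by name.
#'
#' The `target` entry selects a fixture:
#' \describe{
#'   \item{gmm}{`weights`, `means`, `covariances`, `rho` — see
#'     [make_gmm_target()].}
#'   \item{indicator}{`b` and either `direction` or `p` (first-axis
#'     direction) — see [make_indicator_target()].}
#'   \item{posterior}{`prior_mean`, `prior_var`, `obs`, `obs_var` — see
#'     [make_conjugate_posterior_target()].}
#' }
#' The optional `initial` entry (`mean`, `sd`) sets the isotropic Gaussian
#' initial proposal; the default is mean 0, sd 3.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file, or a string of YAML.
#' @return list with elements `target` (an [unnorm_target]), `config`
#'   (a [run_config]) and `raw` (the parsed document).
#' @export
parse_config <- function(path) {
  doc <- tryCatch({
    if (file.exists(path)) {
      if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = TRUE)
      else yaml::read_yaml(path)
    } else {
      yaml::yaml.load(path)
    }
  }, error = function(e) cic_error("cic_config_error", conditionMessage(e)))
  if (!is.list(doc)) cic_error("cic_config_error", "configuration must be a mapping")
  known <- c("target", "initial", names(config_defaults))
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    cic_error("cic_config_error",
              paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  if (is.null(doc$target)) cic_error("cic_config_error", "missing `target` entry")

  target <- tryCatch(build_target(doc$target),
                     cic_invalid_argument = function(e)
                       cic_error("cic_config_error", conditionMessage(e)))
  cfg <- utils::modifyList(config_defaults, doc[setdiff(names(doc), c("target", "initial"))])
  em_known <- names(config_defaults$em)
  em_unknown <- setdiff(names(cfg$em), em_known)
  if (length(em_unknown))
    cic_error("cic_config_error",
              paste("unknown em key(s):", paste(em_unknown, collapse = ", ")))
  init <- doc$initial
  init_mean <- if (!is.null(init$mean)) as.numeric(init$mean) else rep(0, target$p)
  if (length(init_mean) == 1L) init_mean <- rep(init_mean, target$p)
  init_sd <- if (!is.null(init$sd)) as.numeric(init$sd) else 3
  initial_params <- gmm_params(1, matrix(init_mean, 1L),
                               list(diag(init_sd^2, target$p)))
  config <- tryCatch(
    run_config(
      initial_params = initial_params, tau = cfg$tau,
      n_initial = cfg$n_initial, n_stage = cfg$n_stage,
      k_grid = as.integer(cfg$k_grid),
      cumulative = cfg$cumulative, seed = cfg$seed,
      em_options = em_options(max_iters = cfg$em$max_iters,
                              rel_tol = cfg$em$rel_tol,
                              n_restarts = cfg$em$n_restarts,
                              seed = cfg$seed, cov_floor = cfg$em$cov_floor)
    ),
    cic_invalid_argument = function(e) cic_error("cic_config_error", conditionMessage(e))
  )
  list(target = target, config = config, raw = doc)
}

build_target <- function(spec) {
  if (is.null(spec$type)) cic_error("cic_config_error", "target needs a `type`")
  switch(as.character(spec$type),
    gmm = {
      covs <- spec$covariances
      if (is.array(covs) && length(dim(covs)) == 3L)
        covs <- lapply(seq_len(dim(covs)[1L]), function(j) as.matrix(covs[j, , ]))
      params <- gmm_params(spec$weights,
                           if (is.null(dim(spec$means))) as.numeric(spec$means)
                           else as.matrix(spec$means),
                           covs)
      make_gmm_target(params, spec$rho %||% 1)
    },
    indicator = {
      dir <- spec$direction
      if (is.null(dir)) {
        p <- spec$p %||% 2L
        dir <- c(1, rep(0, p - 1L))
      }
      make_indicator_target(dir / sqrt(sum(dir^2)), spec$b %||% 1.5)
    },
    posterior = make_conjugate_posterior_target(
      spec$prior_mean %||% 0, spec$prior_var %||% 1,
      spec$obs %||% cic_error("cic_config_error", "posterior target needs `obs`"),
      spec$obs_var %||% 1),
    cic_error("cic_config_error",
              sprintf("unknown target type '%s'", spec$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a finished run
#'
#' Writes three plain-text artifacts into `out_dir`: `results.json` (the
#' selected mixture, per-iteration CIC tables, the normalizing-constant
#' trajectory, evaluation count and seed), `samples.csv` (one row per
#' archived point: stage, coordinates, \eqn{r} value, proposal log-density,
#' weight) and `manifest.json` (the configuration echo, seed and package
#' version; re-running with the manifest's configuration and seed
#' reproduces `results.json` byte for byte).
#'
#' @param fit a `cic_fit` from [cic_approximate()].
#' @param raw_config the parsed configuration document to echo.
#' @param out_dir output directory, created if needed.
#' @return named character vector of the file paths written.
#' @export
write_results <- function(fit, raw_config, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2L) != 0L)
    cic_error("cic_io_error", sprintf("cannot write to '%s'", out_dir))
  results <- list(
    selected_params = list(
      weights = fit$params$weights, means = fit$params$means,
      covariances = fit$params$covariances
    ),
    rho_hat = fit$rho, rho_se = fit$rho_se,
    rho_trajectory = fit$rho_trajectory,
    stages = lapply(fit$reports, function(rep) list(
      t = rep$t, selected_k = rep$selected_k,
      cic_by_k = as.list(rep$cic_by_k),
      rho_hat = rep$rho_estimate, ess = rep$ess_stage
    )),
    r_evaluations = fit$r_evaluations, seed = fit$seed
  )
  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rows <- do.call(rbind, lapply(fit$archive$stages, function(st) {
    df <- as.data.frame(st$points)
    names(df) <- paste0("x_", seq_len(ncol(st$points)))
    cbind(stage = st$stage_index, df, r_value = st$r_values,
          proposal_log_density = st$proposal_log_density, weight = st$weights)
  }))
  csv_path <- file.path(out_dir, "samples.csv")
  utils::write.csv(rows, csv_path, row.names = FALSE)

  manifest <- list(config = raw_config, seed = fit$seed,
                   package_version = as.character(utils::packageVersion("cicapprox")),
                   files = list(results = "results.json", samples = "samples.csv"))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(results = res_path, samples = csv_path, manifest = man_path)
}

demo_configs <- list(
  gmm = paste(
    "target:",
    "  type: gmm",
    "  weights: [0.5, 0.5]",
    "  means: [-3.0, 3.0]",
    "  covariances: [1.0, 1.0]",
    "  rho: 3.0",
    "initial: {mean: 0.0, sd: 5.0}",
    "tau: 4", "n_initial: 1000", "n_stage: 1000", "k_grid: [1, 2, 3, 4, 5]",
    sep = "\n"),
  indicator = paste(
    "target: {type: indicator, b: 1.5, p: 2}",
    "initial: {mean: 0.0, sd: 3.0}",
    "tau: 5", "n_initial: 1000", "n_stage: 1000", "k_grid: [1, 2, 3]",
    sep = "\n"),
  posterior = paste(
    "target:",
    "  type: posterior",
    "  prior_mean: 0.0",
    "  prior_var: 4.0",
    "  obs: [1.2, 0.7, 1.9, 1.1, 0.4, 1.6, 0.9, 1.3]",
    "  obs_var: 1.0",
    "initial: {mean: 0.0, sd: 3.0}",
    "tau: 3", "n_initial: 1000", "n_stage: 1000", "k_grid: [1, 2, 3]",
    sep = "\n")
)

#' Command-line entry point
#'
#' Implements the `cicapprox` executable. Subcommands:
#' \describe{
#'   \item{approximate}{`--config <file> --out <dir> [--seed N] [--verbose]`
#'     — run the full procedure and write results.}
#'   \item{demo}{`--fixture gmm|indicator|posterior [--out <dir>]
#'     [--seed N]` — run a canned configuration and print the selected
#'     component count, the normalizing-constant estimate and the CIC
#'     table.}
#' }
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return integer exit code, invisibly: 0 on success, 2 on configuration
#'   errors, 3 on degenerate-support or fit failures.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: cicapprox approximate --config <file> --out <dir> [--seed N] [--verbose]\n",
        "       cicapprox demo --fixture {gmm|indicator|posterior} [--out <dir>] [--seed N]\n",
        sep = "")
  }
  if (!length(args)) { usage(); return(invisible(2L)) }
  sub <- args[[1L]]
  opts <- parse_cli_flags(args[-1L])
  if (inherits(opts, "condition")) {
    message("config error: ", conditionMessage(opts)); return(invisible(2L))
  }
  run <- function(parsed, out_dir, verbose) {
    fit <- cic_approximate(parsed$target, parsed$config)
    if (verbose || sub == "demo") {
      for (rep in fit$reports) print(rep)
    }
    cat(sprintf("selected k: %d\n", fit$selected_k[length(fit$selected_k)]))
    cat(sprintf("rho_hat: %.6g (se %.3g)\n", fit$rho, fit$rho_se))
    if (!is.null(out_dir)) {
      paths <- write_results(fit, parsed$raw, out_dir)
      cat("results written to", paths[["results"]], "\n")
    }
    0L
  }
  code <- tryCatch({
    if (sub == "approximate") {
      if (is.null(opts$config)) cic_error("cic_config_error", "--config is required")
      if (is.null(opts$out)) cic_error("cic_config_error", "--out is required")
      parsed <- parse_config(opts$config)
      if (!is.null(opts$seed)) {
        parsed$raw$seed <- opts$seed
        parsed <- reseed_parsed(parsed, opts$seed)
      }
      run(parsed, opts$out, isTRUE(opts$verbose))
    } else if (sub == "demo") {
      fx <- opts$fixture %||% "indicator"
      if (!fx %in% names(demo_configs))
        cic_error("cic_config_error", sprintf("unknown fixture '%s'", fx))
      parsed <- parse_config(demo_configs[[fx]])
      if (!is.null(opts$seed)) parsed <- reseed_parsed(parsed, opts$seed)
      run(parsed, opts$out, TRUE)
    } else {
      usage(); 2L
    }
  },
  cic_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
  cic_degenerate_support = function(e) { message("degenerate support: ", conditionMessage(e)); 3L },
  cic_fit_failed = function(e) { message("fit failed: ", conditionMessage(e)); 3L })
  invisible(as.integer(code))
}

reseed_parsed <- function(parsed, seed) {
  parsed$config$seed <- as.integer(seed)
  parsed$config$em_options$seed <- as.integer(seed)
  parsed$raw$seed <- as.integer(seed)
  parsed
}

parse_cli_flags <- function(args) {
  out <- list(verbose = FALSE)
  i <- 1L
  take <- function(i) {
    if (i + 1L > length(args))
      cic_error("cic_config_error", sprintf("flag %s needs a value", args[[i]]))
    args[[i + 1L]]
  }
  tryCatch({
    while (i <= length(args)) {
      a <- args[[i]]
      if (a == "--config") { out$config <- take(i); i <- i + 2L }
      else if (a == "--out") { out$out <- take(i); i <- i + 2L }
      else if (a == "--seed") { out$seed <- as.integer(take(i)); i <- i + 2L }
      else if (a == "--fixture") { out$fixture <- take(i); i <- i + 2L }
      else if (a == "--verbose") { out$verbose <- TRUE; i <- i + 1L }
      else cic_error("cic_config_error", sprintf("unknown flag '%s'", a))
    }
    out
  }, cic_config_error = function(e) e)
}
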