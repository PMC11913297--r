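# Internal utilities: classed errors, deterministic seed streams, log-sum-exp.

cic_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "cic_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid <- function(msg) cic_error("cic_invalid_argument", msg)
stop_degenerate <- function(msg) cic_error("cic_degenerate_support", msg)

#' Derive a deterministic sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed through
#' independent streams keyed by integer labels (stage, component count,
#' restart, purpose), so that e.g. enlarging the component grid does not
#' perturb the random stream of any other fit. The mixer is a
#' SplitMix-style integer hash reduced modulo 2^31 - 1.
#'
#' @param root integer root seed.
#' @param ... further integer keys identifying the stream.
#' @return an integer between 1 and 2^31 - 2, usable with [set.seed()].
#' @export
derive_seed <- function(root, ...) {
  keys <- c(as.numeric(root), vapply(list(...), as.numeric, 0))
  h <- 0
  m <- 2147483629 # prime < 2^31
  for (k in keys) {
    h <- (h * 48271 + (k %% m) + 11) %% m
    # extra mixing round
    h <- (h * 69621 + 1013904223 %% m) %% m
  }
  as.integer(h %% (2^31 - 2) + 1)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never disturb the global stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-wise log(sum(exp(.))) that tolerates -Inf entries.
row_logsumexp <- function(L) {
  k <- ncol(L)
  m <- L[, 1L]
  if (k > 1L) for (j in 2L:k) m <- pmax(m, L[, j])
  out <- rep(-Inf, nrow(L))
  fin <- which(is.finite(m))
  if (length(fin)) {
    # column recycling subtracts m[fin] from every column
    out[fin] <- m[fin] + log(rowSums(exp(L[fin, , drop = FALSE] - m[fin])))
  }
  out
}

as_points_matrix <- function(points, p) {
  if (is.null(dim(points))) {
    if (p == 1L) points <- matrix(points, ncol = 1L)
    else stop_invalid("`points` must be a matrix with one column per dimension")
  }
  points <- as.matrix(points)
  if (ncol(points) != p)
    stop_invalid(sprintf("`points` has %d columns but the model dimension is %d",
                         ncol(points), p))
  if (!all(is.finite(points))) stop_invalid("`points` must be finite")
  storage.mode(points) <- "double"
  points
}
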