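`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that package functions never
#' leak random-state side effects into the user's session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # force initialization so we have a state to restore
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop_param("`%s` must be a single positive integer (got %s)", name,
               paste(format(x), collapse = ", "))
  as.integer(x)
}

#' @noRd
cpg_ids <- function(m) sprintf("cpg%04d", seq_len(m))

#' @noRd
sample_ids <- function(n) sprintf("s%04d", seq_len(n))

#' @noRd
celltype_ids <- function(k) sprintf("CT%d", seq_len(k))
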