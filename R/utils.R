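# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded internals
#' (random reference graphs, simulators) never disturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Canonical unordered edge keys "<i>|<j>" with i < j (cell-id order).
edge_keys <- function(i, j) {
  a <- pmin(i, j)
  b <- pmax(i, j)
  paste(a, b, sep = "|")
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Mean degree of an edge count m on N nodes.
kavg_of <- function(m, n) 2 * m / n
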