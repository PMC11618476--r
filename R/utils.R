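# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so every generator is a pure function of its arguments.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Smallest p-value kept before conversion to z; avoids infinite quantiles
# while preserving ordering.
.P_FLOOR <- 1e-300

floor_p <- function(p, floor = .P_FLOOR) pmax(p, floor)

#' Stop unless a condition holds
#' @noRd
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Align named vectors/matrices on a common gene set
#'
#' @param ... named vectors (names are gene ids).
#' @return character vector of gene ids present in every input, in the order
#'   of the first input.
#' @noRd
intersect_genes <- function(...) {
  ids <- lapply(list(...), function(x) {
    if (is.matrix(x) || is.data.frame(x)) rownames(x) else names(x)
  })
  out <- Reduce(intersect, ids)
  if (length(out) == 0L) stop("no genes shared between inputs")
  out
}
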