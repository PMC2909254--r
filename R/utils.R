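#' @useDynLib ecmphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rexp rnorm rbinom runif optim pf cophenetic setNames
#'   quantile cmdscale dist isoreg sd
#' @importFrom utils read.delim write.table combn head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' If `seed` is `NULL` the expression draws from the current RNG stream
#' (so that a pipeline seeded once stays on a single stream); otherwise the
#' global RNG state is saved, `set.seed(seed)` applied, and the state
#' restored afterwards.
#'
#' @param seed integer or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

stop_ecm <- function(...) stop(..., call. = FALSE)

is_binary01 <- function(x) all(x %in% c(0L, 1L))
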