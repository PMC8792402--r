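# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded operations never perturb the global stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- utf8ToInt(key)
  s <- 0
  for (v in h) s <- (s * 31 + v) %% 2147483647
  as.integer(s)
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name))
  invisible(x)
}

# numeric matrix coercion with dimension checks
as_num_matrix <- function(x, name = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("%s must be a numeric matrix", name))
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("%s contains missing or non-finite values", name))
  x
}
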