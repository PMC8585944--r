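# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded simulators do not
#' perturb the global random stream. With `seed = NULL` the expression runs
#' on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# scalar checks used by the parameter constructors
checkScalar <- function(x, name, lower = -Inf, upper = Inf,
                        strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}
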