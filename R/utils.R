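# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not disturb the
#' caller's random stream. A `NULL` seed evaluates the code as-is.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic lexicographic sort independent of the user's locale.
lex_sort <- function(x) sort(x, method = "radix")

lex_order <- function(...) order(..., method = "radix")

stop_promreg <- function(...) stop(..., call. = FALSE)

# Format a number for TSV reports: full double precision, stable across runs.
fmt_num <- function(x) sprintf("%.15g", x)
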