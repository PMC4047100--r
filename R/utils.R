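# Internal helpers shared across modules.

# Unit convention: voltages mV, currents pA, resistances megaohm, time ms at
# user surfaces / seconds on the trace grid. V = I * R needs pA * MOhm * 1e-3
# to come out in mV; the constant lives here and nowhere else.
MV_PER_PA_MOHM <- 1e-3

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generation never disturbs
#' the caller's RNG stream. A `NULL` seed evaluates the expression as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic seed splitting: child seeds derived from a parent seed and an
# index, kept inside the 32-bit signed range R requires.
seed_child <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483587 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
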