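## internal helpers -----------------------------------------------------------

mibci_stop <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x))
    mibci_stop(sprintf("`%s` must be a positive integer (got %s)", name,
                       paste(format(x), collapse = ", ")))
  as.integer(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    mibci_stop(sprintf("`%s` must be a number in [%s, %s]", name, lower, upper))
  as.numeric(x)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's RNG afterwards. All randomised operations in the package go
## through this so that seeds are local and reproducible.
with_seed <- function(seed, expr) {
  seed <- check_count(seed + 1L, "seed") - 1L # allow 0
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## numerically safe log cosh
log_cosh <- function(x) {
  ax <- abs(x)
  ifelse(ax > 20, ax - log(2), log(cosh(x)))
}

## E[log cosh Z] for Z ~ N(0,1), by quadrature (frozen to double precision)
LOGCOSH_GAUSS <- 0.374567207491

`%||%` <- function(a, b) if (is.null(a)) b else a
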