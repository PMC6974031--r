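#' @importFrom stats rnorm runif rbinom qnorm pnorm pt pf cor sd var coef
#' @importFrom stats binom.test filter setNames
#' @importFrom utils modifyList head tail
NULL

# Validation failures are signalled with a dedicated condition class so that
# callers (and the CLI) can distinguish bad inputs from programming errors.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("precon_validation_error", "error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stream-specific RNG seed from a master seed. Keeps every derived
# seed a valid 32-bit integer (R integers are 32-bit).
derive_seed <- function(master, ...) {
  key <- paste(c(master, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

unit_vector <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) abort_validation("cannot normalize a zero vector")
  x / n
}
.datatable.aware <- TRUE
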