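# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a private RNG stream
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so simulator determinism never perturbs user code.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# repr-level float formatting: shortest string that round-trips a double
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (digits in 1:17) {
      s <- formatC(v, digits = digits, format = "g")
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g")
  }, character(1))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
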