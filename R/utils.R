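# Internal helpers shared across the package.

# Structured error so callers (and tests) can catch specific failure modes,
# e.g. class "fmisopet_invalid_spec".
fp_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("fmisopet_", class), "fmisopet_error")))
}

fp_assert <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) fp_stop(class, msg, ...)
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} under \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded simulations do not disturb the global stream.
#' A \code{NULL} seed leaves the RNG untouched.
#'
#' @param seed Integer seed or \code{NULL}.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# scalar finite positive check
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
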