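# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so generators are reproducible without clobbering the
#' caller's random stream. With `seed = NULL` the code runs on the current
#' stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# Derive a distinct child seed from a base seed, kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}

stop_ap <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(code, "alpinepheno_error", "error", "condition"),
                    list(message = msg, call = sys.call(-1)))
  stop(cond)
}

warn_ap <- function(code, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(code, "alpinepheno_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1)))
  warning(cond)
}

#' Day of year for a calendar date
#'
#' @param date a `Date` or string coercible to one.
#' @return integer day of year (1--366).
#' @examples doy_of("2021-02-18")
#' @export
doy_of <- function(date) as.integer(strftime(as.Date(date), "%j"))
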