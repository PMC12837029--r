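#' Evaluate code with a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so library functions never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed from a master seed
#'
#' Stages of a workflow each get their own stream so that rerunning one
#' stage does not disturb the others. The derivation hashes
#' (master seed, label) into a 31-bit integer.
#'
#' @param master integer master seed.
#' @param label character tag naming the stage / repetition.
#' @return integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(length(master) == 1L, is.finite(master))
  bytes <- utf8ToInt(paste0(format(as.integer(master)), "/", label))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
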