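# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
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

#' Derive a child seed from a master seed and a stream label
#'
#' Deterministic fan-out of one master seed into independent per-stage and
#' per-contact seeds. A simple polynomial string hash modulo a Mersenne prime
#' keeps results inside the 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param ... character or numeric stream labels (e.g. "cv", contact name).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' childSeed(1, "epochs")
#' childSeed(1, "cv", "CH01", "arabic")
childSeed <- function(seed, ...) {
  toks <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = "|"),
                       character(1)), collapse = "/")
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(toks)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 2) + 1)
}

# single-string scalar check
isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# scalar finite numeric check
isNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
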