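# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded draws inside the package never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic stream-splitting: derive a child seed from a root seed and a
# sequence of keys (integers or strings).  Strings are folded by a small
# polynomial hash; everything is kept inside 32-bit integer range.
derive_seed <- function(root, ...) {
  m <- 2147483629  # prime < 2^31
  h <- as.numeric(root) %% m
  for (key in list(...)) {
    if (is.character(key)) {
      for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% m
    } else {
      h <- (h * 131 + as.numeric(key) %% m) %% m
    }
  }
  as.integer(h)
}

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
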