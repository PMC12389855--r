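# shared internal helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded draws inside the package never
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  force(seed) # before saving state: a lazily evaluated seed expression may draw
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a named sub-seed from a root seed
#'
#' One root seed fans out to reproducible, well-separated sub-seeds for the
#' independent randomness sources (data, weight init, per-step noise, ...) via
#' a small counter/string hash. Results stay in `[1, 2^31 - 2]`.
#'
#' @param root integer root seed.
#' @param ... labels (strings or integers) identifying the consumer.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "noise", 3)
derive_seed <- function(root, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- (as.double(root) %% 2147483647)
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_same_shape <- function(x, y, what = "inputs") {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(y)))) {
    stop_("%s must have identical dimensions (got %s vs %s)", what,
          paste(dim(as.matrix(x)), collapse = "x"),
          paste(dim(as.matrix(y)), collapse = "x"))
  }
  invisible(TRUE)
}

is_binary <- function(m) all(m %in% c(0, 1))
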