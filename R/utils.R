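# Internal helpers shared across modules.

# Evaluate expr under a local RNG state; the caller's .Random.seed is
# restored afterwards so seeded package functions never clobber the
# session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Derive a stream seed from a master seed
#'
#' Counter-based derivation: the result depends only on `(seed, index)`,
#' never on execution order, so batches and repetitions are reproducible
#' even if run out of order or in parallel. All arithmetic stays below
#' 2^53 and the result below 2^31 (a valid R integer seed).
#'
#' @param seed Master seed (integer).
#' @param index Non-negative counter.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, index) {
  x <- (abs(as.double(seed)) %% 2147483647) + 1
  y <- (x * 69069 + as.double(index) * 2246822519 + 1013904223) %% 2147483629
  as.integer(y + 1)
}

# Validate a single positive integer-ish scalar.
check_count_arg <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

arc_key <- function(from, to) paste(from, to, sep = "\r")
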