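#' @import data.table
#' @importFrom stats rbinom runif rnorm setNames aggregate
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a run seed and a stream name
#'
#' All randomness in the package flows from one user-supplied seed; each
#' sub-generator (surnames, corruption, event dates, ...) draws from its own
#' named substream so adding a generator never perturbs the draws of another.
#' The sub-seed is a deterministic 31-bit hash of the seed and the name.
#'
#' @param seed integer run seed.
#' @param stream character name of the substream.
#' @return an integer seed in [0, 2^31).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (cc in utf8ToInt(stream)) {
    # 31-bit multiplicative string hash (Park-Miller modulus)
    h <- (h * 131 + cc) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state seeded from (seed, stream);
# restores the caller's RNG state afterwards.
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  set.seed(substream_seed(seed, stream))
  expr
}

# Missing marker used throughout: "" in files, NA internally for dates.
is_missing_chr <- function(x) is.na(x) | x == ""

# Round half up (the tables' presentation convention; R's round() is
# half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
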