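#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm runif sd var setNames
#' @importFrom utils head tail
NULL

# Run code with a locally derived RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() without the scalar-x surprise (sample(5L) != draw from {5})
sample_from <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size = size, replace = replace)]
}

assert_that <- function(ok, msg, class = "comafusion_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}
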