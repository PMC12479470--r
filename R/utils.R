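## Internal helpers.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Derive a deterministic per-stage child seed
#'
#' Hashes a stage name into the global seed so that every pipeline stage gets
#' its own reproducible stream and adding a stage never perturbs the streams
#' of earlier stages. The result always fits in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (character scalar).
#' @return Integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}
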