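#' Derive a named RNG substream seed from a master seed
#'
#' All stochasticity in a run flows from one master seed through named
#' substreams (reset, restock, scheduler, learner, probe, ...), so that e.g.
#' adding probe episodes does not perturb the training stream. The derivation
#' is a small deterministic integer hash of (seed, stream name); results stay
#' below 2^31 so they are valid R seeds.
#'
#' @param seed integer master seed.
#' @param stream character scalar naming the substream.
#' @param index optional nonnegative integer (e.g. episode counter) mixed in.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1, "probe", 3)
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed %% 2147483647)
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + as.double(index) %% 2147483647) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a fixed RNG seed, restoring the global RNG state
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
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
  })
  set.seed(seed)
  force(code)
}
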