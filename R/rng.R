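#' Derive a per-stage seed from a global seed
#'
#' Expands one user-facing seed into reproducible substreams, one per labelled
#' pipeline stage, so that stages rerun in isolation (packaging, growth,
#' sequencing, ...) see the same random numbers as in a full run.
#'
#' @param seed Integer global seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @examples
#' substream_seed(1L, "packaging")
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (code in utf8ToInt(label)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 7919) %% 2147483647)
}

#' Evaluate an expression under a labelled substream
#'
#' Sets the RNG to the substream seed, evaluates `expr`, and restores the
#' caller's RNG state afterwards.
#'
#' @param seed,label Passed to [substream_seed()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  expr
}
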