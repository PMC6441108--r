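#' Derive a stage-specific seed from a root seed
#'
#' Each pipeline stage draws from its own substream keyed by a stage name,
#' so adding or reordering stages never perturbs another stage's output.
#'
#' @param seed integer root seed.
#' @param stage character stage name.
#' @return integer seed below 2^31.
#' @export
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

## Evaluate expr under a derived stage seed, restoring the caller's RNG
## state afterwards.
withStageSeed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(deriveSeed(seed, stage))
  expr
}
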