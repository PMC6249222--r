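#' Derive a stage-specific seed from a global seed
#'
#' Pipeline stages draw their own random numbers; deriving each stage's seed
#' from one global seed plus the stage name keeps every stage individually
#' rerunnable while the whole run stays deterministic.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # keep arithmetic in doubles; result must fit a 32-bit integer
  as.integer((abs(seed) * 69069 + h * 362437 + 1) %% (2^31 - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}
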