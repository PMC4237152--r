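#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline each consume an independent random stream. The
#' per-stage seed is a stable polynomial hash of the stage name folded into
#' the global seed, so adding or reordering stages never perturbs the seeds
#' of other stages. The result is always a valid 32-bit R integer.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "diversity")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% 2147483647L)
  expr
}

abort_ctx <- function(..., call. = FALSE) stop(..., call. = call.)
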