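#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from one master seed and the stage name, so that re-running a single stage
#' can never perturb the random stream of any other stage.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31)`.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 69069 + h * 1013904223) %% 2147483647)
}

# run expr under a fixed seed without disturbing the caller's RNG state;
# seed = NULL means "use the current stream"
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_np <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_np <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
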