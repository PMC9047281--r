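#' Derive a stage-specific RNG seed from a master seed
#'
#' Every stochastic stage of a simulation run (base sequence, per-family
#' copy mutation, placement) draws from its own stream, seeded
#' deterministically from the single master seed in the configuration.
#' This keeps stages independently replayable: regenerating the base
#' sequence alone gives the same bases as a full run.
#'
#' @param master integer master seed.
#' @param stage character label of the stage (e.g. `"base"`,
#'   `"copies/AluY"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code))
  # multiplier kept small so the product stays exactly representable in a double
  s <- ((abs(master) %% 2147483647) * 69069 + h) %% 2147483647
  as.integer(s)
}
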