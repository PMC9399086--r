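#' Derive a stage/unit seed from a master seed
#'
#' All randomness in the package flows from a single master seed; per-stage
#' and per-unit (agent, session, chain) seeds are derived by a fixed integer
#' hash so any single unit can be re-simulated in isolation. The rule is
#' `(master * 69069 + hash(stage) * 10007 + index * 7919) mod (2^31 - 1)`,
#' where `hash(stage)` is the sum of the stage label's character codes.
#' Arithmetic stays below 2^53 so the result is exact in double precision.
#'
#' @param master Master integer seed.
#' @param stage Character stage label (e.g. `"session"`, `"chain"`).
#' @param index Integer unit index within the stage.
#' @return An integer seed in `[1, 2^31 - 1)`.
#' @export
split_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)))
  x <- (abs(master) %% 2147483647) * 69069 + h * 10007 + index * 7919
  as.integer(x %% 2147483646) + 1L
}

#' Seed the RNG for the calling frame, restoring global state on exit
#' @param seed Integer seed.
#' @param env Frame whose exit restores the previous RNG state.
#' @keywords internal
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

#' Round to whole cents
#' @keywords internal
round_money <- function(x) round(x, 2)
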