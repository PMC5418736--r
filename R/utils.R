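# Seeding helpers. All stochastic entry points take an explicit seed and
# restore the caller's RNG state, so package calls never perturb a user's
# simulation stream.

with_seed <- function(seed, expr) {
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
  expr
}

# Derive a stable component sub-seed from a master seed and a component
# name (splitmix-style). Adding a new component never perturbs the streams
# of existing ones. Kept below 2^31 - 1 so it is a valid R integer seed.
component_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
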