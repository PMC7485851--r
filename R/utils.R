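# Internal helpers: error conditions and local RNG scoping.

aureaValidationError <- function(msg, ...) {
  stop(structure(class = c("aurea_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

aureaIOError <- function(msg, ...) {
  stop(structure(class = c("aurea_io_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# All stochastic package code routes through this, so a caller-supplied seed
# fully determines the output.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
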