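# Internal helpers: classed conditions and reproducible local RNG.

# Condition constructors.  Three classes map onto the CLI exit codes:
#   cwqsar_input_error   -> 2 (bad files / tables / SMILES)
#   cwqsar_config_error  -> 3 (bad parameters, impossible set-up)
#   cwqsar_numeric_error -> 4 (degenerate numerics: zero variance etc.)
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("cwqsar_input_error", "cwqsar_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("cwqsar_config_error", "cwqsar_error")))
}

stop_numeric <- function(...) {
  stop(errorCondition(paste0(...), class = c("cwqsar_numeric_error", "cwqsar_error")))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.  All seeded operations in the package go through this.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_config("seed must be a single finite number")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive `n` sub-seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Decimal text representation that round-trips doubles exactly.
format_full <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}
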