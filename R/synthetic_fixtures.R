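# Synthetic SMILES-like datasets with a planted additive endpoint.
#
# The generator emulates exactly the statistical structure the model
# assumes — an endpoint affine in a sum of per-attribute contributions —
# on grammar-generated, chemistry-free strings: chains of atoms with
# optional branches, optional double-bond marks and one optional ring
# closure.  Every generated string is tokenizable and balanced; nothing
# about chemical validity is claimed or needed, since the method consults
# only token statistics.

.default_true_weights <- c(
  "C" = 0.1, "c" = 0.2, "O" = -0.8, "N" = -0.6, "S" = 1.5,
  "=" = -0.7, "(" = -0.1, "1" = 0.4, "Cl" = 0.6,
  "O|=" = -0.5, "C|=" = -0.3, "c|c" = 0.2, "S|C" = 0.5, "c|1" = 0.15
)

#' Specification for the synthetic dataset generator
#'
#' Defaults define the package's reference benchmark: 300 compounds over
#' a 9-token alphabet, 10-30 tokens long, endpoint
#' `c0 + c1 * DCW_true + N(0, noise_sd)` with planted weights whose signs
#' mirror typical promoter patterns (sulfur and cycles up, oxygen,
#' nitrogen and double bonds down) and whose magnitudes span the blocked
#' /recoverable range.
#'
#' @param n_compounds Number of records (default 300).
#' @param token_alphabet Tokens the grammar may emit (default
#'   `C c O N S = ( 1 Cl`).
#' @param length_range Target token count range per compound.
#' @param true_weights Named vector of planted attribute weights; pair
#'   keys use the canonical `"a|b"` form.
#' @param c0_true,c1_true Affine map from the planted descriptor sum to
#'   the endpoint.
#' @param noise_sd Gaussian noise SD on the endpoint (default 0.1).
#' @param seed RNG seed (default 1).
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_compounds = 300L,
                           token_alphabet = c("C", "c", "O", "N", "S", "=", "(", "1", "Cl"),
                           length_range = c(10L, 30L),
                           true_weights = .default_true_weights,
                           c0_true = -0.5, c1_true = 0.4,
                           noise_sd = 0.1, seed = 1L) {
  if (n_compounds < 1) stop_config("n_compounds must be positive")
  if (length(length_range) != 2L || length_range[1] < 3L || length_range[2] < length_range[1]) {
    stop_config("length_range must be an increasing pair with minimum >= 3")
  }
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (is.null(names(true_weights))) stop_config("true_weights must be named by attribute key")
  structure(list(n_compounds = as.integer(n_compounds),
                 token_alphabet = token_alphabet,
                 length_range = as.integer(length_range),
                 true_weights = true_weights,
                 c0_true = c0_true, c1_true = c1_true,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

# One grammar-generated string: chain of atoms with optional one-atom
# branches, '=' marks always preceding an atom, and at most one ring
# digit pair.  Returns the SMILES text.
.generate_smiles <- function(len, alphabet) {
  atoms <- setdiff(alphabet, c("=", "(", ")", as.character(0:9)))
  if (length(atoms) == 0L) stop_config("alphabet has no atom tokens")
  has <- function(tok) tok %in% alphabet
  pick_atom <- function() sample(atoms, 1)
  out <- pick_atom()
  count <- 1L
  ring_open <- FALSE
  ring_used <- FALSE
  while (count < len) {
    r <- stats::runif(1)
    left <- len - count
    if (r < 0.15 && has("(") && left >= 3L) {
      out <- c(out, "(", pick_atom(), ")")
      count <- count + 3L
    } else if (r < 0.30 && has("=") && left >= 2L) {
      out <- c(out, "=", pick_atom())
      count <- count + 2L
    } else if (r < 0.38 && has("1") && !ring_used) {
      out <- c(out, "1")
      count <- count + 1L
      if (ring_open) ring_used <- TRUE
      ring_open <- !ring_open
    } else {
      out <- c(out, pick_atom())
      count <- count + 1L
    }
  }
  if (ring_open) out <- c(out, "1")
  paste(out, collapse = "")
}

#' Generate a synthetic dataset with a planted additive endpoint
#'
#' @param spec A [generator_spec()].
#' @return A `qsar_dataset` (set labels `unassigned`) with attributes
#'   `"true_weights"`, `"true_dcw"` (the noiseless descriptor sums) and
#'   `"spec"` attached for recovery scoring.
#' @export
generate_dataset <- function(spec = generator_spec()) {
  if (!inherits(spec, "generator_spec")) stop_input("spec must be a generator_spec")
  local_seed(spec$seed, {
    lens <- sample(seq(spec$length_range[1], spec$length_range[2]),
                   spec$n_compounds, replace = TRUE)
    smiles <- vapply(lens, .generate_smiles, "", alphabet = spec$token_alphabet)
    true_dcw <- vapply(smiles, function(s) as.numeric(compute_dcw(s, spec$true_weights)),
                       0, USE.NAMES = FALSE)
    endpoint <- spec$c0_true + spec$c1_true * true_dcw +
      stats::rnorm(spec$n_compounds, 0, spec$noise_sd)
    ds <- suppressWarnings(qsar_dataset(
      id = sprintf("syn%04d", seq_len(spec$n_compounds)),
      smiles = smiles, endpoint = endpoint))
    attr(ds, "true_weights") <- spec$true_weights
    attr(ds, "true_dcw") <- true_dcw
    attr(ds, "spec") <- spec
    ds
  })
}
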