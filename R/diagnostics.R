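# Applicability domain by statistical defects of SMILES attributes, and
# mechanistic interpretation by promoter extraction.
#
# The statistical defect of an attribute measures how unevenly it is
# distributed across the active training, passive training and
# calibration blocks:
#
#   d_k = |P - P'|/(N + N') + |P - P''|/(N + N'') + |P' - P''|/(N' + N'')
#
# with P the per-block compound fraction and N the per-block compound
# count of the attribute.  A compound's defect D_j sums d_k over its
# non-blocked attribute occurrences; a compound is inside the domain iff
# D_j < 2 * mean(D_j over the training population).

#' Statistical defect of one attribute
#'
#' @param key Attribute key present in the dictionary.
#' @param dictionary An [build_attribute_dictionary()] result.
#' @return The defect `d_k >= 0`; 0 (with a warning) for an attribute
#'   absent from all three training-type blocks.
#' @export
statistical_defect <- function(key, dictionary) {
  i <- match(key, dictionary$key)
  if (is.na(i)) stop_input("attribute '", key, "' not in dictionary")
  sizes <- attr(dictionary, "block_sizes")
  if (is.null(sizes)) stop_input("dictionary lacks block sizes; rebuild with build_attribute_dictionary()")
  counts <- c(dictionary$n_active[i], dictionary$n_passive[i], dictionary$n_calibration[i])
  if (all(counts == 0)) {
    warning("attribute '", key, "' absent from active, passive and calibration blocks; defect 0")
    return(0)
  }
  defect_from_counts(counts, sizes[c("active", "passive", "calibration")])
}

# counts, sizes: length-3 vectors (active, passive, calibration).
defect_from_counts <- function(counts, sizes) {
  P <- ifelse(sizes > 0, counts / sizes, 0)
  term <- function(a, b) {
    if (counts[a] + counts[b] == 0) return(0)
    abs(P[a] - P[b]) / (counts[a] + counts[b])
  }
  term(1, 2) + term(1, 3) + term(2, 3)
}

# Vector of defects for every dictionary attribute (blocked included,
# since Eq-14 sums run over non-blocked ones only; callers filter).
attribute_defects <- function(dictionary, sizes) {
  vapply(seq_len(nrow(dictionary)), function(i) {
    counts <- c(dictionary$n_active[i], dictionary$n_passive[i], dictionary$n_calibration[i])
    if (all(counts == 0)) 0 else defect_from_counts(counts, sizes)
  }, 0)
}

#' Statistical defect of one compound
#'
#' Sums the per-attribute defects over every non-blocked attribute
#' occurrence of the SMILES (an attribute occurring twice contributes its
#' defect twice, consistent with per-occurrence descriptor summation).
#' Attributes missing from the defect table contribute 0.
#'
#' @param smiles A SMILES string.
#' @param defects Named numeric vector of per-attribute defects (blocked
#'   attributes excluded).
#' @return `D_j >= 0`, with a warning when every attribute of the
#'   compound is blocked/unknown.
#' @export
compound_defect <- function(smiles, defects) {
  counts <- attribute_counts(smiles)
  known <- intersect(names(counts), names(defects))
  if (length(known) == 0L) {
    warning("all attributes of '", smiles, "' are blocked or unknown; D_j = 0")
    return(0)
  }
  sum(counts[known] * defects[known])
}

#' Applicability-domain membership
#'
#' A compound is inside the domain iff its defect is strictly below twice
#' the mean training defect: `D_j < 2 * D_bar`.  With `D_bar = 0`
#' (degenerate, perfectly uniform data) no compound satisfies the strict
#' inequality and everything is flagged out, with a warning.
#'
#' @param d_j Compound defect(s).
#' @param d_bar Mean defect of the training population.
#' @return Logical vector.
#' @export
in_domain <- function(d_j, d_bar) {
  if (d_bar < 0) stop_config("d_bar must be non-negative")
  if (d_bar == 0) warning("degenerate domain: D_bar = 0, all compounds flagged out")
  d_j < 2 * d_bar
}

# Defect table and training-mean defect for a labeled dataset.  The
# reference population for D_bar is active + passive + calibration, the
# three blocks that define the defects themselves.
domain_reference <- function(dataset, dictionary) {
  dataset <- as_qsar_dataset(dataset)
  sizes <- c(active = sum(dataset$set == "active"),
             passive = sum(dataset$set == "passive"),
             calibration = sum(dataset$set == "calibration"))
  dk <- attribute_defects(dictionary, sizes)
  keep <- !dictionary$blocked
  defects <- data.frame(key = dictionary$key[keep], d_k = dk[keep],
                        stringsAsFactors = FALSE)
  dvec <- stats::setNames(defects$d_k, defects$key)
  train <- dataset$set %in% c("active", "passive", "calibration")
  d_j <- vapply(dataset$smiles[train], function(s)
    suppressWarnings(compound_defect(s, dvec)), 0, USE.NAMES = FALSE)
  list(defects = defects, d_bar = mean(d_j))
}

#' Applicability-domain report for a dataset
#'
#' @param dataset A labeled `qsar_dataset`.
#' @param dictionary The matching attribute dictionary.
#' @return Data frame `id, smiles, set, d_j, in_domain`, with `d_bar`
#'   and the threshold `2 * d_bar` as attributes.
#' @export
domain_report <- function(dataset, dictionary) {
  dataset <- as_qsar_dataset(dataset)
  ref <- domain_reference(dataset, dictionary)
  dvec <- stats::setNames(ref$defects$d_k, ref$defects$key)
  d_j <- vapply(dataset$smiles, function(s)
    suppressWarnings(compound_defect(s, dvec)), 0, USE.NAMES = FALSE)
  out <- data.frame(id = dataset$id, smiles = dataset$smiles, set = dataset$set,
                    d_j = d_j, in_domain = in_domain(d_j, ref$d_bar),
                    stringsAsFactors = FALSE)
  attr(out, "d_bar") <- ref$d_bar
  attr(out, "threshold") <- 2 * ref$d_bar
  out
}

#' Extract endpoint promoters from repeated optimization runs
#'
#' An attribute is a stable promoter when its correlation weight keeps
#' one sign (and stays nonzero) across every run of a series of
#' independent Monte Carlo optimizations: all positive means it promotes
#' an increase of the endpoint, all negative a decrease.  Only attributes
#' occurring in at least `min_frequency` compounds of each of the active,
#' passive and calibration blocks are reported, sorted by active-block
#' frequency.
#'
#' @param runs List of at least 3 named weight vectors (from repeated
#'   [optimize_weights()]/[fit_qsar_model()] runs with different seeds).
#' @param dictionary The shared attribute dictionary.
#' @param min_frequency Minimum per-block compound count (default 10).
#' @return Data frame `role, key, render, run weights..., n_active,
#'   n_passive, n_calibration, d_k`, sorted by role then `n_active`
#'   descending.
#' @export
extract_promoters <- function(runs, dictionary, min_frequency = 10L) {
  if (length(runs) < 3L) stop_config("promoter extraction needs at least 3 runs")
  keys <- dictionary$key
  W <- sapply(runs, function(w) {
    if (is.null(names(w))) stop_input("run weights must be named")
    out <- rep(0, length(keys))
    hit <- intersect(names(w), keys)
    out[match(hit, keys)] <- w[hit]
    out
  })
  all_pos <- apply(W > 0, 1, all)
  all_neg <- apply(W < 0, 1, all)
  frequent <- dictionary$n_active >= min_frequency &
    dictionary$n_passive >= min_frequency &
    dictionary$n_calibration >= min_frequency
  role <- ifelse(all_pos, "increase", ifelse(all_neg, "decrease", "unstable"))
  keep <- frequent & role != "unstable" & !dictionary$blocked
  sizes <- attr(dictionary, "block_sizes")
  dk <- if (!is.null(sizes)) {
    attribute_defects(dictionary, sizes[c("active", "passive", "calibration")])
  } else rep(NA_real_, length(keys))
  out <- data.frame(role = role[keep], key = keys[keep],
                    render = dictionary$render[keep],
                    stringsAsFactors = FALSE)
  runw <- W[keep, , drop = FALSE]
  colnames(runw) <- paste0("run", seq_along(runs))
  out <- cbind(out, runw,
               data.frame(n_active = dictionary$n_active[keep],
                          n_passive = dictionary$n_passive[keep],
                          n_calibration = dictionary$n_calibration[keep],
                          d_k = dk[keep]))
  out[order(out$role, -out$n_active), , drop = FALSE]
}
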