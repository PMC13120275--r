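# SMILES attributes: tokenization into "SMILES atoms" (S_k) and adjacent
# pairs (SS_k), and the attribute dictionary with rarity blocking.
#
# The tokenizer is deliberately chemistry-blind: it segments the notation
# into indivisible fragments but performs no valence or aromaticity checks.
# Closing brackets ')' are folded into '(' so that branching is represented
# by a single attribute, and bracket-atom expressions "[...]" are consumed
# whole so charge/isotope digits are never confused with ring closures.

# Two-character tokens that must never be split.
.two_char_tokens <- c("Cl", "Br", "Si", "@@")

# Single characters accepted as stand-alone tokens (after the multi-char
# rules have had their chance).  Covers organic-subset atoms, aromatic
# lowercase, ring digits, bonds, branching and stereo/direction marks.
.single_char_ok <- c(LETTERS, letters, as.character(0:9),
                     "(", ")", "=", "#", "-", "+", "/", "\\", "@", ".", "*", ":", "~")

#' Tokenize a SMILES string into SMILES atoms
#'
#' Splits a SMILES string into the indivisible fragments ("SMILES atoms")
#' used as model attributes: single characters, two-character groups
#' (`Cl`, `Br`, `Si`, `@@`), bracket-atom expressions `[...]` taken
#' verbatim as one token, and two-digit ring closures `%nn`.  Closing
#' parentheses are normalized to `(` so branching contributes a single
#' attribute type.  Case is preserved (aromatic `c` is distinct from
#' aliphatic `C`).
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens; every input character is consumed
#'   exactly once.
#' @examples
#' tokenize_smiles("O=C(O)C(Oc1ccc(cc1C)Cl)C")
#' tokenize_smiles("CSSSSC")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop_input("smiles must be a single character string")
  }
  if (!nzchar(smiles)) stop_input("empty SMILES string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop_input("unterminated '[' at position ", i, " in '", smiles, "'")
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        stop_input("'%' at position ", i, " must be followed by two digits")
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .two_char_tokens) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch == ")") {
      tokens <- c(tokens, "(")
      i <- i + 1L
    } else if (ch %in% .single_char_ok) {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop_input("unrecognized character '", ch, "' at position ", i, " in '", smiles, "'")
    }
  }
  tokens
}

# Canonical key of an unordered token pair: higher C-locale string first.
pair_key <- function(a, b) {
  s <- sort(c(a, b), decreasing = TRUE, method = "radix")
  paste(s[1], s[2], sep = "|")
}

#' Adjacent-pair attributes of a token sequence
#'
#' Returns the `length(tokens) - 1` attributes formed by tokens adjacent in
#' the notation.  Pairs are unordered: `(O, =)` and `(=, O)` map to the
#' same canonical attribute, keyed with the higher-character-code token
#' first.
#'
#' @param tokens Character vector from [tokenize_smiles()].
#' @return Character vector of canonical pair keys (`"tok1|tok2"`),
#'   empty for a single-token input.
#' @export
pair_attributes <- function(tokens) {
  if (length(tokens) < 2L) return(character(0))
  n <- length(tokens)
  mapply(pair_key, tokens[-n], tokens[-1], USE.NAMES = FALSE)
}

#' Render an attribute in the classic dotted two-column notation
#'
#' Cosmetic rendering used in attribute listings: a single atom is padded
#' with dots to width 12 (`"Cl.........."`); in a pair the first token is
#' padded to width 4, the second appended, then padded to width 12
#' (`"O...=......."`, `"Cl..(......."`).
#'
#' @param key Attribute key: a token, or `"tok1|tok2"` for a pair.
#' @param kind `"single"` or `"pair"`.
#' @return A character string.
#' @export
render_attribute <- function(key, kind = c("single", "pair")) {
  kind <- match.arg(kind)
  pad <- function(s, w) {
    if (nchar(s) >= w) s else paste0(s, strrep(".", w - nchar(s)))
  }
  if (kind == "single") {
    pad(key, 12L)
  } else {
    toks <- strsplit(key, "|", fixed = TRUE)[[1]]
    pad(paste0(pad(toks[1], 4L), toks[2]), 12L)
  }
}

# Occurrence counts of all attributes (singles then pairs) in one SMILES.
# Returns a named integer vector; names are keys, prefixed kind is implied
# by the presence of '|' in pair keys.
attribute_counts <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  keys <- c(toks, pair_attributes(toks))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

attr_kind <- function(keys) ifelse(grepl("|", keys, fixed = TRUE), "pair", "single")

#' Build the attribute dictionary for a labeled dataset
#'
#' Scans every compound, records which attributes (SMILES atoms and
#' adjacent pairs) occur in how many compounds of each block, and blocks
#' as "rare" every attribute seen in fewer than `T` active-training
#' compounds.  Blocked attributes keep a correlation weight of zero
#' throughout optimization.
#'
#' Frequencies are per-compound: an attribute occurring five times in one
#' compound counts once for that block.
#'
#' @param dataset A `qsar_dataset` with set labels assigned.
#' @param T Rarity threshold (default 3): an attribute must occur in at
#'   least `T` active-training compounds to receive a weight.
#' @return A data frame of class `attribute_dictionary` with columns
#'   `key`, `kind`, `render`, `n_active`, `n_passive`, `n_calibration`,
#'   `n_validation`, `blocked`; the threshold is stored in attribute
#'   `"T"`.
#' @export
build_attribute_dictionary <- function(dataset, T = 3L) {
  dataset <- as_qsar_dataset(dataset)
  if (!is.numeric(T) || length(T) != 1L || T < 1) {
    stop_config("T must be a positive integer")
  }
  if (!any(dataset$set == "active")) {
    stop_config("no active-training compounds: assign set labels before building the dictionary")
  }
  per_compound <- lapply(dataset$smiles, function(s) unique(names(attribute_counts(s))))
  all_keys <- sort(unique(unlist(per_compound)), method = "radix")
  sets <- c("active", "passive", "calibration", "validation")
  counts <- sapply(sets, function(lab) {
    in_set <- per_compound[dataset$set == lab]
    if (length(in_set) == 0L) return(integer(length(all_keys)))
    tab <- table(factor(unlist(in_set), levels = all_keys))
    as.integer(tab)
  })
  counts <- matrix(counts, nrow = length(all_keys),
                   dimnames = list(NULL, sets))
  kind <- attr_kind(all_keys)
  dict <- data.frame(
    key = all_keys,
    kind = kind,
    render = mapply(render_attribute, all_keys, kind, USE.NAMES = FALSE),
    n_active = counts[, "active"],
    n_passive = counts[, "passive"],
    n_calibration = counts[, "calibration"],
    n_validation = counts[, "validation"],
    stringsAsFactors = FALSE
  )
  dict$blocked <- dict$n_active < T
  attr(dict, "T") <- as.integer(T)
  attr(dict, "block_sizes") <- vapply(sets, function(lab) sum(dataset$set == lab), 0L)
  class(dict) <- c("attribute_dictionary", "data.frame")
  dict
}

# Compound-by-attribute occurrence matrix for the given keys.
attribute_incidence <- function(dataset, keys) {
  dataset <- as_qsar_dataset(dataset)
  mat <- matrix(0L, nrow = nrow(dataset), ncol = length(keys),
                dimnames = list(dataset$id, keys))
  for (i in seq_len(nrow(dataset))) {
    cnt <- attribute_counts(dataset$smiles[i])
    hit <- intersect(names(cnt), keys)
    mat[i, hit] <- cnt[hit]
  }
  mat
}

#' Token and pair decomposition of one SMILES, attribute-listing style
#'
#' Debug view: one row per token occurrence with the pair completed by the
#' preceding token, mirroring the classic two-column descriptor listing.
#'
#' @param smiles A SMILES string.
#' @param weights Optional named weight vector; if supplied, per-row
#'   correlation weights and their sum (the descriptor value) are included.
#' @return Data frame with columns `sk`, `ss_k` (empty for the first row)
#'   and, when `weights` is given, `cw_sk`, `cw_ssk`.
#' @export
smiles_attribute_table <- function(smiles, weights = NULL) {
  toks <- tokenize_smiles(smiles)
  pairs <- pair_attributes(toks)
  out <- data.frame(
    sk = vapply(toks, render_attribute, "", kind = "single", USE.NAMES = FALSE),
    ss_k = c("", vapply(pairs, render_attribute, "", kind = "pair", USE.NAMES = FALSE)),
    stringsAsFactors = FALSE
  )
  if (!is.null(weights)) {
    wt <- function(k) if (k %in% names(weights)) unname(weights[k]) else 0
    out$cw_sk <- vapply(toks, wt, 0)
    out$cw_ssk <- c(NA_real_, vapply(pairs, wt, 0))
  }
  out
}
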