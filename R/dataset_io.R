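# Compound tables and model files.
#
# A dataset is a plain data frame (class `qsar_dataset`) with columns
# id, smiles, endpoint, set.  The endpoint is consumed already
# log-transformed (e.g. pNOAEL = -log10 of a NOAEL in mg/kg bw/day);
# conversion from raw doses is left to `endpoint_transform`.

.set_levels <- c("active", "passive", "calibration", "validation", "unassigned")
.set_codes <- c(A = "active", P = "passive", C = "calibration", V = "validation")

#' Construct a QSAR compound dataset
#'
#' @param id Character identifiers, unique.
#' @param smiles Non-empty SMILES strings.  Duplicates are permitted but
#'   warned about, since modeling sets are normally de-duplicated.
#' @param endpoint Numeric endpoint values (NA allowed for
#'   prediction-only records).
#' @param set Set labels: `active`, `passive`, `calibration`,
#'   `validation` or `unassigned` (default).
#' @return A data frame of class `qsar_dataset`.
#' @export
qsar_dataset <- function(id, smiles, endpoint = NA_real_, set = "unassigned") {
  id <- as.character(id)
  smiles <- as.character(smiles)
  n <- length(id)
  if (length(smiles) != n) stop_input("id and smiles must have equal length")
  endpoint <- rep_len(as.numeric(endpoint), n)
  set <- rep_len(as.character(set), n)
  if (anyDuplicated(id)) stop_input("compound ids must be unique")
  if (any(is.na(smiles) | !nzchar(smiles))) stop_input("every record needs a non-empty SMILES")
  if (any(!is.na(endpoint) & !is.finite(endpoint))) stop_input("endpoint values must be finite or NA")
  if (!all(set %in% .set_levels)) {
    stop_input("set labels must be one of: ", paste(.set_levels, collapse = ", "))
  }
  if (anyDuplicated(smiles)) warning("duplicate SMILES present; modeling sets are normally de-duplicated")
  out <- data.frame(id = id, smiles = smiles, endpoint = endpoint, set = set,
                    stringsAsFactors = FALSE)
  class(out) <- c("qsar_dataset", "data.frame")
  out
}

as_qsar_dataset <- function(x) {
  if (inherits(x, "qsar_dataset")) return(x)
  need <- c("id", "smiles")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop_input("expected a qsar_dataset or a data frame with columns id, smiles")
  }
  if (is.null(x$endpoint)) x$endpoint <- NA_real_
  if (is.null(x$set)) x$set <- "unassigned"
  suppressWarnings(qsar_dataset(x$id, x$smiles, x$endpoint, x$set))
}

#' Read a compound table from CSV or TSV
#'
#' The file must have a header naming columns `id`, `smiles`, `endpoint`
#' and optionally `set`; set codes `A`, `P`, `C`, `V` map to active,
#' passive, calibration and validation, absent or empty values to
#' `unassigned`.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`; defaults from the file extension.
#' @return A `qsar_dataset`, rows in file order.
#' @export
read_dataset <- function(path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.tab$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  for (col in c("id", "smiles")) {
    if (!col %in% names(raw)) stop_input("missing required column '", col, "' in ", path)
  }
  if (!"endpoint" %in% names(raw)) stop_input("missing required column 'endpoint' in ", path)
  ep_txt <- trimws(raw$endpoint)
  ep <- suppressWarnings(as.numeric(ep_txt))
  bad <- which(!is.na(ep_txt) & nzchar(ep_txt) & is.na(ep))
  if (length(bad)) {
    stop_input("non-numeric endpoint '", ep_txt[bad[1]], "' in row ", bad[1], " of ", path)
  }
  set <- rep("unassigned", nrow(raw))
  if ("set" %in% names(raw)) {
    code <- toupper(trimws(raw$set))
    known <- code %in% names(.set_codes)
    full <- tolower(trimws(raw$set)) %in% .set_levels
    set[known] <- .set_codes[code[known]]
    set[!known & full] <- tolower(trimws(raw$set))[!known & full]
    bad <- !known & !full & nzchar(code)
    if (any(bad)) {
      stop_input("unknown set code '", raw$set[which(bad)[1]], "' in row ", which(bad)[1])
    }
  }
  qsar_dataset(raw$id, raw$smiles, ep, set)
}

#' Write a compound table
#'
#' @param dataset A `qsar_dataset`.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  dataset <- as_qsar_dataset(dataset)
  out <- data.frame(id = dataset$id, smiles = dataset$smiles,
                    endpoint = format_full(dataset$endpoint),
                    set = names(.set_codes)[match(dataset$set, .set_codes)],
                    stringsAsFactors = FALSE)
  out$set[is.na(out$set)] <- ""
  out$endpoint[is.na(dataset$endpoint)] <- ""
  utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert raw doses to a negative-log endpoint
#'
#' Convenience for endpoints defined as the negative decimal logarithm of
#' a dose (e.g. pNOAEL from a NOAEL in mg/kg bw/day).
#'
#' @param dose Positive numeric doses.
#' @return `-log10(dose)`.
#' @export
endpoint_transform <- function(dose) {
  if (any(dose <= 0, na.rm = TRUE)) stop_input("doses must be positive for a -log10 transform")
  -log10(dose)
}

# ---- model files -----------------------------------------------------------
# Plain-text, diffable, locale-free.  Layout:
#   cwqsar-model 1
#   c0 <value> / c1 <value> / T / N / target_function / seed / ...
#   [weights]  key<TAB>weight     (key uses 'a|b' for pairs)
#   [defects]  key<TAB>d_k        (optional, plus d_bar in the header)

#' Write a fitted model to a text file
#'
#' The format is a key/value header (regression coefficients and the
#' optimization configuration) followed by the attribute-to-weight table,
#' all in full decimal precision so that [read_model()] reproduces the
#' model bit-exactly.
#'
#' @param model A `qsar_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "qsar_model")) stop_input("model must be a qsar_model")
  if (is.null(model$c0) || is.null(model$c1) || !is.finite(model$c0) || !is.finite(model$c1)) {
    stop_input("model is not fitted: c0/c1 missing")
  }
  cfg <- model$config
  lines <- c(
    "cwqsar-model 1",
    paste("c0", format_full(model$c0)),
    paste("c1", format_full(model$c1)),
    paste("T", cfg$T),
    paste("N", cfg$N),
    paste("target_function", cfg$target_function),
    paste("seed", cfg$seed),
    paste("step_magnitude", format_full(cfg$step_magnitude)),
    paste("initial_weight", format_full(cfg$initial_weight))
  )
  if (!is.null(model$d_bar)) lines <- c(lines, paste("d_bar", format_full(model$d_bar)))
  lines <- c(lines, "[weights]")
  w <- model$weights
  if (length(w)) {
    lines <- c(lines, paste(names(w), format_full(unname(w)), sep = "\t"))
  }
  if (!is.null(model$defects) && nrow(model$defects)) {
    lines <- c(lines, "[defects]",
               paste(model$defects$key, format_full(model$defects$d_k), sep = "\t"))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a model file written by [write_model()]
#'
#' @param path Path to the model file.
#' @return A `qsar_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^cwqsar-model", lines[1])) {
    stop_input("not a cwqsar model file: ", path)
  }
  wstart <- match("[weights]", lines)
  if (is.na(wstart)) stop_input("model file has no [weights] section: ", path)
  dstart <- match("[defects]", lines)
  header <- lines[2:(wstart - 1L)]
  kv <- strsplit(header, " ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  names(vals) <- keys
  need <- c("c0", "c1", "T", "N", "target_function", "seed")
  for (k in need) {
    if (!k %in% keys) stop_input("model file missing field '", k, "': ", path)
  }
  wend <- if (is.na(dstart)) length(lines) else dstart - 1L
  wlines <- lines[seq.int(wstart + 1L, length.out = max(0L, wend - wstart))]
  wlines <- wlines[nzchar(wlines)]
  weights <- numeric(0)
  if (length(wlines)) {
    parts <- strsplit(wlines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop_input("malformed weight line in ", path)
    weights <- as.numeric(vapply(parts, `[`, "", 2))
    names(weights) <- vapply(parts, `[`, "", 1)
    if (anyNA(weights)) stop_input("non-numeric weight in ", path)
  }
  defects <- NULL
  if (!is.na(dstart) && dstart < length(lines)) {
    dlines <- lines[(dstart + 1L):length(lines)]
    dlines <- dlines[nzchar(dlines)]
    parts <- strsplit(dlines, "\t", fixed = TRUE)
    defects <- data.frame(key = vapply(parts, `[`, "", 1),
                          d_k = as.numeric(vapply(parts, `[`, "", 2)),
                          stringsAsFactors = FALSE)
  }
  num <- function(k) as.numeric(vals[[k]])
  qsar_model(
    weights = weights,
    c0 = num("c0"), c1 = num("c1"),
    config = optimizer_config(
      T = as.integer(num("T")), N = as.integer(num("N")),
      target_function = vals[["target_function"]],
      seed = as.integer(num("seed")),
      step_magnitude = if ("step_magnitude" %in% keys) num("step_magnitude") else 0.5,
      initial_weight = if ("initial_weight" %in% keys) num("initial_weight") else 1.0
    ),
    defects = defects,
    d_bar = if ("d_bar" %in% keys) num("d_bar") else NULL
  )
}
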