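# The optimal descriptor DCW, the final one-descriptor least-squares
# model, and prediction.
#
# DCW(T, N) for a compound is the sum, over every token occurrence and
# every adjacent-pair occurrence in its SMILES, of the attribute's
# correlation weight.  Blocked (rare) attributes and attributes never
# seen in training contribute zero; the latter are counted and surfaced
# with the applicability-domain flag.

#' Optimizer configuration
#'
#' @param T Rarity threshold: attributes in fewer than `T` active-training
#'   compounds are blocked (weight pinned at 0).  Default 3.
#' @param N Number of optimization epochs (one epoch visits every
#'   non-blocked attribute once).  Default 15.
#' @param target_function `"TF1"` (default) or `"TF0"`.
#' @param seed RNG seed for the proposal stream.
#' @param step_magnitude Half-width of the uniform weight perturbation.
#' @param initial_weight Starting weight of every non-blocked attribute.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(T = 3L, N = 15L, target_function = c("TF1", "TF0"),
                             seed = 1L, step_magnitude = 0.5, initial_weight = 1.0) {
  target_function <- match.arg(target_function)
  if (T < 1) stop_config("T must be >= 1")
  if (N < 0) stop_config("N must be >= 0")
  if (step_magnitude <= 0) stop_config("step_magnitude must be positive")
  structure(list(T = as.integer(T), N = as.integer(N),
                 target_function = target_function, seed = as.integer(seed),
                 step_magnitude = step_magnitude, initial_weight = initial_weight),
            class = "optimizer_config")
}

#' Construct a QSAR model object
#'
#' @param weights Named numeric vector of correlation weights (pair keys
#'   use `"a|b"`); blocked attributes appear with weight 0.
#' @param c0,c1 Regression intercept and slope of
#'   `endpoint = c0 + c1 * DCW`.
#' @param config The [optimizer_config()] that produced the weights.
#' @param defects Optional per-attribute statistical-defect table
#'   (columns `key`, `d_k`) for the applicability domain.
#' @param d_bar Optional mean compound defect of the training population.
#' @return A list of class `qsar_model`.
#' @export
qsar_model <- function(weights, c0, c1, config, defects = NULL, d_bar = NULL) {
  if (length(weights) && is.null(names(weights))) stop_input("weights must be named by attribute key")
  structure(list(weights = weights, c0 = c0, c1 = c1, config = config,
                 defects = defects, d_bar = d_bar),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("cwqsar model: endpoint = %.4f + %.4f * DCW(%d,%d)  [%s]\n",
              x$c0, x$c1, x$config$T, x$config$N, x$config$target_function))
  cat(sprintf("  %d attribute weights (%d nonzero)\n",
              length(x$weights), sum(x$weights != 0)))
  if (!is.null(x$d_bar)) {
    cat(sprintf("  applicability domain: D_j < %.6g (2 * mean defect)\n", 2 * x$d_bar))
  }
  invisible(x)
}

#' Compute the optimal descriptor DCW for one SMILES
#'
#' Sums the correlation weight of every attribute occurrence (tokens and
#' adjacent pairs).  Attributes absent from the weight table — blocked or
#' never seen in training — contribute 0; the number of such unseen
#' occurrences is reported for the applicability-domain flag.
#'
#' @param smiles A SMILES string.
#' @param weights Named numeric vector of correlation weights.
#' @return The descriptor value, with attribute `"n_unseen"` giving the
#'   count of occurrences of attributes missing from the table.
#' @export
compute_dcw <- function(smiles, weights) {
  counts <- attribute_counts(smiles)
  known <- names(counts) %in% names(weights)
  val <- if (any(known)) {
    sum(counts[known] * weights[names(counts)[known]])
  } else 0
  structure(val, n_unseen = sum(counts[!known]))
}

# Descriptor values for a whole dataset given an incidence matrix.
dcw_from_incidence <- function(incidence, weights) {
  drop(incidence %*% weights[colnames(incidence)])
}

#' Least-squares fit of the final one-descriptor regression
#'
#' Ordinary least squares of the endpoint on the descriptor:
#' `endpoint = c0 + c1 * DCW`.
#'
#' @param dcw Descriptor values.
#' @param endpoint Observed endpoint values, same length.
#' @return List with `c0`, `c1` and their standard errors `se_c0`,
#'   `se_c1`.
#' @export
fit_regression <- function(dcw, endpoint) {
  check_series(endpoint, dcw, min_n = 3L)
  if (stats::sd(dcw) == 0) stop_numeric("degenerate descriptor: zero variance in DCW")
  fit <- stats::lm.fit(cbind(1, dcw), endpoint)
  cf <- unname(fit$coefficients)
  n <- length(dcw)
  sigma2 <- sum(fit$residuals^2) / (n - 2)
  sxx <- sum((dcw - mean(dcw))^2)
  list(c0 = cf[1], c1 = cf[2],
       se_c0 = sqrt(sigma2 * (1 / n + mean(dcw)^2 / sxx)),
       se_c1 = sqrt(sigma2 / sxx))
}

#' Predict endpoints for new compounds
#'
#' @param object A fitted `qsar_model`.
#' @param newdata A `qsar_dataset`, a data frame with `id` and `smiles`
#'   columns, or a character vector of SMILES.
#' @param ... Unused.
#' @return Data frame with `id`, `smiles`, `dcw`, `prediction`,
#'   `n_unseen` (occurrences of attributes unknown to the model) and,
#'   when the model carries defect information, `d_j` and `in_domain`.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(id = paste0("cmp", seq_along(newdata)),
                          smiles = newdata, stringsAsFactors = FALSE)
  }
  if (!all(c("id", "smiles") %in% names(newdata))) {
    stop_input("newdata needs columns id and smiles")
  }
  dcws <- lapply(newdata$smiles, compute_dcw, weights = object$weights)
  dcw <- vapply(dcws, as.numeric, 0)
  out <- data.frame(
    id = newdata$id, smiles = newdata$smiles,
    dcw = dcw,
    prediction = object$c0 + object$c1 * dcw,
    n_unseen = vapply(dcws, function(x) as.integer(attr(x, "n_unseen")), 0L),
    stringsAsFactors = FALSE
  )
  if (!is.null(object$defects) && !is.null(object$d_bar)) {
    dk <- stats::setNames(object$defects$d_k, object$defects$key)
    out$d_j <- vapply(newdata$smiles, compound_defect, 0, defects = dk, USE.NAMES = FALSE)
    out$in_domain <- in_domain(out$d_j, object$d_bar)
  }
  out
}
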