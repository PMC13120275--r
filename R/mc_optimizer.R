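# Monte Carlo optimization of correlation weights.
#
# One epoch visits every non-blocked attribute once in a seeded random
# order and proposes a uniform perturbation of its weight.  A proposal is
# accepted iff the target function does not decrease:
#
#   TF0 = rA + rP - |rA - rP| * 0.1
#   TF1 = TF0 + (IIC_cal + CII_cal) * 0.5
#
# rA and rP are the signed Pearson correlations between observed endpoint
# and descriptor on the active and passive training blocks; IIC and CII
# are evaluated on the calibration block, IIC against predictions from an
# intercept/slope refit on the active block (IIC is not scale-invariant),
# CII directly against the descriptor (it depends only on correlations).

#' Target function TF0
#'
#' Rewards high and balanced active/passive training correlations:
#' `rA + rP - |rA - rP| * 0.1`.
#'
#' @param rA,rP Pearson correlations on the active and passive training
#'   sets, in `[-1, 1]`.
#' @return TF0 value.
#' @export
tf0 <- function(rA, rP) {
  rA + rP - abs(rA - rP) * 0.1
}

#' Target function TF1
#'
#' Adds the calibration-set index of ideality of correlation and
#' correlation intensity index to TF0: `TF0 + (IIC + CII) * 0.5`.
#'
#' @param tf0_value TF0 value.
#' @param iic_cal,cii_cal Calibration-set IIC and CII.
#' @return TF1 value.
#' @export
tf1 <- function(tf0_value, iic_cal, cii_cal) {
  tf0_value + (iic_cal + cii_cal) * 0.5
}

# Non-throwing metric cores for the hot loop: NA means "undefined".
.r_core <- function(x, y) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

.iic_core <- function(observed, calculated) {
  r <- .r_core(observed, calculated)
  if (is.na(r)) return(NA_real_)
  d <- observed - calculated
  neg <- d[d < 0]
  pos <- d[d >= 0]
  mae_neg <- if (length(neg)) mean(abs(neg)) else 0
  mae_pos <- if (length(pos)) mean(pos) else 0
  hi <- max(mae_neg, mae_pos)
  if (hi == 0) return(r)
  r * min(mae_neg, mae_pos) / hi
}

.cii_core <- function(observed, calculated) {
  r <- .r_core(observed, calculated)
  if (is.na(r)) return(NA_real_)
  rk2 <- loo_r2(observed, calculated)
  rk2[is.na(rk2)] <- 0
  1 - sum(pmax(0, rk2 - r^2))
}

# Evaluate the target function and its components for a descriptor vector.
# Returns NULL when any needed correlation is undefined (degenerate
# proposal); the caller rejects such proposals.
.evaluate_tf <- function(dcw, y, idx, target_function) {
  rA <- .r_core(y[idx$active], dcw[idx$active])
  rP <- .r_core(y[idx$passive], dcw[idx$passive])
  if (is.na(rA) || is.na(rP)) return(NULL)
  t0 <- tf0(rA, rP)
  # calibration predictions from an active-set refit (for IIC, which is
  # sensitive to the residual scale and sign)
  xa <- dcw[idx$active]; ya <- y[idx$active]
  vx <- stats::var(xa)
  if (!is.finite(vx) || vx == 0) return(NULL)
  c1 <- stats::cov(xa, ya) / vx
  c0 <- mean(ya) - c1 * mean(xa)
  pred_cal <- c0 + c1 * dcw[idx$calibration]
  iic_cal <- .iic_core(y[idx$calibration], pred_cal)
  cii_cal <- .cii_core(y[idx$calibration], dcw[idx$calibration])
  if (is.na(iic_cal) || is.na(cii_cal)) return(NULL)
  tf <- if (target_function == "TF1") tf1(t0, iic_cal, cii_cal) else t0
  list(tf = tf, rA = rA, rP = rP, iic_cal = iic_cal, cii_cal = cii_cal)
}

#' Optimize correlation weights by Monte Carlo search
#'
#' Runs `config$N` epochs of seeded Monte Carlo optimization over all
#' non-blocked attributes of the dictionary.  Proposals perturb one
#' weight by `uniform(-step_magnitude, +step_magnitude)` and are accepted
#' iff the target function does not decrease, so the TF sequence over
#' accepted moves is non-decreasing.  Blocked attributes keep weight 0
#' throughout.
#'
#' @param dataset A labeled `qsar_dataset` with non-empty active, passive
#'   and calibration blocks.
#' @param dictionary An [build_attribute_dictionary()] result built with
#'   the same `T` as `config`.
#' @param config An [optimizer_config()].
#' @return List with `weights` (named vector over all dictionary keys,
#'   blocked at 0) and `trace` (list of data frames `moves` — one row per
#'   accepted move — and `epochs` — per-epoch rA, rP, calibration IIC and
#'   CII, and TF).
#' @export
optimize_weights <- function(dataset, dictionary, config = optimizer_config()) {
  dataset <- as_qsar_dataset(dataset)
  if (!inherits(dictionary, "attribute_dictionary")) stop_input("dictionary must be an attribute_dictionary")
  if (!identical(attr(dictionary, "T"), config$T)) {
    stop_config("dictionary was built with T = ", attr(dictionary, "T"),
                " but config has T = ", config$T)
  }
  idx <- list(active = which(dataset$set == "active"),
              passive = which(dataset$set == "passive"),
              calibration = which(dataset$set == "calibration"))
  for (b in names(idx)) {
    if (length(idx[[b]]) == 0L) stop_config("empty ", b, " block")
    yv <- dataset$endpoint[idx[[b]]]
    if (anyNA(yv)) stop_input("missing endpoint in ", b, " block")
    if (stats::sd(yv) == 0) stop_numeric("zero endpoint variance in ", b, " block")
  }
  y <- dataset$endpoint
  free_keys <- dictionary$key[!dictionary$blocked]
  if (length(free_keys) == 0L) stop_config("every attribute is blocked at T = ", config$T)
  X <- attribute_incidence(dataset, free_keys)
  p <- length(free_keys)
  w <- rep(config$initial_weight, p)
  names(w) <- free_keys
  dcw <- drop(X %*% w)

  cur <- .evaluate_tf(dcw, y, idx, config$target_function)
  if (is.null(cur)) stop_numeric("degenerate initial descriptor: undefined correlation at start")

  moves <- list()
  epochs <- list()
  local_seed(config$seed, {
    for (epoch in seq_len(config$N)) {
      order_j <- sample.int(p)
      for (j in order_j) {
        delta <- stats::runif(1, -config$step_magnitude, config$step_magnitude)
        w_start <- w[j]
        # directional search: try +delta, else -delta, then keep stepping
        # in the accepted direction while TF does not decrease
        for (dir_delta in c(delta, -delta)) {
          dcw_new <- dcw + dir_delta * X[, j]
          cand <- .evaluate_tf(dcw_new, y, idx, config$target_function)
          if (!is.null(cand) && cand$tf >= cur$tf) {
            w[j] <- w[j] + dir_delta
            dcw <- dcw_new
            cur <- cand
            # continue in this direction only while TF strictly improves,
            # so plateau ties cannot cause unbounded drift
            steps <- 1L
            while (steps < 20L) {
              dcw_new <- dcw + dir_delta * X[, j]
              cand <- .evaluate_tf(dcw_new, y, idx, config$target_function)
              if (is.null(cand) || cand$tf <= cur$tf) break
              w[j] <- w[j] + dir_delta
              dcw <- dcw_new
              cur <- cand
              steps <- steps + 1L
            }
            break
          }
        }
        if (w[j] != w_start) {
          moves[[length(moves) + 1L]] <- data.frame(
            epoch = epoch, key = free_keys[j],
            old = w_start, new = w[j], tf = cur$tf,
            stringsAsFactors = FALSE)
        }
      }
      epochs[[epoch]] <- data.frame(
        epoch = epoch, rA = cur$rA, rP = cur$rP,
        iic_cal = cur$iic_cal, cii_cal = cur$cii_cal, tf = cur$tf)
    }
  })

  weights <- stats::setNames(rep(0, nrow(dictionary)), dictionary$key)
  weights[free_keys] <- w
  trace <- list(
    moves = if (length(moves)) do.call(rbind, moves) else
      data.frame(epoch = integer(), key = character(), old = numeric(),
                 new = numeric(), tf = numeric(), stringsAsFactors = FALSE),
    epochs = if (length(epochs)) do.call(rbind, epochs) else
      data.frame(epoch = integer(), rA = numeric(), rP = numeric(),
                 iic_cal = numeric(), cii_cal = numeric(), tf = numeric())
  )
  list(weights = weights, trace = trace)
}

#' Fit a complete model on a labeled dataset
#'
#' Convenience wrapper: builds the attribute dictionary, optimizes the
#' correlation weights, fits the final least-squares calibration of the
#' endpoint on DCW over the active training block, and attaches the
#' statistical-defect applicability domain.
#'
#' @inheritParams optimize_weights
#' @return A `qsar_model` with an attached `trace` attribute.
#' @export
fit_qsar_model <- function(dataset, config = optimizer_config()) {
  dataset <- as_qsar_dataset(dataset)
  dictionary <- build_attribute_dictionary(dataset, T = config$T)
  opt <- optimize_weights(dataset, dictionary, config)
  act <- dataset[dataset$set == "active", ]
  dcw_act <- vapply(act$smiles, function(s) as.numeric(compute_dcw(s, opt$weights)), 0,
                    USE.NAMES = FALSE)
  reg <- fit_regression(dcw_act, act$endpoint)
  dom <- domain_reference(dataset, dictionary)
  model <- qsar_model(weights = opt$weights, c0 = reg$c0, c1 = reg$c1,
                      config = config, defects = dom$defects, d_bar = dom$d_bar)
  model$se_c0 <- reg$se_c0
  model$se_c1 <- reg$se_c1
  attr(model, "trace") <- opt$trace
  attr(model, "dictionary") <- dictionary
  model
}

#' Per-block metrics table for a fitted model
#'
#' Applies the model to every labeled block of the dataset and computes
#' the full reporting row (n, R^2, CCC, IIC, CII, Q^2, RMSE, F) per
#' block, in the conventional layout.
#'
#' @param model A fitted `qsar_model`.
#' @param dataset The labeled `qsar_dataset`.
#' @return Data frame with a `set` column followed by the metric columns.
#' @export
block_metrics <- function(model, dataset) {
  dataset <- as_qsar_dataset(dataset)
  preds <- predict(model, dataset)
  blocks <- intersect(c("active", "passive", "calibration", "validation"),
                      unique(dataset$set))
  rows <- lapply(blocks, function(b) {
    sel <- dataset$set == b
    rep <- metrics_report(dataset$endpoint[sel], preds$prediction[sel],
                          dcw = preds$dcw[sel])
    cbind(data.frame(set = b, stringsAsFactors = FALSE), rep)
  })
  do.call(rbind, rows)
}
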