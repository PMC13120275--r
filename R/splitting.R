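# Four-way data splits and the Las Vegas best-of-k split search.

.block_names <- c("active", "passive", "calibration", "validation")

# Largest-remainder apportionment of n into length(p) blocks.
round_targets <- function(n, proportions) {
  raw <- n * proportions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Draw a random four-way partition
#'
#' Assigns every compound to one of active training, passive training,
#' calibration or validation, with block sizes given by largest-remainder
#' rounding of `n * proportions`.  The same seed always yields the same
#' assignment.
#'
#' @param dataset A `qsar_dataset` with at least 8 compounds.
#' @param proportions Four positive fractions summing to 1 (default equal
#'   quarters, matching the convention of approximately equal set
#'   populations).
#' @param seed RNG seed.
#' @return The dataset with the `set` column filled; the seed and
#'   proportions are attached as attributes `"seed"` and
#'   `"proportions"`.
#' @export
random_partition <- function(dataset, proportions = rep(0.25, 4), seed = 1L) {
  dataset <- as_qsar_dataset(dataset)
  if (length(proportions) != 4L || any(proportions <= 0)) {
    stop_config("proportions must be four positive fractions")
  }
  if (abs(sum(proportions) - 1) > 1e-9) stop_config("proportions must sum to 1")
  n <- nrow(dataset)
  if (n < 8L) stop_config("dataset too small to split four ways (need >= 8 compounds)")
  sizes <- round_targets(n, proportions)
  if (any(sizes == 0L)) stop_config("a block would be empty at these proportions")
  labels <- rep(.block_names, times = sizes)
  perm <- local_seed(seed, sample.int(n))
  dataset$set <- labels[perm]
  attr(dataset, "seed") <- as.integer(seed)
  attr(dataset, "proportions") <- proportions
  dataset
}

#' Histogram-intersection overlap of endpoint distributions across blocks
#'
#' For every pair of blocks, bins both endpoint distributions on shared
#' equal-width bins over the pooled range and returns the histogram
#' intersection `sum(pmin(p1, p2))` of the bin proportions — 1 for
#' identical distributions, 0 for disjoint supports.
#'
#' @param dataset A labeled `qsar_dataset` with endpoints for all records.
#' @param bins Number of shared bins (default 10).
#' @return Symmetric matrix of pairwise overlaps in `[0, 1]`, one
#'   row/column per block present.
#' @export
distribution_overlap <- function(dataset, bins = 10L) {
  dataset <- as_qsar_dataset(dataset)
  if (anyNA(dataset$endpoint)) stop_input("every record needs an endpoint for overlap computation")
  blocks <- intersect(.block_names, unique(dataset$set))
  if (length(blocks) < 2L) stop_config("need at least two labeled blocks")
  rng <- range(dataset$endpoint)
  out <- matrix(1, length(blocks), length(blocks), dimnames = list(blocks, blocks))
  if (diff(rng) == 0) {
    warning("zero endpoint variance: all overlaps are 1")
    return(out)
  }
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  prop <- function(b) {
    x <- dataset$endpoint[dataset$set == b]
    bin <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(bin, nbins = bins) / length(x)
  }
  props <- lapply(blocks, prop)
  names(props) <- blocks
  for (i in seq_along(blocks)) {
    for (j in seq_along(blocks)) {
      if (i < j) {
        ov <- sum(pmin(props[[i]], props[[j]]))
        out[i, j] <- ov
        out[j, i] <- ov
      }
    }
  }
  out
}

#' Las Vegas selection of the best four-way split
#'
#' Draws `k` random partitions (candidate seeds derived deterministically
#' from `seed`), scores each with a short probe optimization, and returns
#' the partition with the best calibration-set score.  The default probe
#' score is the calibration `IIC + CII` after `probe_epochs` epochs of
#' TF1 optimization; alternatives are the calibration `R^2` of the probe
#' model or the mean pairwise endpoint-distribution overlap (no
#' optimization).
#'
#' @param dataset A `qsar_dataset` with endpoints.
#' @param k Number of candidate splits (default 10; larger values are
#'   admissible at proportional cost).
#' @param probe_epochs Epochs of the probe optimization (default 3).
#' @param T Rarity threshold for the probe dictionary.
#' @param seed Master seed.
#' @param proportions Block proportions, default equal quarters.
#' @param criterion `"iic_cii"` (default), `"r2"` or `"overlap"`.
#' @return The selected labeled dataset; attribute `"candidates"` holds
#'   the log (data frame of candidate index, seed, score) and
#'   `"score"` the winning score.
#' @export
las_vegas_select <- function(dataset, k = 10L, probe_epochs = 3L, T = 3L, seed = 1L,
                             proportions = rep(0.25, 4),
                             criterion = c("iic_cii", "r2", "overlap")) {
  criterion <- match.arg(criterion)
  dataset <- as_qsar_dataset(dataset)
  if (k < 1L) stop_config("k must be >= 1")
  seeds <- derive_seeds(seed, k)
  scores <- numeric(k)
  splits <- vector("list", k)
  for (i in seq_len(k)) {
    cand <- random_partition(dataset, proportions, seed = seeds[i])
    splits[[i]] <- cand
    scores[i] <- tryCatch(
      switch(criterion,
        overlap = {
          ov <- distribution_overlap(cand)
          mean(ov[upper.tri(ov)])
        },
        {
          cfg <- optimizer_config(T = T, N = probe_epochs, target_function = "TF1",
                                  seed = seeds[i])
          dict <- build_attribute_dictionary(cand, T = T)
          opt <- optimize_weights(cand, dict, cfg)
          ep <- opt$trace$epochs
          last <- ep[nrow(ep), ]
          if (criterion == "r2") {
            sel <- cand$set == "calibration"
            dcw <- dcw_from_incidence(attribute_incidence(cand[sel, ], names(opt$weights)),
                                      opt$weights)
            r2(cand$endpoint[sel], dcw)
          } else {
            last$iic_cal + last$cii_cal
          }
        }),
      cwqsar_error = function(e) -Inf)
  }
  best <- which.max(scores)
  message(sprintf("[split] las vegas: %d candidates, best #%d (score %.4f)",
                  k, best, scores[best]))
  out <- splits[[best]]
  attr(out, "candidates") <- data.frame(candidate = seq_len(k), seed = seeds,
                                        score = scores)
  attr(out, "score") <- scores[best]
  out
}

#' Assign a random four-way split to a dataset
#'
#' Thin wrapper around [random_partition()], kept as the entry point used
#' by the synthetic-data generator.
#'
#' @inheritParams random_partition
#' @return The labeled dataset.
#' @export
assign_splits <- function(dataset, proportions = rep(0.25, 4), seed = 1L) {
  random_partition(dataset, proportions, seed)
}
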