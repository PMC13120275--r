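# Independent brute-force reference implementations used to cross-check
# the package's metric functions.  These deliberately share no code with
# the package: correlations are recomputed from scratch with stats::cor /
# stats::lm at every step.

oracle_iic <- function(obs, calc) {
  r <- cor(obs, calc)
  d <- obs - calc
  neg <- abs(d[d < 0])
  pos <- d[d >= 0]
  mae_neg <- if (length(neg)) sum(neg) / length(neg) else 0
  mae_pos <- if (length(pos)) sum(pos) / length(pos) else 0
  if (max(mae_neg, mae_pos) == 0) return(r)
  r * min(mae_neg, mae_pos) / max(mae_neg, mae_pos)
}

oracle_cii <- function(obs, calc) {
  full <- cor(obs, calc)^2
  protests <- vapply(seq_along(obs), function(k) {
    o <- obs[-k]; c2 <- calc[-k]
    if (sd(o) == 0 || sd(c2) == 0) return(0)
    max(0, cor(o, c2)^2 - full)
  }, 0)
  1 - sum(protests)
}

oracle_ccc <- function(obs, calc) {
  n <- length(obs)
  mo <- mean(obs); mc <- mean(calc)
  vo <- sum((obs - mo)^2) / n
  vc <- sum((calc - mc)^2) / n
  cv <- sum((obs - mo) * (calc - mc)) / n
  2 * cv / (vo + vc + (mo - mc)^2)
}

# LOO Q^2 by literally refitting the intercept/slope n times with lm().
oracle_q2 <- function(x, y) {
  press <- sum(vapply(seq_along(x), function(k) {
    fit <- lm(y[-k] ~ x[-k])
    pred <- coef(fit)[1] + coef(fit)[2] * x[k]
    (y[k] - pred)^2
  }, 0))
  1 - press / sum((y - mean(y))^2)
}

# Small labeled dataset used across module tests.
make_toy_dataset <- function(n = 40, seed = 42, noise_sd = 0.05) {
  ds <- generate_dataset(generator_spec(n_compounds = n, noise_sd = noise_sd,
                                        length_range = c(6L, 15L), seed = seed))
  assign_splits(ds, seed = seed)
}
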