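test_that("statistical defect follows the pairwise probability-difference formula", {
  # direct evaluation: P=0.6 (N=60), P'=0.5 (N'=50), P''=0.4 (N''=40)
  d <- defect_from_counts(c(60, 50, 40), c(100, 100, 100))
  expect_equal(d, 0.1 / 110 + 0.2 / 100 + 0.1 / 90, tolerance = 1e-12)
  # identical probabilities across blocks: zero defect
  expect_equal(defect_from_counts(c(30, 30, 30), c(100, 100, 100)), 0)
  # positivity: d_k = 0 iff all probabilities equal
  expect_gt(defect_from_counts(c(31, 30, 30), c(100, 100, 100)), 0)
})

test_that("per-attribute defects come from dictionary counts", {
  ds <- make_toy_dataset(n = 60, seed = 30)
  dict <- build_attribute_dictionary(ds, T = 2)
  sizes <- attr(dict, "block_sizes")
  key <- dict$key[which(!dict$blocked)[1]]
  i <- match(key, dict$key)
  expected <- defect_from_counts(
    c(dict$n_active[i], dict$n_passive[i], dict$n_calibration[i]),
    sizes[c("active", "passive", "calibration")])
  expect_equal(statistical_defect(key, dict), expected)
  expect_error(statistical_defect("nosuch", dict), class = "cwqsar_input_error")
})

test_that("compound defect sums per occurrence over non-blocked attributes", {
  defects <- c("C" = 0.001, "O" = 0.002, "C|C" = 0.0005)
  # 'C' twice, 'O' once, pair C|C once, pair C|O unknown
  expect_equal(compound_defect("CCO", defects),
               2 * 0.001 + 0.002 + 0.0005, tolerance = 1e-12)
  expect_warning(d0 <- compound_defect("NNN", defects), "blocked or unknown")
  expect_equal(d0, 0)
})

test_that("domain membership uses the strict 2*D_bar threshold", {
  expect_true(in_domain(0, 0.5))
  expect_false(in_domain(1, 0.5))        # exactly 2*D_bar is out
  expect_false(in_domain(1 + 1e-12, 0.5))
  expect_true(in_domain(1 - 1e-12, 0.5))
  expect_warning(res <- in_domain(c(0, 1), 0), "degenerate")
  expect_equal(res, c(FALSE, FALSE))     # strict: 0 < 0 is false
  # monotone: growing D_bar never shrinks the in-domain set
  dj <- c(0.1, 0.5, 0.9, 2)
  expect_true(all(in_domain(dj, 0.3) >= in_domain(dj, 0.2)))
})

test_that("domain_report flags compounds against the training-mean defect", {
  ds <- make_toy_dataset(n = 60, seed = 31)
  dict <- build_attribute_dictionary(ds, T = 2)
  rep <- domain_report(ds, dict)
  expect_equal(nrow(rep), 60L)
  expect_true(all(rep$d_j >= 0))
  train <- rep$set %in% c("active", "passive", "calibration")
  expect_equal(attr(rep, "d_bar"), mean(rep$d_j[train]), tolerance = 1e-12)
  expect_equal(rep$in_domain, rep$d_j < 2 * attr(rep, "d_bar"))
})

test_that("promoters need a stable sign across all runs and enough frequency", {
  ds <- make_toy_dataset(n = 60, seed = 32)
  dict <- build_attribute_dictionary(ds, T = 2)
  keys <- dict$key[!dict$blocked]
  w1 <- stats::setNames(rep(1, length(keys)), keys)
  w2 <- w1; w3 <- w1
  # one attribute flips sign in run 2 -> unstable, excluded
  flip <- keys[1]
  w2[flip] <- -0.2
  # one attribute stays negative everywhere -> decrease
  negk <- keys[2]
  w1[negk] <- -0.6; w2[negk] <- -0.9; w3[negk] <- -0.4
  tab <- extract_promoters(list(w1, w2, w3), dict, min_frequency = 1)
  expect_false(flip %in% tab$key)
  expect_equal(tab$role[tab$key == negk], "decrease")
  expect_true(all(tab$role[tab$key != negk] == "increase"))
  # permutation invariance over runs
  tab2 <- extract_promoters(list(w3, w1, w2), dict, min_frequency = 1)
  expect_equal(sort(tab2$key), sort(tab$key))
  expect_equal(tab2$role[order(tab2$key)], tab$role[order(tab$key)])
  # frequency cut and run-count precondition
  tab3 <- extract_promoters(list(w1, w2, w3), dict,
                            min_frequency = max(dict$n_active) + 1)
  expect_equal(nrow(tab3), 0L)
  expect_error(extract_promoters(list(w1, w2), dict), class = "cwqsar_config_error")
  # sorted by active-block frequency within role
  na_inc <- tab$n_active[tab$role == "increase"]
  expect_true(all(diff(na_inc) <= 0))
})
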