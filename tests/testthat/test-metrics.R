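test_that("iic follows the one-sided mean-absolute-residual formula", {
  # hand-worked case: delta = (-0.1, +0.1, -0.2, +0.4)
  obs <- c(1, 2, 3, 4)
  calc <- c(1.1, 1.9, 3.2, 3.6)
  r <- cor(obs, calc)
  expect_equal(iic(obs, calc), r * 0.15 / 0.25, tolerance = 1e-12)
  # perfect fit: IIC = r = 1
  expect_equal(iic(1:5, 1:5 + 0), 1)
  # symmetric residuals: ratio 1, IIC = r
  obs2 <- c(1, 2, 3, 4)
  calc2 <- c(1.2, 1.8, 3.2, 3.8)
  expect_equal(iic(obs2, calc2), cor(obs2, calc2), tolerance = 1e-12)
  # one-sided residuals: IIC = 0
  expect_equal(iic(c(1, 2, 3), c(0.9, 1.8, 2.7)), 0)
  expect_error(iic(c(1, 1, 1), 1:3), class = "cwqsar_numeric_error")
})

test_that("cii penalizes points whose removal improves the correlation", {
  # points on an exact line: every leave-one-out R2 equals 1, CII = 1
  expect_equal(cii(1:6, 2 * (1:6) - 3), 1)
  # removing the 4th point leaves an exact line: protest_4 = 1 - R2
  obs <- c(1, 2, 3, 10); calc <- c(1, 2, 3, 4)
  full <- cor(obs, calc)^2
  protests <- vapply(1:4, function(k) max(0, cor(obs[-k], calc[-k])^2 - full), 0)
  expect_equal(protests[4], 1 - full, tolerance = 1e-12)
  expect_equal(cii(obs, calc), 1 - sum(protests), tolerance = 1e-12)
  expect_error(cii(1:3, 1:3 + 0), class = "cwqsar_input_error")
})

test_that("ccc matches Lin's formula with population moments", {
  expect_equal(ccc(1:5, 1:5 + 0), 1)
  expect_equal(ccc(c(-1, 1), c(1, -1)), -1)
  # location shift: CCC < 1 and decreasing in |shift|
  x <- rnorm(30)
  expect_lt(ccc(x, x + 0.5), 1)
  expect_lt(ccc(x, x + 1), ccc(x, x + 0.5))
  expect_error(ccc(rep(1, 5), 1:5), class = "cwqsar_numeric_error")
})

test_that("q2_loo equals brute-force leave-one-out refitting", {
  set.seed(5)
  x <- rnorm(10); y <- 1 + 2 * x + rnorm(10, 0, 0.3)
  expect_equal(q2_loo(x, y), oracle_q2(x, y), tolerance = 1e-10)
  # exact linear relation: zero PRESS
  expect_equal(q2_loo(1:8, 3 - 0.5 * (1:8)), 1)
  # Q2 <= R2 for the same frozen descriptor
  expect_lte(q2_loo(x, y), r2(y, x))
})

test_that("f_ratio reproduces the one-descriptor F formula", {
  expect_equal(round(f_ratio(0.719, 210)), 532)
  expect_equal(round(f_ratio(0.5556, 210)), 260)
  expect_equal(f_ratio(0, 100), 0)
  # strictly increasing in r2 and n
  expect_gt(f_ratio(0.7, 100), f_ratio(0.6, 100))
  expect_gt(f_ratio(0.7, 200), f_ratio(0.7, 100))
  expect_error(f_ratio(1, 100), class = "cwqsar_numeric_error")
})

test_that("rmse and r2 behave as defined", {
  expect_equal(rmse(1:4, 1:4 + 0), 0)
  expect_equal(rmse(c(4, 5), c(1, 1)), sqrt(12.5))
  expect_equal(r2(1:5, 1:5 + 0), 1)
  # r2 invariant under affine transforms of the calculated series
  set.seed(8)
  o <- rnorm(20); c2 <- o + rnorm(20, 0, 0.2)
  expect_equal(r2(o, c2), r2(o, 3 - 2 * c2), tolerance = 1e-12)
})

test_that("metric implementations agree with brute-force oracles on random series", {
  set.seed(123)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    obs <- rnorm(n)
    calc <- obs * runif(1, 0.5, 1.5) + rnorm(n, 0, runif(1, 0.05, 1))
    expect_equal(iic(obs, calc), oracle_iic(obs, calc), tolerance = 1e-10)
    expect_equal(cii(obs, calc), oracle_cii(obs, calc), tolerance = 1e-10)
    expect_equal(ccc(obs, calc), oracle_ccc(obs, calc), tolerance = 1e-10)
    expect_equal(q2_loo(calc, obs), oracle_q2(calc, obs), tolerance = 1e-10)
    # shared invariants
    expect_lte(abs(iic(obs, calc)), abs(cor(obs, calc)) + 1e-12)
    expect_lte(cii(obs, calc), 1)
    expect_lte(ccc(obs, calc), abs(cor(obs, calc)) + 1e-12)
  }
})

test_that("metrics are invariant to record order", {
  set.seed(9)
  obs <- rnorm(25); calc <- obs + rnorm(25, 0, 0.3)
  perm <- sample(25)
  expect_equal(iic(obs, calc), iic(obs[perm], calc[perm]))
  expect_equal(cii(obs, calc), cii(obs[perm], calc[perm]))
  expect_equal(ccc(obs, calc), ccc(obs[perm], calc[perm]))
  expect_equal(rmse(obs, calc), rmse(obs[perm], calc[perm]))
})

test_that("metrics_report assembles the standard column set", {
  set.seed(10)
  obs <- rnorm(30); calc <- obs + rnorm(30, 0, 0.2)
  rep <- metrics_report(obs, calc)
  expect_named(rep, c("n", "r2", "ccc", "iic", "cii", "q2", "rmse", "f"))
  expect_equal(rep$n, 30)
  expect_equal(rep$r2, r2(obs, calc))
  expect_equal(rep$f, f_ratio(rep$r2, 30))
})
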