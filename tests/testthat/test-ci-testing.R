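test_that("Fisher z statistic matches its closed form", {
  set.seed(21)
  n <- 500
  x <- rnorm(n); y <- 0.4 * x + rnorm(n)
  m <- cbind(x = x, y = y)
  res <- testIndependence(m, "x", "y", method = "fisher-z")
  expect_equal(res@statistic, atanh(cor(x, y)) * sqrt(n - 3),
               tolerance = 1e-9)
  expect_lt(res@p_value, 1e-6)

  ## partial correlation via residualization agrees with the matrix-inverse
  ## formula on three variables
  z <- rnorm(n); x2 <- 0.6 * z + rnorm(n); y2 <- 0.6 * z + rnorm(n)
  m3 <- cbind(x = x2, y = y2, z = z)
  res3 <- testIndependence(m3, "x", "y", Z = "z", method = "fisher-z")
  om <- solve(cor(m3))
  pr <- -om["x", "y"] / sqrt(om["x", "x"] * om["y", "y"])
  expect_equal(res3@statistic, atanh(pr) * sqrt(n - 1 - 3),
               tolerance = 1e-9)
  expect_gt(res3@p_value, 0.001)  # conditionally independent by construction
})

test_that("degenerate inputs give the independence verdict", {
  set.seed(22)
  m <- cbind(a = rep(3, 100), b = rnorm(100),
             y = rbinom(100, 1, 0.5))
  for (meth in c("fisher-z", "logistic-lrt", "g2-discrete")) {
    res <- testIndependence(m, "a", "y", method = meth)
    expect_equal(res@p_value, 1)
    expect_equal(res@statistic, 0)
  }
  ## unreliable: conditioning set too large for the sample
  msmall <- cbind(x = rnorm(12), y = rbinom(12, 1, 0.5),
                  z1 = rnorm(12), z2 = rnorm(12), z3 = rnorm(12))
  r <- testIndependence(msmall, "x", "y", Z = c("z1", "z2", "z3"),
                        method = "logistic-lrt")
  expect_false(r@reliable)
  expect_equal(r@p_value, 1)
})

test_that("G2 on a uniform three-way table is exactly zero", {
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  m <- as.matrix(g[rep(seq_len(8), each = 50), ])
  res <- testIndependence(m, "x", "y", Z = "z", method = "g2-discrete")
  expect_equal(res@statistic, 0)
  expect_equal(res@p_value, 1)
  expect_equal(res@dof, 2)
})

test_that("discretization schemes are monotone with predictable occupancy", {
  b <- discretize(1:100, n_bins = 4, scheme = "quantile")
  expect_identical(as.integer(table(b)), rep(25L, 4))
  expect_true(all(diff(b[order(1:100)]) >= 0))

  expect_warning(b1 <- discretize(rep(2, 50), n_bins = 3), "collapsed")
  expect_identical(unique(b1), 0L)

  ## rank invariance: monotone transforms leave quantile bins unchanged
  set.seed(23)
  v <- rnorm(200)
  expect_identical(discretize(v, 4), discretize(exp(v), 4))

  expect_error(discretize(1:10, n_bins = 1), "n_bins")
})

test_that("association ranking finds true causes and is deterministic", {
  net <- buildTruthNetwork(8, 1, effect_sizes = 0.75, seed = 24)
  hits <- vapply(1:20, function(s) {
    ct <- sampleCohort(net, 2000, seed = s)
    rk <- associationRank(ct, "survival_2y",
                          networkVariables(net))
    rk$variable[1] == "X1"
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  ## deterministic ordering under exact ties (duplicate pair)
  netd <- buildTruthNetwork(2, 1, effect_sizes = 0.8, seed = 25,
                            equivalence_spec = list(
                              list(source = "X1", mode = "duplicate")))
  ct <- sampleCohort(netd, 1000, seed = 26)
  rk1 <- associationRank(ct, "survival_2y", networkVariables(netd))
  rk2 <- associationRank(ct, "survival_2y", networkVariables(netd))
  expect_identical(rk1, rk2)
  ## duplicates occupy adjacent ranks with identical strength
  i <- match(c("X1", "X1_eq1"), rk1$variable)
  expect_equal(abs(diff(i)), 1)
  expect_equal(rk1$strength[i[1]], rk1$strength[i[2]])
})

test_that("rejection rates grow with effect size and sample size", {
  rate <- function(beta, n, reps = 120) {
    mean(vapply(seq_len(reps), function(s) {
      set.seed(1e4 + s)
      x <- rnorm(n)
      y <- rbinom(n, 1, plogis(beta * x))
      testIndependence(cbind(x = x, y = y), "x", "y",
                       method = "logistic-lrt")@p_value < 0.05
    }, TRUE))
  }
  expect_gt(rate(0.8, 200), rate(0.15, 200))
  expect_gt(rate(0.15, 1500), rate(0.15, 200))
})

test_that("logistic LRT and G2 agree on clear independence calls", {
  agree <- vapply(1:100, function(s) {
    set.seed(3e4 + s)
    n <- 600
    z <- rbinom(n, 1, 0.5)
    alt <- s %% 2 == 0
    x <- rbinom(n, 1, plogis(0.8 * z))
    y <- rbinom(n, 1, plogis(0.7 * z + if (alt) 1.2 * x else 0))
    m <- cbind(x = x, y = y, z = z)
    p1 <- testIndependence(m, "x", "y", "z", method = "logistic-lrt")@p_value
    p2 <- testIndependence(m, "x", "y", "z", method = "g2-discrete")@p_value
    (p1 < 0.05) == (p2 < 0.05)
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})
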