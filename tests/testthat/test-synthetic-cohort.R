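test_that("network construction records the requested causal structure", {
  net <- buildTruthNetwork(10, 5,
                           effect_sizes = c(-0.75, 0.75, -0.75, 0.75, -0.75),
                           seed = 1, horizons = 3)
  ## structural parameters read back exactly as requested
  for (h in 1:3) {
    co <- net@outcome[[h]]$coefficients
    expect_identical(unname(co[paste0("X", 1:5)]),
                     c(-0.75, 0.75, -0.75, 0.75, -0.75))
  }
  expect_identical(trueMarkovBoundary(net, 1), paste0("X", 1:5))
  ## graph is a DAG with terminal outcomes
  expect_true(validObject(net))
  out_ids <- net@nodes$id[net@nodes$role == "outcome"]
  expect_length(out_ids, 3)
  expect_false(any(net@edges$from %in% out_ids))

  ## no-cause network: outcome depends only on the intercept
  net0 <- buildTruthNetwork(5, 0, seed = 2)
  expect_identical(trueMarkovBoundary(net0, 1), character())

  expect_error(buildTruthNetwork(0, 0, seed = 1), "at least one")
  expect_error(buildTruthNetwork(5, 2, effect_sizes = 1, seed = 1), "length")
  expect_error(
    buildTruthNetwork(3, 1, seed = 1,
                      equivalence_spec = list(list(source = "nope",
                                                   mode = "duplicate"))),
    "not a network variable")
})

test_that("cyclic custom specifications fail structural validation", {
  expect_error(
    customTruthNetwork(
      node_params = list(
        A = list(dist = "gaussian-child", coef = c(B = 1), sd = 1),
        B = list(dist = "gaussian-child", coef = c(A = 1), sd = 1)),
      roles = c(A = "clinical-continuous", B = "clinical-continuous"),
      outcome = list("2" = list(intercept = 0, coefficients = c(A = 1)))),
    "acyclic")
})

test_that("sampling is reproducible and respects variable types and splits", {
  net <- buildTruthNetwork(12, 3, seed = 3, horizons = 2,
                           equivalence_spec = list(
                             list(source = "X1", mode = "duplicate")))
  ct1 <- sampleCohort(net, 400, seed = 9)
  ct2 <- sampleCohort(net, 400, seed = 9)
  expect_identical(cohortMatrix(ct1), cohortMatrix(ct2))
  expect_identical(outcomeLabels(ct1, 2), outcomeLabels(ct2, 2))

  m <- cohortMatrix(ct1)
  roles <- variableRoles(ct1)
  cnt <- m[, roles == "smrna-count", drop = FALSE]
  expect_true(all(cnt >= 0) && all(cnt == round(cnt)))
  ord <- m[, roles == "clinical-ordinal", drop = FALSE]
  expect_true(all(ord %in% 0:3))

  ## exact duplicate correlates 1.0 by construction
  expect_equal(cor(m[, "X1"], m[, "X1_eq1"]), 1.0)

  ## split tags partition the samples; discovery + internal = expanded
  sp <- sampleSplits(ct1)
  expect_true(all(sp %in% c("discovery-subset", "internal-validation",
                            "external-validation")))
  exp_d <- cohortSubset(ct1, "expanded-discovery")
  expect_equal(ncol(exp_d),
               sum(sp %in% c("discovery-subset", "internal-validation")))

  ## shared latent risk: horizon labels are nested (alive at 5y => alive
  ## at 2y, because the 2y intercept is larger with shared coefficients)
  l2 <- outcomeLabels(ct1, 2); l5 <- outcomeLabels(ct1, 5)
  expect_true(all(l2[l5 == 1] == 1))
})

test_that("empirical outcome rate matches the logistic intercept", {
  ## with no causes the survival rate is exactly plogis(intercept)
  net <- buildTruthNetwork(3, 0, seed = 5, intercepts = qlogis(0.7))
  ct <- sampleCohort(net, 10000, seed = 6)
  rate <- mean(outcomeLabels(ct, 2))
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(rate - 0.7), 3 * se)
})

test_that("true boundary agrees with the brute-force d-separation oracle", {
  ## chain: the mediator alone is the unique minimal sufficient set
  chain <- chainNetwork(seed = 7)
  expect_identical(trueMarkovBoundary(chain, 1), "M")
  expect_identical(minimalSufficientSets(chain), list("M"))
  expect_true(dSeparated(chain, "X", "survival_2y", "M"))
  expect_false(dSeparated(chain, "X", "survival_2y"))

  ## outcome parents {A, B}: terminal-node MB equals the parent set
  net <- buildTruthNetwork(4, 2, seed = 8)
  expect_identical(minimalSufficientSets(net), list(c("X1", "X2")))

  ## duplicate injection yields exactly one extra minimal set per copy
  netd <- buildTruthNetwork(2, 2, seed = 9,
                            equivalence_spec = list(
                              list(source = "X1", mode = "duplicate")))
  ms <- minimalSufficientSets(netd)
  expect_length(ms, 2)
  expect_true(any(vapply(ms, identical, TRUE, y = c("X1", "X2"))))
  expect_true(any(vapply(ms, identical, TRUE, y = sort(c("X1_eq1", "X2")))))
})

test_that("noisy copies converge to duplicates as SNR grows", {
  snrs <- c(4, 25, Inf)
  cors <- vapply(snrs, function(s) {
    net <- buildTruthNetwork(1, 1, seed = 11,
                             cause_roles = "clinical-continuous",
                             equivalence_spec = list(
                               list(source = "X1", mode = "noisy-copy",
                                    snr = s)))
    m <- cohortMatrix(sampleCohort(net, 3000, seed = 12))
    cor(m[, "X1"], m[, "X1_eq1"])
  }, 1.0)
  expect_true(all(diff(cors) > 0) || cors[3] == 1)
  expect_equal(cors[3], 1.0)           # SNR = Inf behaves as duplicate
  expect_gt(cors[1], 0.8)              # cor ~ 1/sqrt(1 + 1/snr)
  expect_lt(cors[1], 0.95)
})

test_that("network serialization round-trips through JSON", {
  net <- buildTruthNetwork(6, 2, seed = 13, horizons = 2,
                           equivalence_spec = list(
                             list(source = "X2", mode = "noisy-copy",
                                  snr = 9)))
  path <- tempfile(fileext = ".json")
  writeTruthNetwork(net, path)
  net2 <- readTruthNetwork(path)
  expect_identical(trueMarkovBoundary(net, 1), trueMarkovBoundary(net2, 1))
  ct1 <- sampleCohort(net, 200, seed = 14)
  ct2 <- sampleCohort(net2, 200, seed = 14)
  expect_equal(cohortMatrix(ct1), cohortMatrix(ct2))
  expect_identical(outcomeLabels(ct1, 2), outcomeLabels(ct2, 2))
})
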