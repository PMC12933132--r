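test_that("faithful data yields a single boundary equal to its own class", {
  net <- buildTruthNetwork(4, 2, seed = 51)
  ct <- sampleCohort(net, 2500, seed = 52)
  ec <- enumerateMBs(ct, "survival_2y", DiscoveryConfig())
  expect_length(mbBoundaries(ec), 1)
  expect_identical(mbIntersection(ec), mbUnion(ec))
  expect_identical(mbIntersection(ec),
                   sort(mbMembers(mbBoundaries(ec)[[1]])))
  expect_true(all(mbFrequency(ec) == 1))
})

test_that("a duplicated member splits into two non-co-occurring boundaries", {
  net <- buildTruthNetwork(2, 2, seed = 53,
                           equivalence_spec = list(
                             list(source = "X1", mode = "duplicate")))
  ct <- sampleCohort(net, 3000, seed = 54)
  ec <- enumerateMBs(ct, "survival_2y", DiscoveryConfig())
  sets <- lapply(mbBoundaries(ec), function(b) sort(mbMembers(b)))
  expect_gte(length(sets), 2)
  ## the duplicated pair never co-occurs in one boundary
  for (s in sets)
    expect_false(all(c("X1", "X1_eq1") %in% s))
  ## both copies are excluded from the intersection; the non-duplicated
  ## member stays in it
  inter <- mbIntersection(ec)
  expect_false(any(c("X1", "X1_eq1") %in% inter))
  expect_true("X2" %in% inter)
  fr <- mbFrequency(ec)
  expect_equal(unname(fr["X2"]), 1.0)
  expect_equal(unname(fr["X1"]), 0.5)
  expect_equal(unname(fr["X1_eq1"]), 0.5)
  ## matches the brute-force enumeration of minimal sufficient sets
  oracle <- minimalSufficientSets(net)
  expect_setequal(vapply(sets, paste, "", collapse = ","),
                  vapply(oracle, paste, "", collapse = ","))
})

test_that("boundary verification accepts equivalents and rejects deficits", {
  net <- buildTruthNetwork(3, 3, seed = 55,
                           equivalence_spec = list(
                             list(source = "X2", mode = "duplicate")))
  ct <- sampleCohort(net, 4000, seed = 56)
  ref <- gllMB(ct, "survival_2y", DiscoveryConfig())
  expect_setequal(mbMembers(ref), c("X1", "X2", "X3"))

  for (vf in c("independence", "performance-equivalence")) {
    ## self-equivalence
    expect_true(verifyBoundary(ct, "survival_2y", mbMembers(ref), ref,
                               verifier = vf)$pass)
    ## swapping a member for its exact duplicate preserves equivalence
    swapped <- c(setdiff(mbMembers(ref), "X2"), "X2_eq1")
    expect_true(verifyBoundary(ct, "survival_2y", swapped, ref,
                               verifier = vf)$pass)
    ## dropping a true cause with no equivalent fails
    deficient <- setdiff(mbMembers(ref), "X1")
    expect_false(verifyBoundary(ct, "survival_2y", deficient, ref,
                                verifier = vf)$pass)
  }
})

test_that("class summaries report frequencies, cores and size ranges", {
  ec1 <- mkClass(list(c("A", "B", "C")))
  s1 <- summarizeClass(ec1)
  expect_true(all(s1$frequency == 1))
  expect_true(all(s1$in_intersection))

  ## three boundaries sharing a four-variable core
  core <- c("A", "B", "C", "D")
  ec3 <- mkClass(list(c(core, "E"), c(core, "F"), c(core, "G")))
  s3 <- summarizeClass(ec3)
  expect_true(all(s3$frequency[s3$variable %in% core] == 1))
  expect_equal(sort(s3$variable[s3$in_intersection]), core)
  expect_equal(s3$frequency[s3$variable == "E"], 1 / 3)
  expect_identical(attr(s3, "boundary_sizes"), c(5L, 5L))
  expect_match(s3$interpretation[s3$variable == "A"], "direct cause")
})

test_that("re-enumeration is deterministic and budget exhaustion is flagged", {
  net <- buildTruthNetwork(2, 2, seed = 57,
                           equivalence_spec = list(
                             list(source = "X1", mode = "duplicate")))
  ct <- sampleCohort(net, 2500, seed = 58)
  ec1 <- enumerateMBs(ct, "survival_2y", DiscoveryConfig())
  ec2 <- enumerateMBs(ct, "survival_2y", DiscoveryConfig())
  expect_identical(lapply(mbBoundaries(ec1), mbMembers),
                   lapply(mbBoundaries(ec2), mbMembers))
  ## closure: every boundary produced by masking a single accepted
  ## variable is either already in the class or rejected by the verifier
  u <- mbUnion(ec1)
  all_sets <- lapply(mbBoundaries(ec1), function(b) sort(mbMembers(b)))
  m0 <- mbBoundaries(ec1)[[1]]
  for (v in u) {
    b <- gllMB(ct, "survival_2y", DiscoveryConfig(),
               candidates = setdiff(networkVariables(net), v))
    in_class <- any(vapply(all_sets, identical, TRUE,
                           y = sort(mbMembers(b))))
    accepted <- verifyBoundary(ct, "survival_2y", mbMembers(b), m0,
                               verifier = "independence",
                               alpha = 0.01)$pass
    expect_true(in_class || !accepted)
  }
  ec_b <- enumerateMBs(ct, "survival_2y", DiscoveryConfig(), budget = 1L)
  expect_true("possibly-incomplete" %in% ec_b@flags)
})
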