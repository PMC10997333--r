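makeCounts <- function(agent, patient, do, other) {
  data.frame(sentence_id = paste0("s", seq_along(agent)),
             agent_count = agent, patient_count = patient,
             do_count = do, other_scf_count = other)
}

test_that("ratio measures are definitional count ratios with optional smoothing", {
  tab <- ratioMeasures(makeCounts(30, 10, 40, 40))
  expect_equal(tab$agenthood, 3.0)
  expect_equal(tab$patienthood, 1 / 3)
  expect_equal(tab$transitivity, 1.0)
  expect_equal(tab$intransitivity, 1.0)

  sm <- ratioMeasures(makeCounts(0, 5, 2, 3), smoothing = 1)
  expect_equal(sm$agenthood, 1 / 6)

  expect_error(ratioMeasures(makeCounts(0, 5, 2, 3)), "smoothing")
  expect_error(ratioMeasures(makeCounts(-1, 5, 2, 3)), "non-negative")

  # reciprocal structure whenever counts are positive
  set.seed(1)
  r <- ratioMeasures(makeCounts(sample(1:99, 20), sample(1:99, 20),
                                sample(1:99, 20), sample(1:99, 20)))
  expect_equal(r$agenthood * r$patienthood, rep(1, 20))
  expect_equal(r$transitivity * r$intransitivity, rep(1, 20))
})

test_that("interpretation indices multiply ratios; the log index is direction-free", {
  tab <- data.frame(agenthood = 0.5, patienthood = 2,
                    transitivity = 3, intransitivity = 1 / 3)
  out <- interpretationIndices(tab)
  expect_equal(out$passive_index, 6)
  expect_equal(out$active_index, 0.5 / 3)

  flat <- interpretationIndices(
    data.frame(agenthood = 1, patienthood = 1,
               transitivity = 1, intransitivity = 1))
  expect_equal(flat$nondirectional_index, 0)

  # joint reciprocal swap leaves the non-directional index unchanged but
  # swaps passive and active indices
  a <- interpretationIndices(
    data.frame(agenthood = 2, patienthood = 1 / 2,
               transitivity = 1 / 4, intransitivity = 4))
  b <- interpretationIndices(
    data.frame(agenthood = 1 / 2, patienthood = 2,
               transitivity = 4, intransitivity = 1 / 4))
  expect_equal(a$nondirectional_index, b$nondirectional_index)
  expect_equal(a$nondirectional_index, log(2) * log(4))
  expect_equal(a$passive_index, b$active_index)
  expect_false(isTRUE(all.equal(a$passive_index, b$passive_index)))

  # reciprocal structure: passive x active = 1 when built from raw ratios
  set.seed(2)
  r <- ratioMeasures(makeCounts(sample(1:99, 15), sample(1:99, 15),
                                sample(1:99, 15), sample(1:99, 15)))
  idx <- interpretationIndices(r)
  expect_equal(idx$passive_index * idx$active_index, rep(1, 15))
})

test_that("continuation probabilities and contextual transitivity", {
  raw <- rbind(
    data.frame(sentence_id = c("s1", "s2", "s3"), gate = "afterV1",
               n_responses = 30, n_direct_object = c(15, 0, 24),
               n_prepositional_phrase = c(10, 20, 3), n_main_verb = 0),
    data.frame(sentence_id = c("s1", "s2", "s3"), gate = "afterPP",
               n_responses = 18, n_direct_object = 0,
               n_prepositional_phrase = 0, n_main_verb = c(9, 0, 18)))
  expect_warning(out <- continuationProbabilities(raw), "clipped")
  expect_equal(out$DO_prob, c(0.5, 0, 0.8))
  expect_equal(out$MV_prob, c(0.5, 0, 1))
  expect_equal(out$ctx_transitivity[1], 1.0)
  expect_equal(out$ctx_transitivity[3], 4.0)
  expect_true(is.finite(out$ctx_transitivity[2]))
  expect_equal(out$ctx_transitivity * out$ctx_intransitivity, rep(1, 3))

  bad <- raw
  bad$n_direct_object[1] <- 99
  expect_error(continuationProbabilities(bad), "exceeds")
})

test_that("permutation Spearman p-values: perfect monotone, enumeration oracle, null validity", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3, 2.3, 8.4)
  ps <- permutationSpearman(x, x, nPerm = 999L, seed = 1L)
  expect_equal(ps$rho, 1)
  expect_equal(ps$p, 1 / 1000)

  # tiny n: estimate approaches the exhaustive-enumeration p
  set.seed(5)
  x5 <- rnorm(5); y5 <- rnorm(5)
  exact <- oraclePermP(x5, y5)
  est <- permutationSpearman(x5, y5, nPerm = 20000L, seed = 2L)$p
  expect_lt(abs(est - exact), 0.02)

  # independent draws: rejection rate at alpha = 0.05 within binomial CI
  set.seed(6)
  rej <- replicate(200, {
    permutationSpearman(rnorm(60), rnorm(60), nPerm = 199L,
                        seed = sample.int(1e6, 1))$p < 0.05
  })
  ci <- qbinom(c(0.005, 0.995), 200, 0.05)
  expect_gte(sum(rej), ci[1])
  expect_lte(sum(rej), ci[2])

  expect_error(permutationSpearman(rep(1, 6), rnorm(6)), "constant")
})

test_that("BH step-up flags match a literal implementation", {
  expect_true(all(fdrCorrect(rep(0.001, 10))$significant))
  expect_false(any(fdrCorrect(rep(1, 8))$significant))
  expect_equal(fdrCorrect(c(0.01, 0.02, 0.20))$significant,
               c(TRUE, TRUE, FALSE))
  expect_error(fdrCorrect(numeric(0)), "empty")
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_equal(fdrCorrect(p)$significant, oracleBH(p, 0.05))
  }
})

test_that("summary-statistics t-test reproduces hand and printed values", {
  expect_equal(summaryTwoSampleT(1, 1, 10, 1, 1, 10)$t, 0)
  ht <- summaryTwoSampleT(1, 1, 2, 0, 1, 2)
  expect_equal(ht$t, 1.0)
  expect_equal(ht$df, 2)
  # the printed direct-object probability contrast of the two verb lists
  pt <- summaryTwoSampleT(0.71, 0.16, 60, 0.44, 0.19, 59)
  expect_equal(pt$df, 117)
  expect_lt(abs(pt$t - 8.45) / 8.45, 0.02)
  expect_error(summaryTwoSampleT(1, 0, 5, 0, 1, 5), "sd")
})
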