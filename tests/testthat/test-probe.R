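test_that("probe recovers planted squared-norm depths on noiseless data", {
  pp <- plantedProblem(nSets = 3L, d = 8L, k = 4L, noiseSd = 0)
  gen <- pp$gen
  probe <- trainProbe(gen$embeddings, gen$gold, k = 4L, nRestarts = 2L,
                      seed = 5L, maxIter = 2500L, lr = 1e-2)
  errs <- vapply(names(gen$gold), function(kk) {
    pred <- predictDepths(probe, gen$embeddings@embeddings[[kk]])@depths
    max(abs(pred - gen$gold[[kk]]))
  }, numeric(1))
  expect_lt(max(errs), 1e-3)
  # accepted loss trace is monotone non-increasing
  expect_true(all(diff(probe@meta$trace) <= 1e-12))
})

test_that("probe training honours restart count and zero targets", {
  pp <- plantedProblem(nSets = 2L, d = 6L, k = 3L)
  gold0 <- lapply(pp$gen$gold, function(g) g * 0)
  probe <- trainProbe(pp$gen$embeddings, gold0, k = 3L, nRestarts = 10L,
                      seed = 2L, maxIter = 150L)
  expect_length(probe@meta$restart_losses, 10L)
  pred <- predictDepths(probe,
                        pp$gen$embeddings@embeddings[[1]])@depths
  expect_lt(max(pred), 1e-2)  # transform driven to (near) zero map
  expect_error(trainProbe(pp$gen$embeddings, list()), "empty training set")
})

test_that("predicted depth is the squared norm of the transformed embedding", {
  B <- matrix(c(1, 0, 0, 2), 2, 2)
  probe <- new("ProbeModel", transform = B, meta = list())
  expect_equal(depths(predictDepths(probe, matrix(0, 1, 2))), 0)
  one <- new("ProbeModel", transform = matrix(1, 1, 1), meta = list())
  expect_equal(depths(predictDepths(one, matrix(1.7, 1, 1))), 1.7^2)

  set.seed(3)
  H <- matrix(rnorm(12), 6, 2)
  expect_equal(depths(predictDepths(probe, H)),
               apply(H, 1, function(h) sum((B %*% h)^2)))
  expect_error(predictDepths(probe, matrix(0, 1, 3)), "dimension")

  # invariance under joint orthogonal rotation of the transform rows
  th <- 0.6
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- new("ProbeModel", transform = Q %*% B, meta = list())
  expect_equal(depths(predictDepths(rot, H)), depths(predictDepths(probe, H)))
})

test_that("restart averaging is an element-wise mean and commutes with prediction", {
  a <- new("ParseDepthVector", sentenceId = "s", depths = c(0, 2),
           source = "probe")
  b <- new("ParseDepthVector", sentenceId = "s", depths = c(2, 0),
           source = "probe")
  expect_equal(depths(averageRestarts(list(a, b))), c(1, 1))
  expect_equal(depths(averageRestarts(list(a, a, a))), depths(a))
  set.seed(8)
  vecs <- replicate(10, rnorm(4), simplify = FALSE)
  expect_equal(depths(averageRestarts(vecs)),
               Reduce(`+`, vecs) / 10)
  expect_error(averageRestarts(list(a, rnorm(3))), "mismatch")

  # identical transforms across restarts: averaging changes nothing
  B <- matrix(rnorm(6), 2, 3)
  pm <- new("ProbeModel", transform = B,
            meta = list(restart_transforms = list(B, B, B)))
  H <- matrix(rnorm(9), 3, 3)
  expect_equal(depths(predictDepthsAveraged(pm, H)),
               depths(predictDepths(pm, H)))
})

test_that("root accuracy is 1 on noiseless planted data, 0 for a zero probe, chance for shuffled labels", {
  pp <- plantedProblem(nSets = 3L, d = 8L, k = 4L, noiseSd = 0)
  probe <- trainProbe(pp$gen$embeddings, pp$gen$gold, k = 4L,
                      nRestarts = 1L, seed = 5L, maxIter = 2500L, lr = 1e-2)
  expect_equal(rootAccuracy(probe, pp$gen$embeddings, pp$mv), 1.0)

  zero <- new("ProbeModel", transform = matrix(0, 4, 8), meta = list())
  expect_equal(rootAccuracy(zero, pp$gen$embeddings, pp$mv), 0)

  # random main-verb annotation: accuracy ~ mean(1 / n_tokens)
  big <- plantedProblem(nSets = 25L, d = 8L, k = 4L, noiseSd = 0, seed = 3L)
  probeB <- trainProbe(big$gen$embeddings, big$gen$gold, k = 4L,
                       nRestarts = 1L, seed = 5L, maxIter = 2000L, lr = 1e-2)
  set.seed(9)
  nTok <- big$stimuli$sentences$n_tokens[big$stimuli$sentences$is_target]
  shuffled <- setNames(vapply(nTok, function(n) sample.int(n, 1), 1L),
                       names(big$mv))
  acc <- rootAccuracy(probeB, big$gen$embeddings, shuffled)
  p0 <- mean(1 / nTok)
  ci <- qbinom(c(0.005, 0.995), length(nTok), p0) / length(nTok)
  expect_gte(acc, ci[1])
  expect_lte(acc, ci[2])
  expect_error(rootAccuracy(probe, pp$gen$embeddings, big$mv[0]),
               "main-verb annotation")
})

test_that("positional contribution matches enumeration and ranks content above function words", {
  # a position with identical depth across sentences contributes nothing
  m <- cbind(rep(2, 5), c(1, 2, 3, 4, 5), c(0, 1, 0, 1, 0))
  expect_equal(positionContribution(m, 1L, nShuffles = 20L), 0)

  # prefix length 2: only two rank orders exist; brute-force expectation
  set.seed(4)
  m2 <- cbind(runif(6), runif(6))
  got <- positionContribution(m2, 2L, nShuffles = 4000L, seed = 1L)
  nS <- nrow(m2)
  exp_dist <- 0
  for (i in seq_len(nS)) {
    vals <- sapply(seq_len(nS), function(j)
      1 - cor(m2[i, ], c(m2[i, 1], m2[j, 2]), method = "spearman"))
    exp_dist <- exp_dist + mean(vals) / nS
  }
  expect_lt(abs(got - exp_dist), 0.05)

  # constant vectors: distance undefined
  expect_warning(
    out <- positionContribution(matrix(1, 4, 3), 2L, nShuffles = 5L),
    "constant")
  expect_true(is.na(out))

  # cross-sentence variance carried by content positions, not determiners
  set.seed(12)
  depthM <- cbind(rep(2, 40), rnorm(40, 1, 0.6), rnorm(40, 1.2, 0.8))
  contDet <- positionContribution(depthM, 1L, nShuffles = 200L, seed = 2L)
  contV1 <- positionContribution(depthM, 3L, nShuffles = 200L, seed = 2L)
  expect_gt(contV1, contDet)
})
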