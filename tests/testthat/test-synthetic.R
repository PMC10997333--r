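test_that("stimulus generation matches the design counts and is deterministic", {
  st <- generateStimuli(60, seed = 1)
  expect_equal(nrow(st$sentences), 360)
  expect_equal(sum(st$sentences$is_target), 120)
  expect_setequal(unique(st$sentences$condition),
                  c("UNA", "HiTrans", "LoTrans", "PAS", "DO1", "DO2"))

  tiny <- generateStimuli(1, seed = 2)
  expect_equal(nrow(tiny$sentences), 6)
  expect_equal(sum(tiny$sentences$is_target), 2)
  for (id in targetIds(tiny)) {
    tr <- tiny$trees[[id]]
    expect_named(tr, c("passive", "active"))
    expect_equal(tokens(tr$active),
                 tokens(tr$passive)[seq_len(nTokens(tr$active))])
    expect_equal(depths(nodeDepths(tr$passive))[3], 2)
    expect_equal(depths(nodeDepths(tr$active))[3], 0)
  }
  expect_identical(generateStimuli(5, seed = 9), generateStimuli(5, seed = 9))
})

test_that("planted embeddings reproduce the schedule exactly at zero noise", {
  st <- generateStimuli(2, seed = 3)
  gen <- generateEmbeddings(st, d = 10, k = 5, noiseSd = 0, seed = 4)
  for (key in names(gen$gold)) {
    H <- gen$embeddings@embeddings[[key]]
    got <- rowSums((H %*% t(gen$B0))^2)
    expect_equal(got, gen$gold[[key]], tolerance = 1e-9)
  }
  # the LoTrans schedule moves Verb1 depth up toward 2 at the main verb
  lo <- grep("LoTrans", targetIds(st), value = TRUE)[1]
  row <- st$sentences[st$sentences$sentence_id == lo, ]
  atV1 <- gen$gold[[paste0(lo, "#", row$v1_pos)]][row$v1_pos]
  atMV <- gen$gold[[paste0(lo, "#", row$mv_pos)]][row$v1_pos]
  expect_gt(v1DepthChange(atMV, atV1), 0)
  expect_equal(atMV, 2)

  # noise degrades probe-side recovery monotonically
  cors <- vapply(c(0, 0.3, 1.5), function(ns) {
    g <- generateEmbeddings(st, d = 10, k = 5, noiseSd = ns, seed = 5)
    pred <- unlist(lapply(names(g$gold), function(kk)
      rowSums((g$embeddings@embeddings[[kk]] %*% t(g$B0))^2)))
    cor(pred, unlist(g$gold))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_equal(cors[1], 1, tolerance = 1e-9)
})

test_that("corpus counts carry the transitivity gap and calibrate to the target means", {
  st <- generateStimuli(60, seed = 6)
  cc <- generateCorpusCounts(st, seed = 7)
  expect_true(all(cc[, c("agent_count", "patient_count", "do_count",
                         "other_scf_count")] >= 1))
  tab <- interpretationIndices(ratioMeasures(cc))
  hi <- log(tab$transitivity[tab$condition == "HiTrans"])
  lo <- log(tab$transitivity[tab$condition == "LoTrans"])
  expect_gt(t.test(hi, lo)$statistic, 3)

  # gap 0: conditions indistinguishable (no systematic t inflation)
  set.seed(8)
  t0 <- replicate(40, {
    c0 <- generateCorpusCounts(st, doMeanHi = 0.55, doSdHi = 0.17,
                               doMeanLo = 0.55, doSdLo = 0.17,
                               seed = sample.int(1e6, 1))
    r <- ratioMeasures(c0)
    t.test(log(r$transitivity[r$condition == "HiTrans"]),
           log(r$transitivity[r$condition == "LoTrans"]))$p.value
  })
  expect_lte(sum(t0 < 0.05), qbinom(0.999, 40, 0.05))
  expect_identical(generateCorpusCounts(st, seed = 11),
                   generateCorpusCounts(st, seed = 11))

  # continuation DO probability recovers the calibration means
  ct <- generateContinuations(st, seed = 9)
  cp <- suppressWarnings(continuationProbabilities(ct))  # boundary clipping
  cond <- st$sentences$condition[st$sentences$is_target]
  mHi <- mean(cp$DO_prob[cond == "HiTrans"])
  mLo <- mean(cp$DO_prob[cond == "LoTrans"])
  expect_lt(abs(mHi - 0.71), 3 * 0.18 / sqrt(60))
  expect_lt(abs(mLo - 0.44), 3 * 0.21 / sqrt(60))
  # and DO probability correlates with corpus transitivity across sentences
  merged <- merge(cp, tab, by = "sentence_id")
  expect_gt(cor(merged$DO_prob, log(merged$transitivity),
                method = "spearman"), 0.3)
})

test_that("epoch arrays honour the declared dimensions and planted geometry", {
  st <- generateStimuli(8, seed = 12)
  ids <- targetIds(st)
  mesh <- generateMesh(15, seed = 13)
  ep0 <- generateEpochs(ids, mesh, nParticipants = 3, seed = 14)
  expect_equal(dim(ep0@data), c(3, 16, 15, 120))  # 600 ms at 200 Hz
  expect_equal(ep0@times[2] - ep0@times[1], 5)
  expect_identical(generateEpochs(ids, mesh, nParticipants = 2, seed = 15),
                   generateEpochs(ids, mesh, nParticipants = 2, seed = 15))

  set.seed(16)
  rdm <- modelRdm(runif(length(ids)), "absolute_difference",
                  conditions = ids)
  effV <- 1:4
  ep <- generateEpochs(ids, mesh, nParticipants = 2, effects = list(
    list(vertices = effV, window = c(100, 250), rdm = rdm, size = 2)),
    seed = 17)
  sl <- which(ep@times >= 100 & ep@times <= 250)
  dr <- dataRdm(ep, effV, sl, participant = 1, normalize = FALSE)
  expect_gt(fitModel(rdm, dr), 0.5)

  # invalid effect declarations are rejected
  expect_error(generateEpochs(ids, mesh, effects = list(
    list(vertices = effV, window = c(100, 250), rdm = rdm, size = 0))),
    "positive")
  rdm2 <- modelRdm(runif(length(ids)), "absolute_difference",
                   conditions = ids)
  expect_error(generateEpochs(ids, mesh, nParticipants = 2, effects = list(
    list(vertices = effV, window = c(100, 250), rdm = rdm, size = 1),
    list(vertices = 3:6, window = c(200, 350), rdm = rdm2, size = 1)),
    seed = 18), "contradictory")
})

test_that("array containers and probe serialization round-trip", {
  a <- array(rnorm(24), c(2, 3, 4))
  tmp <- tempfile(fileext = ".rds")
  writeArray(a, tmp, dimLabels = c("p", "v", "t"), meta = list(rate = 200))
  back <- readArray(tmp)
  expect_equal(back$data, a)
  expect_equal(back$meta$dim, c(2, 3, 4))
  expect_equal(back$meta$rate, 200)

  pm <- new("ProbeModel", transform = matrix(rnorm(6), 2, 3),
            meta = list(restart_losses = c(0.2, 0.1), best_restart = 2))
  tp <- tempfile(fileext = ".tsv")
  writeProbe(pm, tp)
  got <- readProbe(tp)
  expect_equal(got@transform, pm@transform, tolerance = 1e-12)
  expect_equal(got@meta$restart_losses, c(0.2, 0.1))
})
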