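meshFromCoords <- function(xyz) {
  data.frame(vertex_id = sprintf("v%d", seq_len(nrow(xyz))),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("searchlight neighborhoods and windows follow the radius rules", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  idx <- searchlightIndex(meshFromCoords(xyz), seq(0, 595, by = 5))
  expect_equal(idx$neighbors[[1]], c(1L, 2L))
  expect_equal(idx$neighbors[[2]], c(1L, 2L))
  expect_equal(idx$neighbors[[3]], 3L)  # isolated: itself only

  # 30 ms radius at 200 Hz: 13 samples mid-epoch, clipped at the edges
  expect_length(idx$windows[[30]], 13)
  expect_length(idx$windows[[1]], 7)
  expect_length(idx$windows[[120]], 7)
  expect_true(all(vapply(seq_along(idx$windows), function(i)
    idx$centerIdx[i] %in% idx$windows[[i]], logical(1))))

  # regular 4-mm grid: agree with the all-pairs brute-force scan
  g <- as.matrix(expand.grid(x = seq(0, 16, 4), y = seq(0, 16, 4), z = 0))
  idxg <- searchlightIndex(meshFromCoords(g), c(0, 5))
  oracle <- oracleNeighbors(g, 10)
  expect_equal(idxg$neighbors, oracle)
  expect_error(searchlightIndex(meshFromCoords(g), numeric(0)), "time axis")
})

test_that("multivariate normalization whitens against the noise covariance", {
  set.seed(1)
  P <- matrix(rnorm(40), 8, 5)
  # exactly-identity noise covariance: output proportional to input
  R <- matrix(rnorm(5 * 500), 500, 5)
  R <- sweep(R, 2, colMeans(R))
  R <- R %*% solve(chol(cov(R)))  # sample covariance now the identity
  W <- multivariateNormalize(P, R)
  ratio <- W / P
  expect_lt(sd(ratio) / abs(mean(ratio)), 1e-6)

  # diagonal covariance diag(4, 1): first channel down-weighted by ~1/2
  R2 <- cbind(rnorm(5000, sd = 2), rnorm(5000, sd = 1))
  P2 <- matrix(rnorm(20), 10, 2)
  W2 <- multivariateNormalize(P2, R2)
  expect_equal(mean((W2 / P2)[, 1]) / mean((W2 / P2)[, 2]), 0.5,
               tolerance = 0.1)

  # correlated noise: whitened residuals have near-identity covariance
  set.seed(2)
  A <- matrix(rnorm(16), 4, 4)
  Sigma <- crossprod(A) + diag(4)
  L <- chol(Sigma)
  R3 <- matrix(rnorm(1000 * 4), 1000, 4) %*% L
  W3 <- multivariateNormalize(R3, R3)
  C <- cov(W3)
  C <- C / mean(diag(C))
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
  expect_error(multivariateNormalize(P2, R2[1, , drop = FALSE]), "residual")
})

test_that("data RDMs are Pearson correlation distances over searchlight patterns", {
  # construct epochs where sentence patterns are controlled
  nS <- 4; nV <- 3; nT <- 10
  base <- matrix(rnorm(nV * nT), nV, nT)
  dat <- array(0, c(1, nS, nV, nT))
  dat[1, 1, , ] <- base
  dat[1, 2, , ] <- base          # identical to sentence 1
  dat[1, 3, , ] <- -base         # anti-correlated
  dat[1, 4, , ] <- matrix(rnorm(nV * nT), nV, nT)
  ep <- new("SourceEpochs", data = dat, samplingRate = 200,
            epochLabel = "V1", sentenceIds = paste0("s", 1:4),
            times = (0:(nT - 1)) * 5)
  r <- dataRdm(ep, vertices = 1:3, samples = 1:10, normalize = FALSE)
  m <- rdmMatrix(r)
  expect_equal(m[1, 2], 0)
  expect_equal(m[1, 3], 2)
  expect_equal(diag(m), rep(0, 4))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 2))

  const <- dat
  const[1, 2, , ] <- 1
  epc <- new("SourceEpochs", data = const, samplingRate = 200,
             epochLabel = "V1", sentenceIds = paste0("s", 1:4),
             times = (0:(nT - 1)) * 5)
  expect_error(dataRdm(epc, 1:3, 1:10, normalize = FALSE), "constant.*s2")
})

test_that("model fit is a rank correlation over the lower triangle", {
  set.seed(3)
  m <- modelRdm(runif(6), "absolute_difference", conditions = paste0("c", 1:6))
  expect_equal(fitModel(m, m), 1)

  # rank-reversed counterpart
  mat <- max(rdmMatrix(m)) - rdmMatrix(m)
  diag(mat) <- 0
  rev <- new("RDM", matrix = mat, label = "rev",
             metric = "absolute_difference", conditions = conditionIds(m))
  expect_equal(fitModel(m, rev), -1)

  # 4-condition worked case against the midrank oracle
  a <- modelRdm(c(0.3, 1.1, 0.2, 2.5), "absolute_difference",
                conditions = paste0("c", 1:4))
  b <- modelRdm(c(1.0, 0.1, 0.8, 0.4), "absolute_difference",
                conditions = paste0("c", 1:4))
  lt <- lower.tri(rdmMatrix(a))
  expect_equal(fitModel(a, b),
               oracleSpearman(rdmMatrix(a)[lt], rdmMatrix(b)[lt]))

  # invariance under monotone transforms of either RDM
  mono <- new("RDM", matrix = log1p(rdmMatrix(b)) * 3, label = "mono",
              metric = "absolute_difference", conditions = conditionIds(b))
  expect_equal(fitModel(a, mono), fitModel(a, b))
  bad <- new("RDM", matrix = rdmMatrix(b), label = "x",
             metric = "absolute_difference",
             conditions = rev(conditionIds(b)))
  expect_error(fitModel(a, bad), "condition order")
})

test_that("searchlight RSA recovers planted geometry and is null on noise", {
  set.seed(4)
  st <- generateStimuli(10, seed = 21)
  ids <- targetIds(st)
  mesh <- generateMesh(20, seed = 22)
  vals <- runif(length(ids))
  rdm <- modelRdm(vals, "absolute_difference", "planted", conditions = ids)
  D <- as.matrix(dist(as.matrix(mesh[, c("x", "y", "z")])))
  effV <- sort(order(D[which.min(rowSums(D)), ])[1:4])
  spec <- new("SearchlightSpec", temporalStride = 30L)
  ep <- generateEpochs(ids, mesh, nParticipants = 6, effects = list(
    list(vertices = effV, window = c(200, 400), rdm = rdm, size = 2)),
    seed = 23)
  fm <- runSsrsa(ep, rdm, mesh, spec)
  expect_s4_class(fm, "FitMap")
  idx <- searchlightIndex(mesh, ep@times, spec)
  inW <- which(idx$centers >= 200 & idx$centers <= 400)
  mrho <- apply(fitArray(fm), c(2, 3), mean)
  expect_gt(mean(mrho[effV, inW]), mean(mrho[-effV, -inW]) + 0.2)

  # pure noise: mean rho indistinguishable from zero
  ep0 <- generateEpochs(ids, mesh, nParticipants = 12, seed = 24)
  fm0 <- runSsrsa(ep0, rdm, mesh,
                  new("SearchlightSpec", temporalStride = 60L))
  r0 <- fitArray(fm0)
  grand <- apply(r0, 1, mean)
  expect_lt(abs(mean(grand)), 3 * sd(grand) / sqrt(length(grand)))

  # degenerate searchlight: one vertex, one window reduces to fitModel
  one <- dataRdm(ep, idx$neighbors[[5]], idx$windows[[2]], participant = 3)
  fmOne <- fitArray(fm)[3, 5, 2]
  expect_equal(fmOne, fitModel(rdm, one))
})
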