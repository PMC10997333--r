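test_that("interpretative mismatch is the cosine distance and is scale-invariant", {
  expect_equal(interpretativeMismatch(c(2, 1, 2), c(2, 1, 2)), 0)
  expect_equal(interpretativeMismatch(c(1, 0), c(0, 1)), 1)
  expect_equal(interpretativeMismatch(c(2, 1, 2), c(2, 1, 0)),
               1 - 5 / (3 * sqrt(5)))
  set.seed(1)
  v <- runif(3, 0.1, 3); L <- c(2, 1, 0)
  for (c0 in c(0.1, 1, 17)) {
    expect_equal(interpretativeMismatch(c0 * v, L),
                 interpretativeMismatch(v, L))
  }
  expect_error(interpretativeMismatch(c(0, 0), c(1, 1)), "zero-norm")
  expect_error(interpretativeMismatch(c(1, 2), c(1, 2, 3)), "prefix")
})

test_that("landmark trajectories: distances, deltas and telescoping", {
  pas <- c(2, 1, 2); act <- c(2, 1, 0)
  const <- landmarkTrajectory(matrix(rep(c(1, 1, 1), 4), 4, byrow = TRUE),
                              pas, act)
  expect_true(all(const$delta_passive[-1] == 0))
  expect_true(all(const$delta_active[-1] == 0))

  # linear motion from the active to the passive landmark
  steps <- t(sapply(seq(0, 1, length.out = 6), function(a)
    (1 - a) * act + a * pas))
  traj <- landmarkTrajectory(steps, pas, act)
  expect_true(all(diff(traj$distance_to_passive) < 0))
  expect_true(all(diff(traj$distance_to_active) > 0))
  expect_equal(traj$distance_to_passive[1], sqrt(sum((pas - act)^2)))

  # oracle recomputation + telescoping sum of deltas
  set.seed(2)
  V <- matrix(runif(15, 0, 3), 5, 3)
  tr <- landmarkTrajectory(V, pas, act)
  expect_equal(tr$distance_to_passive,
               apply(V, 1, function(v) sqrt(sum((v - pas)^2))))
  expect_equal(sum(tr$delta_passive[-1]),
               tr$distance_to_passive[5] - tr$distance_to_passive[1])
  trc <- landmarkTrajectory(V, pas, act, metric = "cosine")
  expect_equal(trc$distance_to_active,
               apply(V, 1, function(v)
                 1 - sum(v * act) / sqrt(sum(v^2) * sum(act^2))))
})

test_that("Verb1 depth change is the signed update at the main verb", {
  expect_equal(v1DepthChange(1.8, 1.8), 0)
  expect_equal(v1DepthChange(1.9, 0.4), 1.5)
  expect_equal(v1DepthChange(0.3, 1.2), -0.9)
  expect_error(v1DepthChange(NA, 1), "missing")
})

test_that("PCA scores match an eigendecomposition oracle with a fixed sign convention", {
  # rank-1 matrix: PC1 carries all variance
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  expect_warning(pc1 <- pcaScores(outer(u, v), 2L), "rank")
  expect_equal(pc1$explained[1], 1)

  set.seed(3)
  iso <- cbind(rnorm(4000), rnorm(4000))
  pci <- pcaScores(iso, 2L)
  expect_lt(abs(pci$explained[1] - pci$explained[2]), 0.05)

  X <- matrix(rnorm(60), 12, 5)
  pc <- pcaScores(X, 2L)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  for (j in 1:2) {
    o <- Xc %*% ev$vectors[, j]
    expect_equal(abs(pc$scores[, j]), abs(as.numeric(o)), tolerance = 1e-8)
    # sign convention: largest-magnitude loading positive
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("model RDMs: absolute difference, cosine distance, structural invariants", {
  r <- modelRdm(c(1, 2, 4), "absolute_difference")
  expect_equal(rdmMatrix(r),
               rbind(c(0, 1, 3), c(1, 0, 2), c(3, 2, 0)))

  same <- modelRdm(matrix(1, 5, 3), "cosine_distance")
  expect_equal(max(abs(rdmMatrix(same))), 0)

  set.seed(4)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    V <- matrix(runif(n * 4, 0.1, 2), n, 4)
    rc <- modelRdm(V, "cosine_distance")
    m <- rdmMatrix(rc)
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(0, n))
    expect_true(all(m >= 0 & m <= 2))
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    expect_equal(m[i, j],
                 1 - sum(V[i, ] * V[j, ]) /
                   sqrt(sum(V[i, ]^2) * sum(V[j, ]^2)))
  }
  expect_error(modelRdm(1, "absolute_difference"), "at least 2")
  expect_error(modelRdm(c(1, 2), "cosine_distance"), "vector-valued")
})

test_that("RDM text round-trip preserves matrix and condition order", {
  set.seed(5)
  r <- modelRdm(runif(6), "absolute_difference", label = "demo",
                conditions = paste0("c", 1:6))
  tmp <- tempfile(fileext = ".tsv")
  writeRdm(r, tmp)
  back <- readRdm(tmp)
  expect_equal(rdmMatrix(back), rdmMatrix(r), tolerance = 1e-12)
  expect_equal(conditionIds(back), conditionIds(r))
  expect_equal(back@metric, "absolute_difference")
})
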