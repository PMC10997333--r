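# One multiplicative-update NMF run (Frobenius objective) from a random
# initialization. The update rules keep the objective non-increasing up to
# the epsilon guard; the RMS trace is returned for assertion.
nmfOnce <- function(V, k, maxIter = 200L, tol = 1e-6) {
  eps <- 1e-12
  n <- nrow(V); m <- ncol(V)
  sc <- sqrt(mean(V) / k + eps)
  W <- matrix(runif(n * k), n, k) * sc
  H <- matrix(runif(k * m), k, m) * sc
  rmsTrace <- numeric(0)
  last <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
    W <- W * ((V %*% t(H)) / (W %*% tcrossprod(H) + eps))
    rms <- sqrt(mean((V - W %*% H)^2))
    rmsTrace <- c(rmsTrace, rms)
    if (last - rms < tol * max(last, eps)) break
    last <- rms
  }
  list(W = W, H = H, rms = rmsTrace[length(rmsTrace)], trace = rmsTrace)
}

#' Non-negative matrix factorization of model-fit maps
#'
#' Decomposes whole-brain model-fit maps into non-negative spatial bases
#' and factor time series. Each participant's vertex x time fit map is
#' z-scored per vertex over time, negative fits are zeroed, and the maps
#' are concatenated across participants along time. Multiplicative-update
#' NMF is repeated `nRestarts` times per candidate factor count; for each k
#' the restart with the least RMS reconstruction residual is kept, and the
#' k with the least RMS over `kRange` is chosen.
#'
#' @param fitmap a [FitMap-class], or a 3-d array participant x vertex x
#'   time of model fits.
#' @param kRange candidate factor counts (default `2:50`, truncated to the
#'   matrix rank bound).
#' @param nRestarts random restarts per k (default 20).
#' @param seed RNG seed.
#' @param maxIter,tol multiplicative-update controls.
#' @param normalize z-score each participant's map per vertex over time
#'   before zeroing negatives (default TRUE).
#' @return a [FactorSet-class]; `H` is reshaped to k x time x participant.
#' @export
nmfDecompose <- function(fitmap, kRange = 2:50, nRestarts = 20L, seed = 1L,
                         maxIter = 200L, tol = 1e-6, normalize = TRUE) {
  rho <- if (is(fitmap, "FitMap")) fitmap@rho else fitmap
  stopifnot(length(dim(rho)) == 3L)
  nP <- dim(rho)[1]; nV <- dim(rho)[2]; nT <- dim(rho)[3]
  maps <- vector("list", nP)
  for (p in seq_len(nP)) {
    m <- matrix(rho[p, , ], nV, nT)
    if (normalize) {
      mu <- rowMeans(m)
      sdv <- apply(m, 1, sd)
      sdv[sdv == 0] <- 1
      m <- (m - mu) / sdv
    }
    m[m < 0] <- 0  # negative model fits zeroed
    maps[[p]] <- m
  }
  V <- do.call(cbind, maps)
  if (all(V == 0)) stop("degenerate input: all fits non-positive after zeroing")
  kRange <- kRange[kRange >= 1 & kRange <= min(dim(V))]
  if (!length(kRange)) stop("empty factor-count range")
  set.seed(seed)
  best <- NULL
  rmsPerK <- setNames(numeric(length(kRange)), kRange)
  tracePerK <- list()
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    runs <- lapply(seq_len(nRestarts), function(r) nmfOnce(V, k, maxIter, tol))
    rmss <- vapply(runs, `[[`, 1, "rms")
    b <- which.min(rmss)
    rmsPerK[i] <- rmss[b]
    tracePerK[[as.character(k)]] <- runs[[b]]$trace
    if (is.null(best) || rmss[b] < best$rms)
      best <- c(runs[[b]], list(k = k))
  }
  H <- array(best$H, c(best$k, nT, nP))
  new("FactorSet", W = best$W, H = H, k = as.integer(best$k),
      rms = rmsPerK,
      meta = list(kRange = kRange, nRestarts = nRestarts, seed = seed,
                  traces = tracePerK, n_participants = nP))
}
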