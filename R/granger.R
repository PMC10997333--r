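# Stack lagged design rows for a pooled VAR across participants.
# Z: vars x time x participant. Rows never cross participant boundaries.
varDesign <- function(Z, order) {
  nv <- dim(Z)[1]; nT <- dim(Z)[2]; nP <- dim(Z)[3]
  if (nT <= order) stop("series shorter than VAR order + 1")
  Ys <- list(); Xs <- list()
  for (p in seq_len(nP)) {
    M <- t(Z[, , p, drop = FALSE][, , 1])        # time x vars
    rows <- (order + 1):nT
    Y <- M[rows, , drop = FALSE]
    X <- do.call(cbind, lapply(seq_len(order), function(l)
      M[rows - l, , drop = FALSE]))
    Ys[[p]] <- Y; Xs[[p]] <- X
  }
  Y <- do.call(rbind, Ys)
  X <- cbind(1, do.call(rbind, Xs))
  # column j of each lag block corresponds to variable j
  lagVar <- rep(seq_len(nv), times = order)
  list(Y = Y, X = X, lagVar = lagVar)
}

varResidVar <- function(X, y) {
  fit <- lm.fit(X, y)
  r <- fit$residuals
  sum(r^2) / (length(r) - ncol(X))
}

# Conditional time-domain Granger statistic source -> target within the
# joint VAR: log ratio of target residual variances with the source's past
# excluded vs included.
condGCstat <- function(design, order, source, target) {
  keepRed <- c(TRUE, design$lagVar != source)
  sFull <- varResidVar(design$X, design$Y[, target])
  sRed <- varResidVar(design$X[, keepRed, drop = FALSE], design$Y[, target])
  log(sRed / sFull)
}

varStable <- function(design, order, nv) {
  B <- qr.coef(qr(design$X), design$Y)        # (1 + nv*order) x nv
  A <- t(B[-1, , drop = FALSE])               # nv x (nv*order)
  comp <- rbind(A, cbind(diag(nv * (order - 1)),
                         matrix(0, nv * (order - 1), nv)))
  if (order == 1L) comp <- A
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1
}

selectOrderAIC <- function(Z, maxOrder) {
  nv <- dim(Z)[1]
  aic <- rep(NA_real_, maxOrder)
  for (p in seq_len(maxOrder)) {
    d <- tryCatch(varDesign(Z, p), error = function(e) NULL)
    if (is.null(d)) break
    if (nrow(d$Y) < 2L * ncol(d$X)) break  # too few rows to fit this order
    E <- d$Y - d$X %*% qr.coef(qr(d$X), d$Y)
    Tn <- nrow(d$Y)
    Sig <- crossprod(E) / Tn
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    aic[p] <- as.numeric(ld) + 2 * p * nv^2 / Tn
  }
  if (all(is.na(aic))) stop("could not fit any VAR order")
  which.min(aic)
}

asFactorArray <- function(x) {
  if (is(x, "FactorSet")) return(x@H)
  if (is.matrix(x)) return(array(x, c(nrow(x), ncol(x), 1)))
  stopifnot(length(dim(x)) == 3L)
  x
}

#' Multivariate Granger causality between two factor sets
#'
#' Fits a joint vector-autoregressive model over the factor time series of
#' both sets (participants pooled as independent realizations) with the
#' model order selected by AIC, then computes the conditional time-domain
#' Granger statistic — the log ratio of the target's residual variance with
#' the source's past excluded versus included — for every directed
#' connection from set A to set B and from B to A.
#'
#' @param factorsA,factorsB [FactorSet-class] objects (or k x time x
#'   participant arrays) with aligned time axes.
#' @param maxOrder largest VAR order tried (default 10).
#' @param order optional fixed order; skips AIC selection.
#' @return data.frame with one row per directed connection: `source_set`,
#'   `source`, `target_set`, `target`, `statistic`, `order`, `stable`.
#'   Connections from an unstable VAR are flagged (`stable = FALSE`) with
#'   `statistic = NA`. Zero-variance factor series raise an error.
#' @export
gcPairwise <- function(factorsA, factorsB, maxOrder = 10L, order = NULL) {
  A <- asFactorArray(factorsA); B <- asFactorArray(factorsB)
  stopifnot(dim(A)[2] == dim(B)[2], dim(A)[3] == dim(B)[3])
  kA <- dim(A)[1]; kB <- dim(B)[1]
  Z <- array(0, c(kA + kB, dim(A)[2], dim(A)[3]))
  Z[seq_len(kA), , ] <- A
  Z[kA + seq_len(kB), , ] <- B
  sds <- apply(Z, 1, sd)
  if (any(sds == 0))
    stop("degenerate factor series (zero variance): ",
         paste(which(sds == 0), collapse = ", "))
  if (is.null(order)) order <- selectOrderAIC(Z, maxOrder)
  design <- varDesign(Z, order)
  nv <- kA + kB
  stable <- varStable(design, order, nv)
  if (!stable)
    warning("unstable VAR (spectral radius >= 1); statistics flagged")
  pairs <- rbind(
    expand.grid(source = seq_len(kA), target = kA + seq_len(kB),
                source_set = "A", target_set = "B",
                stringsAsFactors = FALSE),
    expand.grid(source = kA + seq_len(kB), target = seq_len(kA),
                source_set = "B", target_set = "A",
                stringsAsFactors = FALSE))
  stat <- if (stable) {
    vapply(seq_len(nrow(pairs)), function(i)
      condGCstat(design, order, pairs$source[i], pairs$target[i]), numeric(1))
  } else rep(NA_real_, nrow(pairs))
  data.frame(
    source_set = pairs$source_set,
    source = ifelse(pairs$source_set == "A", pairs$source, pairs$source - kA),
    target_set = pairs$target_set,
    target = ifelse(pairs$target_set == "B", pairs$target - kA, pairs$target),
    statistic = stat, order = order, stable = stable)
}

# Surrogate factor array: each participant's source series is cut into
# contiguous windows of length `order` (trailing samples dropped) and the
# windows are shuffled in time; other series are left intact.
shuffleWindows <- function(Z, varIdx, order) {
  nT <- dim(Z)[2]; nP <- dim(Z)[3]
  nW <- nT %/% order
  if (nW < 2L) stop("fewer than 2 windows: surrogate impossible")
  keep <- seq_len(nW * order)
  Zs <- Z[, keep, , drop = FALSE]
  for (p in seq_len(nP)) {
    w <- sample.int(nW)
    idx <- as.vector(outer(seq_len(order), (w - 1L) * order, `+`))
    Zs[varIdx, , p] <- Zs[varIdx, idx, p]
  }
  Zs
}

gpdTailP <- function(obs, surrogate, tailFrac = 0.1) {
  u <- quantile(surrogate, 1 - tailFrac, names = FALSE)
  exc <- surrogate[surrogate > u] - u
  if (length(exc) < 10L || obs <= u) return(NA_real_)
  nll <- function(par) {
    xi <- par[1]; beta <- exp(par[2])
    z <- 1 + xi * exc / beta
    if (any(z <= 0)) return(1e10)
    sum(log(beta) + (1 / xi + 1) * log(z))
  }
  fit <- tryCatch(
    optim(c(0.1, log(mean(exc))), nll, method = "Nelder-Mead"),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0) return(NA_real_)
  xi <- fit$par[1]; beta <- exp(fit$par[2])
  z <- 1 + xi * (obs - u) / beta
  tail <- if (z <= 0) 0 else z^(-1 / xi)
  (length(exc) / length(surrogate)) * tail
}

#' Surrogate-based significance of Granger-causal connections
#'
#' For each directed connection, surrogate data sets are created by
#' randomly rearranging short time windows (of length equal to the VAR
#' model order) of the source factor series; the Granger statistic is
#' recomputed on each surrogate and the add-one permutation p-value taken.
#' p-values below `gpdThreshold` are refined via a generalized Pareto tail
#' approximation fitted to the upper surrogate exceedances (falling back to
#' the raw permutation p when the tail fit fails). All connections are then
#' FDR-corrected (Benjamini-Hochberg).
#'
#' @param factorsA,factorsB the factor sets passed to [gcPairwise()].
#' @param gcResult the data.frame returned by [gcPairwise()].
#' @param nSurrogates number of surrogate data sets (default 1000).
#' @param seed RNG seed.
#' @param gpdThreshold refine p-values below this value (default 0.005).
#' @param fdrAlpha FDR level (default 0.05).
#' @return `gcResult` with columns `p`, `p_refined`, `fdr_significant`
#'   appended.
#' @export
gcSignificance <- function(factorsA, factorsB, gcResult,
                           nSurrogates = 1000L, seed = 1L,
                           gpdThreshold = 0.005, fdrAlpha = 0.05) {
  A <- asFactorArray(factorsA); B <- asFactorArray(factorsB)
  kA <- dim(A)[1]; kB <- dim(B)[1]
  Z <- array(0, c(kA + kB, dim(A)[2], dim(A)[3]))
  Z[seq_len(kA), , ] <- A
  Z[kA + seq_len(kB), , ] <- B
  order <- gcResult$order[1]
  set.seed(seed)
  p <- rep(NA_real_, nrow(gcResult))
  pRef <- rep(NA_real_, nrow(gcResult))
  for (i in seq_len(nrow(gcResult))) {
    if (!is.finite(gcResult$statistic[i])) next
    src <- if (gcResult$source_set[i] == "A") gcResult$source[i]
           else kA + gcResult$source[i]
    tgt <- if (gcResult$target_set[i] == "B") kA + gcResult$target[i]
           else gcResult$target[i]
    surr <- numeric(nSurrogates)
    for (b in seq_len(nSurrogates)) {
      Zs <- shuffleWindows(Z, src, order)
      ds <- varDesign(Zs, order)
      surr[b] <- condGCstat(ds, order, src, tgt)
    }
    obs <- gcResult$statistic[i]
    p[i] <- (1 + sum(surr >= obs)) / (nSurrogates + 1)
    pRef[i] <- p[i]
    if (p[i] < gpdThreshold) {
      pr <- gpdTailP(obs, surr)
      if (is.finite(pr) && pr > 0) pRef[i] <- pr
    }
  }
  gcResult$p <- p
  gcResult$p_refined <- pRef
  ok <- is.finite(pRef)
  gcResult$fdr_significant <- FALSE
  if (any(ok))
    gcResult$fdr_significant[ok] <- fdrCorrect(pRef[ok], fdrAlpha)$significant
  gcResult
}
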