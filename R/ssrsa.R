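#' Build spatiotemporal searchlight neighborhoods
#'
#' For every vertex, the set of vertices within the spatial radius
#' (Euclidean distance in source coordinates, the center always included),
#' and for every window center the sample indices within the temporal
#' radius, clipped at the epoch boundaries. Window centers are placed at
#' every `temporalStride`-th sample.
#'
#' @param mesh data.frame with columns `vertex_id`, `x`, `y`, `z`
#'   (coordinates in mm) and optionally `region`.
#' @param times numeric vector of sample times in ms.
#' @param spec a [SearchlightSpec-class].
#' @return list with `neighbors` (per vertex: integer vertex indices),
#'   `windows` (per center: sample indices), `centers` (center times in
#'   ms), `centerIdx` (center sample indices).
#' @export
searchlightIndex <- function(mesh, times, spec = new("SearchlightSpec")) {
  stopifnot(is(spec, "SearchlightSpec"), nrow(mesh) >= 1L)
  if (!length(times)) stop("empty time axis")
  xyz <- as.matrix(mesh[, c("x", "y", "z")])
  d2 <- as.matrix(dist(xyz))
  neighbors <- lapply(seq_len(nrow(xyz)),
                      function(v) unname(which(d2[v, ] <= spec@spatialRadius)))
  centerIdx <- seq(1L, length(times), by = spec@temporalStride)
  windows <- lapply(centerIdx, function(ci)
    which(abs(times - times[ci]) <= spec@temporalRadius + 1e-9))
  list(neighbors = neighbors, windows = windows,
       centers = times[centerIdx], centerIdx = centerIdx)
}

# Ledoit-Wolf style shrinkage of a sample covariance toward a scaled
# identity target; returns the regularized covariance.
shrinkCovariance <- function(R) {
  m <- nrow(R); p <- ncol(R)
  if (m < 2L) stop("need at least 2 residual samples to estimate covariance")
  Rc <- sweep(R, 2, colMeans(R))
  S <- crossprod(Rc) / (m - 1)
  mu <- mean(diag(S))
  Tgt <- diag(mu, p)
  num <- 0
  for (i in seq_len(m)) {
    xi <- Rc[i, ]
    num <- num + sum((tcrossprod(xi) - S)^2)
  }
  num <- num / m^2
  den <- sum((S - Tgt)^2)
  lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  (1 - lambda) * S + lambda * Tgt
}

matInvSqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-10)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Multivariate noise normalization of activity patterns
#'
#' Whitens patterns by the inverse square root of a shrinkage-regularized
#' noise covariance estimated from residuals, improving the reliability of
#' the correlation distances computed from them. With an identity noise
#' covariance the patterns are unchanged up to a global scale.
#'
#' @param patterns numeric `observations x channels` matrix.
#' @param residuals numeric `samples x channels` matrix from which the
#'   noise covariance is estimated (>= 2 rows).
#' @return whitened patterns, same shape.
#' @export
multivariateNormalize <- function(patterns, residuals) {
  if (!is.matrix(patterns)) patterns <- rbind(patterns)
  stopifnot(is.matrix(residuals), ncol(residuals) == ncol(patterns))
  if (nrow(residuals) < 2L)
    stop("need at least 2 residual samples")
  patterns %*% matInvSqrt(shrinkCovariance(residuals))
}

# Extract the flattened (vertices x window samples) per-sentence pattern
# matrix of one searchlight from one participant's epochs, with optional
# vertex-wise multivariate normalization.
searchlightPatterns <- function(cube, verts, samples, normalize = TRUE) {
  # cube: sentence x vertex x time
  sub <- cube[, verts, samples, drop = FALSE]
  nS <- dim(sub)[1]; nV <- dim(sub)[2]; nT <- dim(sub)[3]
  if (normalize && nV > 1L) {
    res <- sub - rep(colMeans(sub, dims = 1), each = nS)  # trial mean removed
    R <- matrix(aperm(res, c(1, 3, 2)), nrow = nS * nT, ncol = nV)
    Wm <- matInvSqrt(shrinkCovariance(R))
    flat <- matrix(aperm(sub, c(1, 3, 2)), nrow = nS * nT, ncol = nV) %*% Wm
    sub <- aperm(array(flat, c(nS, nT, nV)), c(1, 3, 2))
  }
  matrix(sub, nrow = nS)
}

#' Data RDM of one spatiotemporal searchlight
#'
#' Vectorizes the source data inside one searchlight (vertices in the
#' sphere x samples in the window) for every sentence and computes the
#' pairwise Pearson correlation distance (1 - Pearson's r), after
#' multivariate noise normalization across the vertices of the searchlight.
#'
#' @param epochs a [SourceEpochs-class].
#' @param vertices integer vertex indices of the searchlight sphere.
#' @param samples integer sample indices of the time window.
#' @param participant which participant's data to use (default 1).
#' @param normalize apply multivariate normalization (default TRUE).
#' @return an [RDM-class] with metric `"pearson_correlation_distance"`.
#' @export
dataRdm <- function(epochs, vertices, samples, participant = 1L,
                    normalize = TRUE) {
  stopifnot(is(epochs, "SourceEpochs"), length(vertices) >= 1L,
            length(samples) >= 1L)
  cube <- epochs@data[participant, , , , drop = TRUE]
  if (length(dim(cube)) != 3L)
    cube <- array(cube, dim(epochs@data)[2:4])
  if (dim(cube)[1] < 2L) stop("need at least 2 sentences")
  P <- searchlightPatterns(cube, vertices, samples, normalize)
  sds <- apply(P, 1, sd)
  if (any(sds == 0))
    stop("constant searchlight pattern for sentence(s): ",
         paste(epochs@sentenceIds[sds == 0], collapse = ", "))
  m <- 1 - cor(t(P))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new("RDM", matrix = unname(m), label = "data",
      metric = "pearson_correlation_distance",
      conditions = epochs@sentenceIds)
}

#' Spearman fit between a model RDM and a data RDM
#'
#' Spearman's rank correlation over the lower-triangle entries (diagonal
#' excluded) of the two RDMs. Condition order is checked before comparing.
#'
#' @param model,data [RDM-class] objects of the same size and condition
#'   order.
#' @return rho in `[-1, 1]`.
#' @export
fitModel <- function(model, data) {
  stopifnot(is(model, "RDM"), is(data, "RDM"))
  if (nrow(model@matrix) != nrow(data@matrix))
    stop("RDM sizes differ")
  if (!identical(model@conditions, data@conditions))
    stop("condition order mismatch between model and data RDM")
  lt <- lower.tri(model@matrix)
  cor(data.table::frank(model@matrix[lt], ties.method = "average"),
      data.table::frank(data@matrix[lt], ties.method = "average"))
}

#' Run spatiotemporal searchlight RSA
#'
#' Maps a searchlight across every vertex and window center of every
#' participant's epochs: at each location, the local data RDM is computed
#' ([dataRdm()]) and compared with the model RDM by Spearman's rank
#' correlation, giving a time series of model fit per vertex and
#' participant.
#'
#' @param epochs a [SourceEpochs-class].
#' @param model an [RDM-class] with the same conditions as the epochs.
#' @param mesh the vertex table the epochs were sampled on.
#' @param spec a [SearchlightSpec-class].
#' @param normalize apply multivariate normalization per searchlight.
#' @return a [FitMap-class].
#' @export
runSsrsa <- function(epochs, model, mesh, spec = new("SearchlightSpec"),
                     normalize = TRUE) {
  stopifnot(is(epochs, "SourceEpochs"), is(model, "RDM"))
  if (!identical(model@conditions, epochs@sentenceIds))
    stop("condition order mismatch between model RDM and epochs")
  idx <- searchlightIndex(mesh, epochs@times, spec)
  dims <- dim(epochs@data)
  nP <- dims[1]; nV <- dims[3]; nC <- length(idx$windows)
  if (nV != nrow(mesh)) stop("mesh size does not match epoch vertex dimension")
  lt <- lower.tri(model@matrix)
  rkM <- data.table::frank(model@matrix[lt], ties.method = "average")
  rho <- array(NA_real_, c(nP, nV, nC))
  for (p in seq_len(nP)) {
    cube <- array(epochs@data[p, , , , drop = TRUE], dims[2:4])
    for (ci in seq_len(nC)) {
      samples <- idx$windows[[ci]]
      for (v in seq_len(nV)) {
        P <- searchlightPatterns(cube, idx$neighbors[[v]], samples, normalize)
        D <- 1 - cor(t(P))
        rkD <- data.table::frank(D[lt], ties.method = "average")
        rho[p, v, ci] <- cor(rkM, rkD)
      }
    }
  }
  new("FitMap", rho = rho, model = model@label, centers = idx$centers)
}
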