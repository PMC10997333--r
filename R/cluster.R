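# Connected components over suprathreshold (vertex, window) cells.
# Cells are adjacent when they share a window and their vertices are
# spatial neighbors, or share a vertex in consecutive windows. Returns a
# list of integer vectors indexing `cells` rows.
clusterCells <- function(cells, adjacency, nV, nC) {
  if (!nrow(cells)) return(list())
  cellId <- matrix(0L, nV, nC)
  cellId[cells] <- seq_len(nrow(cells))
  visited <- logical(nrow(cells))
  comps <- list()
  for (s in seq_len(nrow(cells))) {
    if (visited[s]) next
    queue <- s
    visited[s] <- TRUE
    member <- integer(0)
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      member <- c(member, i)
      v <- cells[i, 1]; ci <- cells[i, 2]
      nb <- cellId[adjacency[[v]], ci]
      if (ci > 1L) nb <- c(nb, cellId[v, ci - 1L])
      if (ci < nC) nb <- c(nb, cellId[v, ci + 1L])
      nb <- nb[nb > 0L]
      nb <- nb[!visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    comps[[length(comps) + 1L]] <- member
  }
  comps
}

maxClusterMass <- function(tvec, thr, adjacency, nV, nC) {
  sup <- which(tvec > thr)
  if (!length(sup)) return(0)
  cells <- cbind((sup - 1L) %% nV + 1L, (sup - 1L) %/% nV + 1L)
  comps <- clusterCells(cells, adjacency, nV, nC)
  max(vapply(comps, function(m) sum(tvec[sup[m]]), numeric(1)))
}

#' Group-level cluster-based sign-flip permutation test
#'
#' At each vertex and window center, a one-tailed one-sample t-test over
#' participants asks whether the mean model fit exceeds zero. Cells above
#' the vertex-wise threshold (t quantile at `vertexP`, df = participants -
#' 1) are grouped into spatiotemporally connected clusters scored by their
#' t-mass (summed t). The null distribution of the maximal cluster mass is
#' built by randomly flipping the sign of each participant's whole fit map;
#' a cluster is significant when its mass exceeds the `1 - clusterP` null
#' quantile.
#'
#' @param fitmap a [FitMap-class].
#' @param adjacency per-vertex spatial neighbor lists (e.g.
#'   `searchlightIndex(...)$neighbors`); vertices in the same window are
#'   cluster-adjacent when listed as neighbors, and the same vertex is
#'   adjacent across consecutive windows.
#' @param nPerm number of sign-flip permutations (default 5000). If it
#'   exceeds the `2^participants` distinct flips, all flips are enumerated
#'   with a warning.
#' @param vertexP vertex-wise threshold p (default 0.01).
#' @param clusterP cluster-wise significance level (default 0.05).
#' @param seed RNG seed.
#' @return a [ClusterResult-class].
#' @export
groupClusterTest <- function(fitmap, adjacency, nPerm = 5000L,
                             vertexP = 0.01, clusterP = 0.05, seed = 1L) {
  stopifnot(is(fitmap, "FitMap"))
  rho <- fitmap@rho
  nP <- dim(rho)[1]; nV <- dim(rho)[2]; nC <- dim(rho)[3]
  if (nP < 2L) stop("need at least 2 participants")
  if (length(adjacency) != nV)
    stop("adjacency must have one entry per vertex")
  X <- matrix(rho, nrow = nP)  # participants x (vertex, window) cells
  thr <- qt(1 - vertexP, df = nP - 1)

  ssq <- colSums(X^2)
  tFromMean <- function(m) {
    s2 <- (ssq - nP * m^2) / (nP - 1)
    s2[s2 < 1e-24] <- 1e-24
    m / sqrt(s2 / nP)
  }
  tobs <- tFromMean(colMeans(X))

  # observed clusters
  sup <- which(tobs > thr)
  clusters <- list()
  if (length(sup)) {
    cells <- cbind((sup - 1L) %% nV + 1L, (sup - 1L) %/% nV + 1L)
    comps <- clusterCells(cells, adjacency, nV, nC)
    clusters <- lapply(comps, function(m)
      list(cells = cells[m, , drop = FALSE], mass = sum(tobs[sup[m]])))
  }

  # sign-flip null of maximal cluster mass
  if (nPerm >= 2^nP) {
    warning(sprintf("nPerm %d >= 2^%d; enumerating all sign flips", nPerm, nP))
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), nP)))
    nPerm <- nrow(S)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), nPerm * nP, replace = TRUE), nPerm, nP)
  }
  M <- (S %*% X) / nP
  nullMass <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    tb <- tFromMean(M[b, ])
    nullMass[b] <- maxClusterMass(tb, thr, adjacency, nV, nC)
  }

  mask <- matrix(FALSE, nV, nC)
  for (i in seq_along(clusters)) {
    mass <- clusters[[i]]$mass
    p <- (1 + sum(nullMass >= mass)) / (nPerm + 1)
    clusters[[i]]$p <- p
    if (p < clusterP) mask[clusters[[i]]$cells] <- TRUE
  }
  new("ClusterResult", tmap = matrix(tobs, nV, nC), threshold = thr,
      clusters = clusters, mask = mask, nullMass = nullMass)
}

#' Summary statistics of a cluster result
#'
#' Vertex t-mass (each vertex's summed t over its significant samples),
#' per-cluster t-mass time series (summed t of a cluster's significant
#' vertices at each window), and, when region labels are supplied, the ROI
#' peak-t series (highest t in the region at each window).
#'
#' @param result a [ClusterResult-class].
#' @param regions optional character vector of region labels per vertex;
#'   without it the ROI outputs are skipped.
#' @return list with `vertex_tmass` (per vertex), `cluster_tmass`
#'   (clusters x windows matrix, significant clusters only) and `roi_peak`
#'   (regions x windows matrix or NULL).
#' @export
summaryMaps <- function(result, regions = NULL) {
  stopifnot(is(result, "ClusterResult"))
  tmap <- result@tmap
  mask <- result@mask
  vertex_tmass <- rowSums(tmap * mask)
  sig <- Filter(function(cl) cl$p < 0.05, result@clusters)
  cluster_tmass <- if (length(sig)) {
    t(vapply(sig, function(cl) {
      series <- numeric(ncol(tmap))
      for (r in seq_len(nrow(cl$cells))) {
        v <- cl$cells[r, 1]; ci <- cl$cells[r, 2]
        series[ci] <- series[ci] + tmap[v, ci]
      }
      series
    }, numeric(ncol(tmap))))
  } else matrix(numeric(0), 0, ncol(tmap))
  roi_peak <- NULL
  if (!is.null(regions)) {
    stopifnot(length(regions) == nrow(tmap))
    rr <- sort(unique(regions))
    roi_peak <- t(vapply(rr, function(g)
      apply(tmap[regions == g, , drop = FALSE], 2, max),
      numeric(ncol(tmap))))
    rownames(roi_peak) <- rr
  }
  list(vertex_tmass = vertex_tmass, cluster_tmass = cluster_tmass,
       roi_peak = roi_peak)
}
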