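cosineDistance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine distance undefined for a zero-norm vector")
  1 - sum(a * b) / (na * nb)
}

#' Interpretative mismatch between estimated and context-free depths
#'
#' Cosine distance between an incremental probe-estimated parse-depth
#' vector and the corresponding incremental context-free parse-depth vector
#' of one interpretation. Smaller mismatch means a stronger preference for
#' that interpretation.
#'
#' @param probeVector [ParseDepthVector-class] (or numeric) — the estimated
#'   incremental depths.
#' @param contextFreeVector [ParseDepthVector-class] (or numeric) — the
#'   context-free landmark depths for the same prefix length.
#' @return cosine distance in `[0, 2]`.
#' @export
interpretativeMismatch <- function(probeVector, contextFreeVector) {
  a <- if (is(probeVector, "ParseDepthVector")) probeVector@depths
       else as.numeric(probeVector)
  b <- if (is(contextFreeVector, "ParseDepthVector")) contextFreeVector@depths
       else as.numeric(contextFreeVector)
  if (length(a) != length(b))
    stop("prefix lengths differ between the two depth vectors")
  cosineDistance(a, b)
}

#' Landmark distances and movement along an unfolding sentence
#'
#' Tracks one sentence's 3-d parse-depth vector (determiner, subject noun,
#' Verb1 depths) across prefix positions and measures, at each step, its
#' distance from the passive and active context-free landmarks plus the
#' step-to-step change of those distances (a negative delta is movement
#' toward that landmark).
#'
#' @param vectors numeric `steps x 3` matrix (or list of length-3 vectors):
#'   the depth vector at each prefix position.
#' @param passive,active length-3 context-free landmark vectors (or
#'   [ParseDepthVector-class]).
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @param sentenceId identifier carried through.
#' @return data.frame with one row per step: `step`,
#'   `distance_to_passive`, `distance_to_active`, `delta_passive`,
#'   `delta_active` (deltas `NA` at the first step).
#' @export
landmarkTrajectory <- function(vectors, passive, active,
                               metric = c("euclidean", "cosine"),
                               sentenceId = "sentence") {
  metric <- match.arg(metric)
  if (is.list(vectors)) vectors <- do.call(rbind, vectors)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = 1)
  pv <- if (is(passive, "ParseDepthVector")) passive@depths else as.numeric(passive)
  av <- if (is(active, "ParseDepthVector")) active@depths else as.numeric(active)
  stopifnot(ncol(vectors) == length(pv), length(pv) == length(av),
            nrow(vectors) >= 1L)
  dfun <- switch(metric,
    euclidean = function(a, b) sqrt(sum((a - b)^2)),
    cosine = cosineDistance)
  dp <- apply(vectors, 1, dfun, pv)
  da <- apply(vectors, 1, dfun, av)
  data.frame(sentence_id = sentenceId, step = seq_len(nrow(vectors)),
             distance_to_passive = dp, distance_to_active = da,
             delta_passive = c(NA, diff(dp)), delta_active = c(NA, diff(da)))
}

#' Change of Verb1 parse depth at the main verb
#'
#' Signed difference between the updated Verb1 depth when the actual main
#' verb is presented and its initial value when Verb1 is first encountered.
#' A positive change (toward the context-free passive value 2) marks a
#' shift to the passive reading; a negative change (toward 0) marks the
#' active reading.
#'
#' @param atMV Verb1 depth in the prefix ending at the main verb.
#' @param atV1 Verb1 depth in the prefix ending at Verb1.
#' @return `atMV - atV1`.
#' @export
v1DepthChange <- function(atMV, atV1) {
  if (any(is.na(atMV)) || any(is.na(atV1)))
    stop("missing prefix record for Verb1 depth")
  atMV - atV1
}

#' Principal-component scores of parse-depth vectors
#'
#' Centered PCA of a sentences x positions depth matrix; the component sign
#' is fixed by making the largest-magnitude loading positive. Used to
#' summarize whole incremental depth vectors at a fixed prefix position
#' across the stimulus sentences.
#'
#' @param depthMatrix numeric `sentences x positions` matrix.
#' @param nComponents number of components (default 2).
#' @return list with `scores` (sentences x components), `loadings`,
#'   `explained` (proportion of variance). If the matrix rank supports
#'   fewer than `nComponents` components, the available ones are returned
#'   with a warning.
#' @export
pcaScores <- function(depthMatrix, nComponents = 2L) {
  stopifnot(is.matrix(depthMatrix), nrow(depthMatrix) >= 2L)
  pc <- prcomp(depthMatrix, center = TRUE, scale. = FALSE)
  pos <- pc$sdev > max(pc$sdev) * 1e-8
  avail <- sum(pos)
  if (avail < nComponents) {
    warning(sprintf("rank supports only %d components (requested %d)",
                    avail, nComponents))
    nComponents <- avail
  }
  idx <- seq_len(nComponents)
  L <- pc$rotation[, idx, drop = FALSE]
  S <- pc$x[, idx, drop = FALSE]
  for (j in idx) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) { L[, j] <- -L[, j]; S[, j] <- -S[, j] }
  }
  list(scores = S, loadings = L,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[idx])
}

#' Build a model RDM from per-condition values
#'
#' For a scalar measure the dissimilarity is the absolute pairwise
#' difference; for vector measures (incremental parse-depth vectors) the
#' pairwise cosine distance. The condition order is the canonical stimulus
#' order and is recorded in the object.
#'
#' @param values numeric vector (scalar measure, one value per condition)
#'   or a `conditions x p` matrix / list of equal-length vectors.
#' @param metric `"absolute_difference"`, `"cosine_distance"` or
#'   `"euclidean"`.
#' @param label measure name.
#' @param conditions condition ids; defaults to names/rownames or 1..n.
#' @return an [RDM-class].
#' @export
modelRdm <- function(values, metric = c("absolute_difference",
                                        "cosine_distance", "euclidean"),
                     label = "model", conditions = NULL) {
  metric <- match.arg(metric)
  if (metric == "absolute_difference") {
    v <- as.numeric(values)
    n <- length(v)
    if (n < 2L) stop("need at least 2 conditions")
    m <- abs(outer(v, v, "-"))
    if (is.null(conditions)) conditions <- names(values)
  } else {
    if (is.list(values)) values <- do.call(rbind, values)
    if (!is.matrix(values))
      stop("metric '", metric, "' needs vector-valued conditions")
    n <- nrow(values)
    if (n < 2L) stop("need at least 2 conditions")
    if (metric == "cosine_distance") {
      nrm <- sqrt(rowSums(values^2))
      if (any(nrm == 0)) stop("zero-norm condition vector")
      u <- values / nrm
      m <- 1 - tcrossprod(u)
    } else {
      m <- as.matrix(dist(values))
    }
    if (is.null(conditions)) conditions <- rownames(values)
  }
  if (is.null(conditions)) conditions <- as.character(seq_len(n))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  new("RDM", matrix = unname(m), label = label, metric = metric,
      conditions = as.character(conditions))
}

#' Read and write RDMs as delimited text with a JSON sidecar
#'
#' The matrix is stored as a square tab-separated file and the metadata
#' (label, metric, condition order) in `<path>.json`, so that condition
#' order can be checked across RDMs.
#'
#' @param rdm an [RDM-class].
#' @param path file path for the matrix.
#' @return `writeRdm()` the path invisibly; `readRdm()` an [RDM-class].
#' @export
writeRdm <- function(rdm, path) {
  stopifnot(is(rdm, "RDM"))
  utils::write.table(rdm@matrix, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(label = rdm@label, metric = rdm@metric,
                            conditions = rdm@conditions),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRdm
#' @export
readRdm <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("RDM", matrix = unname(m), label = meta$label, metric = meta$metric,
      conditions = as.character(meta$conditions))
}
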