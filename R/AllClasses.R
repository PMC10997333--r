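#' @import methods
#' @importFrom stats cmdscale cor dist lm.fit optim prcomp pt qt quantile
#'   rbinom rnorm runif sd setNames
#' @importFrom utils head read.table tail write.table
NULL

#' Dependency parse tree of one sentence
#'
#' A rooted tree over the tokens of a sentence. Each token points to its
#' syntactic head via `head`; the root is marked with head 0. The
#' `interpretation` label records which structural reading the tree encodes
#' (for the target sentences both a passive and an active parse exist over
#' the same token prefix).
#'
#' @slot sentenceId character(1) identifier.
#' @slot tokens character vector of word forms, positions 1-based.
#' @slot head integer vector, same length as `tokens`; `head[i]` is the
#'   position of token i's head, 0 for the root.
#' @slot interpretation one of `"passive"`, `"active"`, `"other"`.
#' @exportClass DependencyTree
setClass("DependencyTree",
  representation(
    sentenceId = "character",
    tokens = "character",
    head = "integer",
    interpretation = "character"
  )
)

setValidity("DependencyTree", function(object) {
  n <- length(object@tokens)
  h <- object@head
  if (length(h) != n)
    return("head vector length differs from token count")
  if (n < 1L) return("tree must contain at least one token")
  if (!object@interpretation %in% c("passive", "active", "other"))
    return("interpretation must be passive, active or other")
  roots <- which(h == 0L)
  if (length(roots) == 0L) return("no root (token with head 0)")
  if (length(roots) > 1L)
    return(sprintf("multiple roots at tokens %s",
                   paste(roots, collapse = ", ")))
  bad <- which(h < 0L | h > n)
  if (length(bad))
    return(sprintf("head index out of range for token %d", bad[1]))
  self <- which(h == seq_len(n))
  if (length(self))
    return(sprintf("token %d is its own head", self[1]))
  # walk each token to the root; revisiting a token on the same walk = cycle
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (h[j] != 0L) {
      if (seen[j])
        return(sprintf("cycle involving token %d", i))
      seen[j] <- TRUE
      j <- h[j]
    }
  }
  TRUE
})

#' Per-word parse depths for an incremental prefix
#'
#' Holds one real-valued depth per word position of a sentence prefix.
#' Context-free depths (derived from a [DependencyTree-class]) are
#' non-negative integers with the root at 0; probe-estimated depths are
#' non-negative reals.
#'
#' @slot sentenceId character(1) identifier.
#' @slot depths numeric vector, one entry per word of the prefix.
#' @slot source `"context_free"` or `"probe"`.
#' @exportClass ParseDepthVector
setClass("ParseDepthVector",
  representation(
    sentenceId = "character",
    depths = "numeric",
    source = "character"
  )
)

setValidity("ParseDepthVector", function(object) {
  if (!object@source %in% c("context_free", "probe"))
    return("source must be context_free or probe")
  if (length(object@depths) < 1L) return("empty depth vector")
  if (any(!is.finite(object@depths))) return("non-finite depth")
  if (object@source == "context_free") {
    d <- object@depths
    if (any(d < 0) || any(d != round(d)))
      return("context-free depths must be non-negative integers")
  }
  TRUE
})

#' Contextual word embeddings for incremental sentence prefixes
#'
#' Stores one embedding matrix (prefix_len x d) per (sentence, prefix-length)
#' pair, i.e. the hidden-state vectors of every word each time one more word
#' of the sentence has been presented.
#'
#' @slot embeddings named list of numeric matrices; names are
#'   `"<sentence_id>#<prefix_len>"`, each matrix has `prefix_len` rows and
#'   `dim` columns.
#' @slot dim embedding dimension d.
#' @slot layerTag identifier of the representation source.
#' @exportClass EmbeddingSet
setClass("EmbeddingSet",
  representation(
    embeddings = "list",
    dim = "integer",
    layerTag = "character"
  )
)

setValidity("EmbeddingSet", function(object) {
  d <- object@dim
  if (length(d) != 1L || d < 1L) return("dim must be a positive scalar")
  if (length(object@embeddings) == 0L) return("empty embedding set")
  nm <- names(object@embeddings)
  if (is.null(nm) || any(!grepl("#", nm, fixed = TRUE)))
    return("embedding names must be '<sentence_id>#<prefix_len>'")
  for (i in seq_along(object@embeddings)) {
    m <- object@embeddings[[i]]
    if (!is.matrix(m) || ncol(m) != d)
      return(sprintf("entry %s is not a matrix with %d columns", nm[i], d))
    plen <- as.integer(sub(".*#", "", nm[i]))
    if (nrow(m) != plen)
      return(sprintf("entry %s has %d rows, expected %d", nm[i], nrow(m), plen))
    if (any(!is.finite(m)))
      return(sprintf("non-finite embedding in %s", nm[i]))
  }
  TRUE
})

#' Linear structural probe
#'
#' The probe is a k x d linear map B; the predicted parse depth of a word
#' with embedding h is the squared L2 norm of B h.
#'
#' @slot transform numeric k x d matrix.
#' @slot meta list with training metadata (per-restart losses, loss curve of
#'   the returned restart, seed, config).
#' @exportClass ProbeModel
setClass("ProbeModel",
  representation(transform = "matrix", meta = "list")
)

setValidity("ProbeModel", function(object) {
  if (nrow(object@transform) < 1L) return("probe rank k must be >= 1")
  if (any(!is.finite(object@transform))) return("non-finite transform")
  TRUE
})

#' Representational dissimilarity matrix
#'
#' Symmetric zero-diagonal matrix of pairwise dissimilarities between
#' conditions (here: the target sentences in canonical stimulus order).
#'
#' @slot matrix n x n numeric dissimilarity matrix.
#' @slot label measure name.
#' @slot metric one of `"absolute_difference"`, `"cosine_distance"`,
#'   `"pearson_correlation_distance"`, `"euclidean"`.
#' @slot conditions character vector of condition ids (row/column order).
#' @exportClass RDM
setClass("RDM",
  representation(
    matrix = "matrix",
    label = "character",
    metric = "character",
    conditions = "character"
  )
)

setValidity("RDM", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("RDM must be square")
  if (nrow(m) < 2L) return("RDM needs at least 2 conditions")
  if (length(object@conditions) != nrow(m))
    return("condition labels must match matrix size")
  if (any(!is.finite(m))) return("non-finite dissimilarity")
  if (max(abs(diag(m))) > 1e-10) return("diagonal must be zero")
  if (max(abs(m - t(m))) > 1e-8) return("matrix must be symmetric")
  TRUE
})

#' Source-space epoch array
#'
#' Complete 4-d array of source-localized activity indexed
#' (participant, sentence, vertex, time sample). Time 0 is the onset of the
#' epoch's aligning word; sentences follow the canonical stimulus order.
#'
#' @slot data 4-d numeric array.
#' @slot samplingRate sampling rate in Hz.
#' @slot epochLabel one of `"V1"`, `"PP1"`, `"MV"`.
#' @slot sentenceIds condition order along dimension 2.
#' @slot times time of each sample in ms relative to word onset.
#' @exportClass SourceEpochs
setClass("SourceEpochs",
  representation(
    data = "array",
    samplingRate = "numeric",
    epochLabel = "character",
    sentenceIds = "character",
    times = "numeric"
  )
)

setValidity("SourceEpochs", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L)
    return("data must be participant x sentence x vertex x time")
  if (any(!is.finite(object@data))) return("ragged or non-finite data")
  if (length(object@sentenceIds) != d[2])
    return("sentenceIds must match sentence dimension")
  if (length(object@times) != d[4])
    return("times must match time dimension")
  if (!object@epochLabel %in% c("V1", "PP1", "MV"))
    return("epochLabel must be V1, PP1 or MV")
  TRUE
})

#' Spatiotemporal searchlight specification
#'
#' @slot spatialRadius sphere radius in mm (default 10).
#' @slot temporalRadius half-window in ms (default 30, i.e. a 60 ms sliding
#'   window).
#' @slot temporalStride spacing of window centers in samples (default 1).
#' @exportClass SearchlightSpec
setClass("SearchlightSpec",
  representation(
    spatialRadius = "numeric",
    temporalRadius = "numeric",
    temporalStride = "integer"
  ),
  prototype(spatialRadius = 10, temporalRadius = 30, temporalStride = 1L)
)

setValidity("SearchlightSpec", function(object) {
  if (object@spatialRadius <= 0 || object@temporalRadius <= 0)
    return("radii must be positive")
  if (object@temporalStride < 1L) return("temporalStride must be >= 1")
  TRUE
})

#' Model-fit map from searchlight RSA
#'
#' Spearman rank-correlation between a model RDM and the local data RDM, per
#' participant, vertex and time-window center.
#'
#' @slot rho 3-d array participant x vertex x window-center.
#' @slot model model RDM label.
#' @slot centers window-center times in ms.
#' @exportClass FitMap
setClass("FitMap",
  representation(rho = "array", model = "character", centers = "numeric")
)

setValidity("FitMap", function(object) {
  if (length(dim(object@rho)) != 3L)
    return("rho must be participant x vertex x center")
  r <- object@rho[is.finite(object@rho)]
  if (length(r) && (min(r) < -1 - 1e-8 || max(r) > 1 + 1e-8))
    return("rho outside [-1, 1]")
  if (length(object@centers) != dim(object@rho)[3])
    return("centers must match third dimension")
  TRUE
})

#' Cluster-based permutation test result
#'
#' @slot tmap vertex x window-center matrix of one-sample t values.
#' @slot threshold vertex-wise t threshold used to form clusters.
#' @slot clusters list; each element has `cells` (2-column matrix of
#'   vertex/center indices), `mass` and `p`.
#' @slot mask logical vertex x center matrix marking significant cells.
#' @slot nullMass permutation null distribution of maximal cluster mass.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(
    tmap = "matrix",
    threshold = "numeric",
    clusters = "list",
    mask = "matrix",
    nullMass = "numeric"
  )
)

setValidity("ClusterResult", function(object) {
  if (!identical(dim(object@tmap), dim(object@mask)))
    return("mask and tmap dimensions differ")
  for (cl in object@clusters) {
    if (!is.null(cl$p) && (cl$p <= 0 || cl$p > 1))
      return("cluster p outside (0, 1]")
  }
  TRUE
})

#' Non-negative factor decomposition of a model-fit map
#'
#' @slot W vertex x k non-negative spatial bases.
#' @slot H k x time x participant non-negative factor time series.
#' @slot k chosen factor count.
#' @slot rms RMS reconstruction residual per candidate k (named vector).
#' @slot meta list (restart RMS traces, seed, k range).
#' @exportClass FactorSet
setClass("FactorSet",
  representation(
    W = "matrix", H = "array", k = "integer", rms = "numeric", meta = "list"
  )
)

setValidity("FactorSet", function(object) {
  if (min(object@W) < 0 || min(object@H) < 0)
    return("bases and time series must be non-negative")
  if (ncol(object@W) != object@k || dim(object@H)[1] != object@k)
    return("k inconsistent with W/H")
  TRUE
})
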