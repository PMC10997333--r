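#' Accessors for incstruct classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an incstruct object.
#' @return `depths()` the numeric depth vector; `rdmMatrix()` the square
#'   dissimilarity matrix; `conditionIds()` the condition order;
#'   `fitArray()` the participant x vertex x center rho array;
#'   `nTokens()` the token count of a tree.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))
#' @rdname accessors
#' @export
setMethod("depths", "ParseDepthVector", function(x) x@depths)

#' @rdname accessors
#' @export
setGeneric("rdmMatrix", function(x) standardGeneric("rdmMatrix"))
#' @rdname accessors
#' @export
setMethod("rdmMatrix", "RDM", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("conditionIds", function(x) standardGeneric("conditionIds"))
#' @rdname accessors
#' @export
setMethod("conditionIds", "RDM", function(x) x@conditions)
#' @rdname accessors
#' @export
setMethod("conditionIds", "SourceEpochs", function(x) x@sentenceIds)

#' @rdname accessors
#' @export
setGeneric("fitArray", function(x) standardGeneric("fitArray"))
#' @rdname accessors
#' @export
setMethod("fitArray", "FitMap", function(x) x@rho)

#' @rdname accessors
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))
#' @rdname accessors
#' @export
setMethod("nTokens", "DependencyTree", function(x) length(x@tokens))

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))
#' @rdname accessors
#' @export
setMethod("tokens", "DependencyTree", function(x) x@tokens)

#' @rdname accessors
#' @export
setGeneric("headIndices", function(x) standardGeneric("headIndices"))
#' @rdname accessors
#' @export
setMethod("headIndices", "DependencyTree", function(x) x@head)

setMethod("show", "DependencyTree", function(object) {
  cat(sprintf("DependencyTree '%s' (%s): %d tokens, root at %d\n",
              object@sentenceId, object@interpretation,
              length(object@tokens), which(object@head == 0L)))
  cat(" ", paste(object@tokens, collapse = " "), "\n")
})

setMethod("show", "ParseDepthVector", function(object) {
  cat(sprintf("ParseDepthVector '%s' (%s), prefix length %d\n",
              object@sentenceId, object@source, length(object@depths)))
  print(round(object@depths, 3))
})

setMethod("show", "RDM", function(object) {
  cat(sprintf("RDM '%s' (%s): %d x %d conditions\n", object@label,
              object@metric, nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "EmbeddingSet", function(object) {
  cat(sprintf("EmbeddingSet [%s]: %d (sentence, prefix) entries, d = %d\n",
              object@layerTag, length(object@embeddings), object@dim))
})

setMethod("show", "ProbeModel", function(object) {
  cat(sprintf("ProbeModel: rank %d probe on %d-dim embeddings\n",
              nrow(object@transform), ncol(object@transform)))
  if (!is.null(object@meta$restart_losses))
    cat(sprintf("  best of %d restarts, training loss %.4g\n",
                length(object@meta$restart_losses),
                min(object@meta$restart_losses)))
})

setMethod("show", "SourceEpochs", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SourceEpochs [%s]: %d participants x %d sentences x %d vertices x %d samples @ %g Hz\n",
    object@epochLabel, d[1], d[2], d[3], d[4], object@samplingRate))
})

setMethod("show", "FitMap", function(object) {
  d <- dim(object@rho)
  cat(sprintf("FitMap '%s': %d participants x %d vertices x %d windows\n",
              object@model, d[1], d[2], d[3]))
})

setMethod("show", "ClusterResult", function(object) {
  nsig <- if (length(object@clusters))
    sum(vapply(object@clusters, function(cl) cl$p, 1) < 0.05) else 0L
  cat(sprintf("ClusterResult: %d clusters (%d significant), t threshold %.3f\n",
              length(object@clusters), nsig, object@threshold))
})

setMethod("show", "FactorSet", function(object) {
  cat(sprintf("FactorSet: k = %d factors over %d vertices, %d samples x %d participants\n",
              object@k, nrow(object@W), dim(object@H)[2], dim(object@H)[3]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
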