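#' Construct an embedding set
#'
#' @param embeddings named list of `prefix_len x d` matrices with names
#'   `"<sentence_id>#<prefix_len>"`.
#' @param layerTag identifier of the representation source.
#' @return an [EmbeddingSet-class].
#' @export
embeddingSet <- function(embeddings, layerTag = "layer") {
  d <- ncol(embeddings[[1]])
  new("EmbeddingSet", embeddings = embeddings, dim = as.integer(d),
      layerTag = as.character(layerTag))
}

embKey <- function(sentenceId, prefixLen) paste0(sentenceId, "#", prefixLen)

#' @rdname embeddingSet
#' @param x an [EmbeddingSet-class].
#' @param sentenceId,prefixLen entry key.
#' @return `embeddingEntry()` the embedding matrix for one
#'   (sentence, prefix) pair.
#' @export
embeddingEntry <- function(x, sentenceId, prefixLen) {
  m <- x@embeddings[[embKey(sentenceId, prefixLen)]]
  if (is.null(m))
    stop(sprintf("no embeddings for sentence '%s' at prefix %d",
                 sentenceId, prefixLen))
  m
}

probeLoss <- function(B, X, y, w) {
  q <- rowSums((X %*% t(B))^2)
  sum(w * abs(q - y))
}

# One fit from a random initialization, in two phases. Phase 1: adaptive
# moment-scaled gradient descent (Adam-style, decaying step) to find the
# basin. Phase 2: plain subgradient descent in which steps that would
# increase the loss are rejected with the step halved, so the accepted loss
# trace is monotone non-increasing and the iterate converges inside the
# basin. Loss: per-sentence length-normalized mean absolute error between
# the squared-norm depth estimate and the gold depth, averaged over
# sentences.
probeFitOnce <- function(X, y, w, k, lr, maxIter, tol) {
  d <- ncol(X)
  B <- matrix(rnorm(k * d, sd = 0.2), k, d)
  gradf <- function(B) {
    q <- rowSums((X %*% t(B))^2)
    2 * B %*% crossprod(X, (w * sign(q - y)) * X)
  }
  m <- v <- B * 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (it in seq_len(maxIter)) {
    G <- gradf(B)
    m <- b1 * m + (1 - b1) * G
    v <- b2 * v + (1 - b2) * G^2
    step <- 0.05 / (1 + it / 1000)
    B <- B - step * (m / (1 - b1^it)) / (sqrt(v / (1 - b2^it)) + eps)
  }
  loss <- probeLoss(B, X, y, w)
  trace <- loss
  for (it in seq_len(maxIter)) {
    Bnew <- B - lr * gradf(B)
    lnew <- probeLoss(Bnew, X, y, w)
    if (lnew <= loss) {
      rel <- (loss - lnew) / max(loss, 1e-12)
      B <- Bnew
      loss <- lnew
      trace <- c(trace, loss)
      lr <- lr * 1.1
      if (rel < tol && it > 10L) break
    } else {
      lr <- lr / 2
      if (lr < 1e-14) break
    }
  }
  list(B = B, loss = loss, trace = trace)
}

#' Train a linear structural probe
#'
#' Fits the linear map B such that the squared L2 norm of `B %*% h` best
#' estimates each word's parse depth, by gradient descent on a
#' sentence-length-normalized L1 loss. Training is repeated `nRestarts`
#' times from different random initializations; the restart with the lowest
#' training loss is returned, and all restart losses (and each restart's
#' transform) are kept in the metadata so that predictions can be averaged
#' across restarts downstream.
#'
#' @param embeddings an [EmbeddingSet-class] with the training entries.
#' @param gold named list of gold depth vectors (numeric or
#'   [ParseDepthVector-class]), names matching the embedding entry keys
#'   `"<sentence_id>#<prefix_len>"`.
#' @param k probe rank (rows of B); default the embedding dimension.
#' @param nRestarts number of random restarts (default 10).
#' @param seed RNG seed.
#' @param maxIter,tol,lr optimizer controls: iteration cap, relative
#'   loss-change tolerance for early stopping, initial step size.
#' @return a [ProbeModel-class]; `meta` holds `restart_losses`,
#'   `restart_transforms`, the accepted-loss `trace` of the best restart and
#'   the config.
#' @export
trainProbe <- function(embeddings, gold, k = NULL, nRestarts = 10L,
                       seed = 1L, maxIter = 2000L, tol = 1e-6, lr = 1e-3) {
  stopifnot(is(embeddings, "EmbeddingSet"))
  keys <- names(embeddings@embeddings)
  keys <- keys[keys %in% names(gold)]
  if (!length(keys)) stop("empty training set: no embedding entry has gold depths")
  Xs <- list(); ys <- list(); ws <- list()
  for (kk in keys) {
    m <- embeddings@embeddings[[kk]]
    g <- gold[[kk]]
    if (is(g, "ParseDepthVector")) g <- g@depths
    if (length(g) != nrow(m))
      stop(sprintf("gold depths for %s have length %d, expected %d",
                   kk, length(g), nrow(m)))
    Xs[[kk]] <- m
    ys[[kk]] <- as.numeric(g)
    ws[[kk]] <- rep(1 / (nrow(m) * length(keys)), nrow(m))
  }
  X <- do.call(rbind, Xs)
  if (any(!is.finite(X))) stop("non-finite embeddings in training set")
  y <- unlist(ys, use.names = FALSE)
  w <- unlist(ws, use.names = FALSE)
  if (is.null(k)) k <- ncol(X)
  k <- as.integer(k)
  stopifnot(k >= 1L)

  fits <- vector("list", nRestarts)
  oldseed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (r in seq_len(nRestarts))
    fits[[r]] <- probeFitOnce(X, y, w, k, lr, maxIter, tol)
  if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv)

  losses <- vapply(fits, `[[`, 1, "loss")
  best <- which.min(losses)
  new("ProbeModel", transform = fits[[best]]$B,
      meta = list(restart_losses = losses,
                  restart_transforms = lapply(fits, `[[`, "B"),
                  best_restart = best,
                  trace = fits[[best]]$trace,
                  config = list(k = k, nRestarts = nRestarts, seed = seed,
                                maxIter = maxIter, tol = tol, lr = lr)))
}

#' Predict parse depths for one sentence prefix
#'
#' The predicted depth of each word is the squared L2 norm of its
#' transformed embedding, hence always non-negative.
#'
#' @param probe a [ProbeModel-class].
#' @param embeddings `prefix_len x d` matrix of word embeddings.
#' @param sentenceId identifier for the returned vector.
#' @return a [ParseDepthVector-class] with `source = "probe"`.
#' @export
predictDepths <- function(probe, embeddings, sentenceId = "sentence") {
  stopifnot(is(probe, "ProbeModel"))
  if (!is.matrix(embeddings)) embeddings <- matrix(embeddings, nrow = 1)
  if (ncol(embeddings) != ncol(probe@transform))
    stop(sprintf("embedding dimension %d does not match probe dimension %d",
                 ncol(embeddings), ncol(probe@transform)))
  d <- rowSums((embeddings %*% t(probe@transform))^2)
  new("ParseDepthVector", sentenceId = as.character(sentenceId)[1],
      depths = d, source = "probe")
}

#' Average depth predictions over probe restarts
#'
#' Element-wise mean of depth vectors predicted by the independently
#' initialized probe restarts; the averaged depth vector is what all
#' downstream geometry and RSA measures consume.
#'
#' @param depthVectors list of [ParseDepthVector-class] (or numeric vectors)
#'   of identical length.
#' @return a [ParseDepthVector-class] with `source = "probe"`.
#' @export
averageRestarts <- function(depthVectors) {
  stopifnot(length(depthVectors) >= 1L)
  vecs <- lapply(depthVectors, function(v)
    if (is(v, "ParseDepthVector")) v@depths else as.numeric(v))
  len <- unique(lengths(vecs))
  if (length(len) != 1L) stop("restart predictions have mismatched shapes")
  sid <- if (is(depthVectors[[1]], "ParseDepthVector"))
    depthVectors[[1]]@sentenceId else "sentence"
  new("ParseDepthVector", sentenceId = sid,
      depths = colMeans(do.call(rbind, vecs)), source = "probe")
}

#' Predict with every restart and average
#'
#' Convenience wrapper: applies each restart's transform kept in the probe
#' metadata and averages the predictions in depth space.
#'
#' @inheritParams predictDepths
#' @return a [ParseDepthVector-class].
#' @export
predictDepthsAveraged <- function(probe, embeddings, sentenceId = "sentence") {
  Bs <- probe@meta$restart_transforms
  if (is.null(Bs)) return(predictDepths(probe, embeddings, sentenceId))
  preds <- lapply(Bs, function(B)
    predictDepths(new("ProbeModel", transform = B, meta = list()),
                  embeddings, sentenceId))
  averageRestarts(preds)
}

#' Root accuracy of a probe
#'
#' Fraction of evaluation sentences in which the smallest predicted parse
#' depth (with the whole sentence as input) is assigned to the main verb —
#' the root of the dependency parse tree, whose parse depth is 0. A
#' non-unique minimum counts as incorrect.
#'
#' @param probe a [ProbeModel-class].
#' @param embeddings an [EmbeddingSet-class]; for each sentence the entry
#'   with the largest prefix length is taken as the whole-sentence input.
#' @param mainVerb named integer vector: main-verb (root) position per
#'   sentence id.
#' @param tieTol two depths closer than this are tied (default 1e-9).
#' @return fraction in `[0, 1]`.
#' @export
rootAccuracy <- function(probe, embeddings, mainVerb, tieTol = 1e-9) {
  stopifnot(is(embeddings, "EmbeddingSet"))
  keys <- names(embeddings@embeddings)
  sid <- sub("#.*", "", keys)
  plen <- as.integer(sub(".*#", "", keys))
  ids <- unique(sid)
  missing <- setdiff(ids, names(mainVerb))
  if (length(missing))
    stop("missing main-verb annotation for: ", paste(missing, collapse = ", "))
  correct <- vapply(ids, function(s) {
    k <- keys[sid == s][which.max(plen[sid == s])]
    d <- predictDepths(probe, embeddings@embeddings[[k]], s)@depths
    mn <- min(d)
    hits <- which(d <= mn + tieTol)
    length(hits) == 1L && hits == mainVerb[[s]]
  }, logical(1))
  mean(correct)
}

#' Positional contribution to parse-depth vectors
#'
#' Shuffles the parse depths of the words at one position across sentences
#' (keeping other positions fixed) and measures the mean Spearman distance
#' (1 - Spearman's rho) between each sentence's original and shuffled depth
#' vector, averaged over sentences and shuffles. The larger the distance,
#' the more the words at that position contribute to the cross-sentence
#' variance of the vectors.
#'
#' @param depthMatrix numeric `sentences x prefix_len` matrix of parse
#'   depths at a fixed prefix.
#' @param position column to shuffle.
#' @param nShuffles number of random shuffles (default 100).
#' @param seed RNG seed.
#' @return mean Spearman distance in `[0, 2]`; `NA` (with a warning) if
#'   every depth vector is constant so that rank correlation is undefined.
#' @export
positionContribution <- function(depthMatrix, position, nShuffles = 100L,
                                 seed = 1L) {
  stopifnot(is.matrix(depthMatrix), nrow(depthMatrix) >= 3L,
            position >= 1L, position <= ncol(depthMatrix))
  nS <- nrow(depthMatrix)
  dist1 <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    1 - cor(a, b, method = "spearman")
  }
  set.seed(seed)
  vals <- replicate(nShuffles, {
    perm <- sample.int(nS)
    shuf <- depthMatrix
    shuf[, position] <- depthMatrix[perm, position]
    mean(vapply(seq_len(nS), function(i)
      dist1(depthMatrix[i, ], shuf[i, ]), numeric(1)), na.rm = TRUE)
  })
  out <- mean(vals, na.rm = TRUE)
  if (!is.finite(out)) {
    warning("Spearman distance undefined: constant depth vectors")
    return(NA_real_)
  }
  out
}

#' Compare probes (layers) by root accuracy
#'
#' Helper for picking the best representation source among several embedding
#' sets: trains (or applies) one probe per set and ranks them by root
#' accuracy on the evaluation data.
#'
#' @param probes named list of [ProbeModel-class], one per candidate layer.
#' @param embeddingSets named list of [EmbeddingSet-class], same names.
#' @param mainVerb named integer vector of main-verb positions.
#' @return data.frame with columns `layer`, `root_accuracy`, sorted
#'   decreasing.
#' @export
compareLayers <- function(probes, embeddingSets, mainVerb) {
  stopifnot(identical(sort(names(probes)), sort(names(embeddingSets))))
  acc <- vapply(names(probes), function(nm)
    rootAccuracy(probes[[nm]], embeddingSets[[nm]], mainVerb), numeric(1))
  out <- data.frame(layer = names(probes), root_accuracy = unname(acc))
  out[order(-out$root_accuracy), , drop = FALSE]
}
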