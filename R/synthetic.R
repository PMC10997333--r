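.vocab <- list(
  nouns = c("dog", "king", "child", "artist", "farmer", "singer", "doctor",
            "pilot", "teacher", "sailor", "poet", "miner", "baker", "clerk",
            "judge", "nurse", "monk", "guard", "chef", "scout"),
  verbs1 = c("found", "walked", "moved", "watched", "left", "dressed",
             "washed", "turned", "called", "pushed", "raced", "bathed",
             "cheered", "guided", "rushed", "served", "trained", "carried",
             "dropped", "lifted"),
  places = c("park", "garden", "market", "harbour", "field", "forest",
             "square", "station", "meadow", "valley", "castle", "village",
             "stable", "chapel", "museum", "orchard", "quarry", "theatre",
             "library", "tavern"),
  verbs2 = c("covered", "praised", "noticed", "greeted", "scolded",
             "painted", "admired", "spotted", "briefed", "thanked",
             "teased", "helped", "blamed", "chased", "hugged", "saluted",
             "sketched", "quizzed", "filmed", "timed"),
  finals = c("mud", "public", "silence", "secret", "daylight", "private",
             "winter", "summer", "passing", "earnest", "style", "return",
             "protest", "delight", "sorrow", "wonder", "haste", "jest",
             "vain", "turn")
)

pick <- function(pool, i) pool[((i - 1L) %% length(pool)) + 1L]

# Passive full-sentence parse of a target sentence
#   The(1) SN(2) V1(3) prep(4) the(5) place(6) MV(7) V2(8) prep2(9) final(10)
# Convention: the word after the prepositional phrase is the main verb and
# the root; V1 heads the reduced relative clause attached to the subject
# noun; prepositions attach to the verb they modify, their nouns to the
# preposition, determiners to their nouns.
targetPassiveHeads <- function() c(2L, 7L, 2L, 3L, 6L, 4L, 0L, 7L, 8L, 9L)

# Active parse of the prefix before the actual main verb: V1 is the root.
targetActiveHeads <- function() c(2L, 3L, 0L, 3L, 6L, 4L)

#' Generate the synthetic stimulus set
#'
#' Builds sentence sets mirroring the stimulus design: each set holds six
#' spoken sentences (unambiguous, high-transitivity and low-transitivity
#' targets, passive, and two direct-object fillers); the two target
#' sentences per set differ only in the transitivity bias of Verb1 and each
#' carries both a passive-interpretation and an active-interpretation
#' dependency parse over the same tokens. Word-position labels (determiner,
#' subject noun, Verb1, prepositional phrase, main verb) and simple word
#' timing metadata (onset/uniqueness-point offsets) are recorded.
#'
#' @param nSets number of sentence sets (default 60, i.e. 360 sentences of
#'   which 120 are targets).
#' @param seed RNG seed (word timing jitter only; token choice is
#'   deterministic in the set index).
#' @return list with `sentences` (data.frame: sentence_id, set, condition,
#'   is_target, text, n_tokens, det_pos, sn_pos, v1_pos, pp1_pos, pp3_pos,
#'   mv_pos, onset_ms, uniqueness_ms), `trees` (named list; targets map to
#'   a list with `passive` and `active` [DependencyTree-class] objects,
#'   fillers to a single tree) and `tokens` (named list of token vectors).
#' @export
generateStimuli <- function(nSets = 60L, seed = 1L) {
  set.seed(seed)
  conds <- c("UNA", "HiTrans", "LoTrans", "PAS", "DO1", "DO2")
  rows <- list(); trees <- list(); toks <- list()
  for (s in seq_len(nSets)) {
    sn <- pick(.vocab$nouns, s)
    pl <- pick(.vocab$places, s)
    v2 <- pick(.vocab$verbs2, s)
    fin <- pick(.vocab$finals, s)
    for (cond in conds) {
      id <- sprintf("set%02d_%s", s, cond)
      isTarget <- cond %in% c("HiTrans", "LoTrans")
      blend <- NA_real_
      if (isTarget) {
        v1 <- pick(.vocab$verbs1, s + (cond == "LoTrans") * nSets)
        tk <- c("The", sn, v1, "in", "the", pl, "was", v2, "in", fin)
        # sentence-specific interpretation preference: trajectories are
        # distributed within condition, not a single point per condition
        blend <- if (cond == "HiTrans") runif(1, 0.6, 0.9) else runif(1, 0.1, 0.4)
        trees[[id]] <- list(
          passive = buildTree(tk, targetPassiveHeads(), "passive", id),
          active = buildTree(tk[1:6], targetActiveHeads(), "active", id))
        pos <- c(det = 1L, sn = 2L, v1 = 3L, pp1 = 4L, pp3 = 6L, mv = 7L)
      } else if (cond == "UNA") {
        v1 <- pick(.vocab$verbs1, s + 2L * nSets)
        tk <- c("The", sn, "that", "was", v1, "in", "the", pl, "was", v2)
        hd <- c(2L, 9L, 5L, 5L, 2L, 5L, 8L, 6L, 0L, 9L)
        trees[[id]] <- buildTree(tk, hd, "other", id)
        pos <- c(det = 1L, sn = 2L, v1 = 5L, pp1 = 6L, pp3 = 8L, mv = 9L)
      } else if (cond == "PAS") {
        tk <- c("The", sn, "was", v2, "in", "the", pl)
        hd <- c(2L, 3L, 0L, 3L, 4L, 7L, 5L)
        trees[[id]] <- buildTree(tk, hd, "other", id)
        pos <- c(det = 1L, sn = 2L, v1 = 4L, pp1 = 5L, pp3 = 7L, mv = 3L)
      } else {
        v1 <- pick(.vocab$verbs1, s + 3L * nSets)
        obj <- pick(.vocab$nouns, s + (cond == "DO2") * 7L + 3L)
        tk <- c("The", sn, v1, "the", obj, "in", "the", pl)
        hd <- c(2L, 3L, 0L, 5L, 3L, 3L, 8L, 6L)
        trees[[id]] <- buildTree(tk, hd, "other", id)
        pos <- c(det = 1L, sn = 2L, v1 = 3L, pp1 = 6L, pp3 = 8L, mv = 3L)
      }
      n <- length(tk)
      onset <- cumsum(c(0, round(runif(n - 1, 200, 450))))
      uniq <- onset + round(runif(n, 120, 300))
      toks[[id]] <- tk
      rows[[id]] <- data.frame(
        sentence_id = id, set = s, condition = cond, is_target = isTarget,
        text = paste(tk, collapse = " "), n_tokens = n,
        det_pos = pos[["det"]], sn_pos = pos[["sn"]], v1_pos = pos[["v1"]],
        pp1_pos = pos[["pp1"]], pp3_pos = pos[["pp3"]], mv_pos = pos[["mv"]],
        blend = blend,
        onset_ms = paste(onset, collapse = ","),
        uniqueness_ms = paste(uniq, collapse = ","))
    }
  }
  list(sentences = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       trees = trees, tokens = toks)
}

#' @rdname generateStimuli
#' @param stimuli output of `generateStimuli()`.
#' @return `targetIds()` the sentence ids of the 2-per-set target sentences
#'   in canonical stimulus order.
#' @export
targetIds <- function(stimuli) {
  stimuli$sentences$sentence_id[stimuli$sentences$is_target]
}

# Scheduled (planted) parse depth of each word of a target sentence at a
# given prefix length: a blend of the active and passive context-free full
# tree depths, moving to the passive parse once the main verb is heard.
depthSchedule <- function(stimuli, id, prefixLen, blend = NULL) {
  row <- stimuli$sentences[stimuli$sentences$sentence_id == id, ]
  tr <- stimuli$trees[[id]]
  dPass <- nodeDepths(tr$passive)@depths
  dAct <- nodeDepths(tr$active)@depths
  dAct <- c(dAct, dPass[(length(dAct) + 1):length(dPass)])
  if (is.null(blend)) {
    blend <- row$blend
    if (is.na(blend))
      blend <- if (row$condition == "HiTrans") 0.75 else 0.25
  }
  alpha <- if (prefixLen >= row$mv_pos) 1 else blend
  w <- seq_len(prefixLen)
  alpha * dPass[w] + (1 - alpha) * dAct[w]
}

nullspaceBasis <- function(B) {
  d <- ncol(B)
  q <- qr(t(B))
  Q <- qr.Q(q, complete = TRUE)
  if (d > nrow(B)) Q[, (nrow(B) + 1):d, drop = FALSE] else NULL
}

#' Generate embeddings with a planted linear depth structure
#'
#' For every target sentence and every incremental prefix, per-word
#' embeddings h are constructed such that `||B0 h||^2` equals the scheduled
#' parse depth (the context-free depth blended toward the condition's
#' preferred interpretation, switching to the passive parse at the main
#' verb) plus optional Gaussian noise; a random null-space component of B0
#' is added so the embeddings are not confined to the probed subspace.
#'
#' @param stimuli output of [generateStimuli()].
#' @param d embedding dimension (default 16).
#' @param k rank of the planted probe matrix B0 (default 8).
#' @param B0 optional planted probe matrix (k x d, full row rank); default
#'   drawn from the seed.
#' @param noiseSd SD of Gaussian noise added to the scheduled depth before
#'   embedding (default 0); noisy depths are clamped at 0.
#' @param prefixes which prefix lengths to generate per sentence; default
#'   all `1..n_tokens`.
#' @param seed RNG seed.
#' @return list with `embeddings` ([EmbeddingSet-class]), `gold` (named
#'   list of planted depth vectors per entry), `B0`.
#' @export
generateEmbeddings <- function(stimuli, d = 16L, k = 8L, B0 = NULL,
                               noiseSd = 0, prefixes = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(B0)) B0 <- matrix(rnorm(k * d), k, d)
  k <- nrow(B0); d <- ncol(B0)
  if (qr(B0)$rank < k) stop("B0 must have full row rank")
  Bpinv <- t(B0) %*% solve(tcrossprod(B0))
  Nsp <- nullspaceBasis(B0)
  emb <- list(); gold <- list()
  ids <- targetIds(stimuli)
  for (id in ids) {
    n <- stimuli$sentences$n_tokens[stimuli$sentences$sentence_id == id]
    pls <- if (is.null(prefixes)) seq_len(n) else prefixes[prefixes <= n]
    for (L in pls) {
      sched <- depthSchedule(stimuli, id, L)
      if (any(sched < 0)) stop("infeasible schedule: negative target depth")
      tgt <- pmax(0, sched + rnorm(L, sd = noiseSd))
      H <- matrix(0, L, d)
      for (w in seq_len(L)) {
        u <- rnorm(k); u <- u / sqrt(sum(u^2))
        h <- Bpinv %*% (sqrt(tgt[w]) * u)
        if (!is.null(Nsp)) h <- h + Nsp %*% rnorm(ncol(Nsp), sd = 0.5)
        H[w, ] <- h
      }
      key <- embKey(id, L)
      emb[[key]] <- H
      gold[[key]] <- sched
    }
  }
  list(embeddings = embeddingSet(emb, layerTag = "planted"),
       gold = gold, B0 = B0)
}

betaFromMoments <- function(m, s) {
  nu <- m * (1 - m) / s^2 - 1
  if (nu <= 0) stop("infeasible beta moments")
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

# Latent per-sentence direct-object probability shared by the corpus-count
# and continuation generators (same seed -> same latent), carrying the
# condition gap in transitivity.
latentDoProb <- function(stimuli, doMeanHi = 0.71, doSdHi = 0.16,
                         doMeanLo = 0.44, doSdLo = 0.19, seed = 1L) {
  ids <- targetIds(stimuli)
  cond <- stimuli$sentences$condition[stimuli$sentences$is_target]
  set.seed(as.integer((as.numeric(seed) * 1000003) %% 2147483647))
  p <- numeric(length(ids))
  hi <- betaFromMoments(doMeanHi, doSdHi)
  lo <- betaFromMoments(doMeanLo, doSdLo)
  p[cond == "HiTrans"] <- stats::rbeta(sum(cond == "HiTrans"), hi[1], hi[2])
  p[cond == "LoTrans"] <- stats::rbeta(sum(cond == "LoTrans"), lo[1], lo[2])
  pmin(pmax(p, 0.03), 0.97)
}

#' Generate corpus count tables with condition-correlated biases
#'
#' Draws per-sentence thematic-role and subcategorization tallies such that
#' Verb1 log-transitivity is higher for high-transitivity than for
#' low-transitivity targets (the gap set by the condition direct-object
#' probability means) and subject-noun patienthood co-varies with
#' transitivity, as the constraint analysis assumes. All counts are >= 1.
#'
#' @param stimuli output of [generateStimuli()].
#' @param nVerb,nNoun corpus tally sizes per sentence (default 200).
#' @param doMeanHi,doSdHi,doMeanLo,doSdLo condition means/SDs of the latent
#'   direct-object probability (defaults 0.71/0.16 and 0.44/0.19).
#' @param roleCoupling slope tying the latent patient-role probability to
#'   the direct-object probability (default 0.6).
#' @param seed RNG seed; the latent probabilities are shared with
#'   [generateContinuations()] at the same seed.
#' @return data.frame with sentence_id, condition, agent_count,
#'   patient_count, do_count, other_scf_count.
#' @export
generateCorpusCounts <- function(stimuli, nVerb = 200L, nNoun = 200L,
                                 doMeanHi = 0.71, doSdHi = 0.16,
                                 doMeanLo = 0.44, doSdLo = 0.19,
                                 roleCoupling = 0.6, seed = 1L) {
  ids <- targetIds(stimuli)
  cond <- stimuli$sentences$condition[stimuli$sentences$is_target]
  p <- latentDoProb(stimuli, doMeanHi, doSdHi, doMeanLo, doSdLo, seed)
  set.seed(seed)
  do_count <- pmax(1L, rbinom(length(ids), nVerb, p))
  other <- pmax(1L, nVerb - do_count)
  q <- pmin(pmax(0.5 + roleCoupling * (p - mean(c(doMeanHi, doMeanLo))) +
                   rnorm(length(ids), sd = 0.08), 0.05), 0.95)
  patient_count <- pmax(1L, rbinom(length(ids), nNoun, q))
  agent_count <- pmax(1L, nNoun - patient_count)
  data.frame(sentence_id = ids, condition = cond,
             agent_count = agent_count, patient_count = patient_count,
             do_count = do_count, other_scf_count = other)
}

#' Generate sentence-continuation count tables
#'
#' Emulates the two continuation pre-tests: after Verb1, responses are
#' split between direct-object, prepositional-phrase and other
#' continuations with the direct-object probability tied to the sentence's
#' latent transitivity; after the prepositional phrase, main-verb
#' continuations are more likely the more transitive (passive-leaning) the
#' sentence.
#'
#' @param stimuli output of [generateStimuli()].
#' @param nAfterV1,nAfterPP responses per sentence at the two gates
#'   (defaults 30 and 18, the pre-test group sizes).
#' @param mvCoupling slope tying main-verb probability to the latent
#'   direct-object probability (default 0.9).
#' @inheritParams generateCorpusCounts
#' @return data.frame in the layout [continuationProbabilities()] reads:
#'   sentence_id, gate, n_responses, n_direct_object,
#'   n_prepositional_phrase, n_main_verb.
#' @export
generateContinuations <- function(stimuli, nAfterV1 = 30L, nAfterPP = 18L,
                                  doMeanHi = 0.71, doSdHi = 0.16,
                                  doMeanLo = 0.44, doSdLo = 0.19,
                                  mvCoupling = 0.9, seed = 1L) {
  ids <- targetIds(stimuli)
  p <- latentDoProb(stimuli, doMeanHi, doSdHi, doMeanLo, doSdLo, seed)
  set.seed(seed + 1L)
  nDO <- rbinom(length(ids), nAfterV1, p)
  nPP <- rbinom(length(ids), nAfterV1 - nDO, 0.8)
  pMV <- pmin(pmax(0.5 + mvCoupling * (p - 0.5) + rnorm(length(ids), sd = 0.1),
                   0.02), 0.98)
  nMV <- rbinom(length(ids), nAfterPP, pMV)
  rbind(
    data.frame(sentence_id = ids, gate = "afterV1", n_responses = nAfterV1,
               n_direct_object = nDO, n_prepositional_phrase = nPP,
               n_main_verb = 0L),
    data.frame(sentence_id = ids, gate = "afterPP", n_responses = nAfterPP,
               n_direct_object = 0L, n_prepositional_phrase = 0L,
               n_main_verb = nMV))
}

#' Generate a synthetic cortical vertex table
#'
#' Uniform random vertices in a box whose extent gives nearest-neighbor
#' spacings of a few mm (so a 10 mm searchlight holds a handful of
#' vertices), split into left/right regions at the midline.
#'
#' @param nVertices vertex count.
#' @param extent box dimensions in mm (default `c(60, 60, 30)`).
#' @param seed RNG seed.
#' @return data.frame with `vertex_id`, `x`, `y`, `z`, `region`.
#' @export
generateMesh <- function(nVertices = 50L, extent = c(60, 60, 30), seed = 1L) {
  set.seed(seed)
  xyz <- cbind(runif(nVertices, -extent[1] / 2, extent[1] / 2),
               runif(nVertices, -extent[2] / 2, extent[2] / 2),
               runif(nVertices, -extent[3] / 2, extent[3] / 2))
  data.frame(vertex_id = sprintf("v%04d", seq_len(nVertices)),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             region = ifelse(xyz[, 1] < 0, "left", "right"))
}

#' Generate source-space epochs with planted representational geometry
#'
#' Epochs are spatially correlated Gaussian noise (exponential spatial
#' covariance, temporally white) plus, inside each effect's vertex set and
#' time window, a signal whose across-sentence pattern geometry matches the
#' target model RDM: the RDM is embedded by classical multidimensional
#' scaling (rank <= 10) and mapped onto random orthonormal spatiotemporal
#' patterns shared by all participants, scaled by the effect size.
#'
#' @param sentenceIds condition order of the sentence dimension.
#' @param mesh vertex table from [generateMesh()].
#' @param nParticipants participants (default 12).
#' @param samplingRate Hz (default 200).
#' @param epochMs epoch length in ms (default 600).
#' @param epochLabel `"V1"`, `"PP1"` or `"MV"`.
#' @param effects list of effects, each a list with `vertices` (indices
#'   into the mesh), `window` (`c(start, end)` in ms), `rdm` (an
#'   [RDM-class] over `sentenceIds`) and `size` (> 0; default 2).
#'   Overlapping effects with different RDMs are rejected.
#' @param noiseSd noise SD per cell (default 1).
#' @param lengthScale spatial noise correlation length in mm (default 15).
#' @param seed RNG seed.
#' @return a [SourceEpochs-class].
#' @export
generateEpochs <- function(sentenceIds, mesh, nParticipants = 12L,
                           samplingRate = 200, epochMs = 600,
                           epochLabel = "MV", effects = list(),
                           noiseSd = 1, lengthScale = 15, seed = 1L) {
  set.seed(seed)
  nS <- length(sentenceIds)
  nV <- nrow(mesh)
  nT <- as.integer(round(epochMs / 1000 * samplingRate))
  times <- (seq_len(nT) - 1L) * 1000 / samplingRate
  D <- as.matrix(dist(as.matrix(mesh[, c("x", "y", "z")])))
  K <- exp(-D / lengthScale)
  L <- t(chol(K + diag(1e-8, nV)))
  data <- array(0, c(nParticipants, nS, nV, nT))

  # planted signals (shared across participants)
  signal <- array(0, c(nS, nV, nT))
  owner <- array(0L, c(nV, nT))
  for (ei in seq_along(effects)) {
    ef <- effects[[ei]]
    if (is.null(ef$size)) ef$size <- 2
    if (ef$size <= 0) stop("effect size must be positive")
    if (any(ef$vertices < 1L | ef$vertices > nV))
      stop("effect vertex set outside mesh")
    rdm <- ef$rdm
    stopifnot(is(rdm, "RDM"))
    if (!identical(rdm@conditions, as.character(sentenceIds)))
      stop("effect RDM condition order must match sentenceIds")
    tIdx <- which(times >= ef$window[1] & times <= ef$window[2])
    if (!length(tIdx)) stop("effect window outside the epoch")
    cellsV <- rep(ef$vertices, times = length(tIdx))
    cellsT <- rep(tIdx, each = length(ef$vertices))
    prev <- owner[cbind(cellsV, cellsT)]
    if (any(prev > 0L))
      stop("overlapping effects with contradictory RDMs at effect ", ei)
    owner[cbind(cellsV, cellsT)] <- ei
    r <- min(10L, nS - 1L)
    Y <- suppressWarnings(cmdscale(rdm@matrix, k = r))
    Y <- scale(Y, center = TRUE, scale = FALSE)
    Y <- Y / sqrt(mean(rowSums(Y^2)))
    nCells <- length(cellsV)
    r <- ncol(Y)
    U <- qr.Q(qr(matrix(rnorm(nCells * r), nCells, r)))
    G <- sqrt(nCells) * ef$size * (Y %*% t(U))   # nS x nCells
    for (s in seq_len(nS))
      signal[s, , ][cbind(cellsV, cellsT)] <-
        signal[s, , ][cbind(cellsV, cellsT)] + G[s, ]
  }

  for (p in seq_len(nParticipants)) {
    for (s in seq_len(nS)) {
      noise <- noiseSd * (L %*% matrix(rnorm(nV * nT), nV, nT))
      data[p, s, , ] <- signal[s, , ] + noise
    }
  }
  new("SourceEpochs", data = data, samplingRate = samplingRate,
      epochLabel = epochLabel, sentenceIds = as.character(sentenceIds),
      times = times)
}
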