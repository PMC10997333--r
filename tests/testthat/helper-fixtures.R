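# Fixture trees: the worked target sentence with its two structural
# readings (main verb = root convention; V1 heads the reduced relative
# attached to the subject noun; prepositions attach to their verb, their
# nouns to the preposition, determiners to their nouns).
fixtureTokens <- function() {
  c("The", "dog", "found", "in", "the", "park", "was", "covered", "in", "mud")
}

fixturePassive <- function() {
  buildTree(fixtureTokens(), c(2L, 7L, 2L, 3L, 6L, 4L, 0L, 7L, 8L, 9L),
            "passive", "fixture")
}

fixtureActive <- function() {
  buildTree(fixtureTokens()[1:6], c(2L, 3L, 0L, 3L, 6L, 4L),
            "active", "fixture")
}

chainTree <- function(n) {
  buildTree(paste0("w", seq_len(n)), c(0L, seq_len(n - 1L)), "other", "chain")
}

# Small planted embedding problem shared by probe tests.
plantedProblem <- function(nSets = 4L, d = 10L, k = 5L, noiseSd = 0,
                           seed = 11L) {
  st <- generateStimuli(nSets, seed = seed)
  gen <- generateEmbeddings(st, d = d, k = k, noiseSd = noiseSd,
                            seed = seed + 1L)
  list(stimuli = st, gen = gen,
       mv = setNames(st$sentences$mv_pos[st$sentences$is_target],
                     targetIds(st)))
}
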