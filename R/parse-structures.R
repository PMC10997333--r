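#' Build a validated dependency tree
#'
#' Constructs a [DependencyTree-class] from tokens and a head assignment and
#' runs full structural validation: exactly one root (head 0), all head
#' indices in range, no cycles, so that the head relation forms a rooted
#' tree with n - 1 edges. Malformed input raises an error naming the
#' offending token.
#'
#' @param tokens character vector of word forms (positions 1-based).
#' @param head integer vector of head positions, 0 marking the root.
#' @param interpretation `"passive"`, `"active"` or `"other"` — which
#'   structural reading this tree encodes.
#' @param sentenceId identifier stored with the tree.
#' @return a [DependencyTree-class].
#' @examples
#' tr <- buildTree(c("The", "dog", "barked"), c(2L, 3L, 0L), "active", "ex1")
#' depths(nodeDepths(tr))
#' @export
buildTree <- function(tokens, head, interpretation = "other",
                      sentenceId = "sentence") {
  tokens <- as.character(tokens)
  head <- as.integer(head)
  new("DependencyTree", sentenceId = as.character(sentenceId)[1],
      tokens = tokens, head = head,
      interpretation = match.arg(interpretation,
                                 c("passive", "active", "other")))
}

#' Context-free parse depth of every word in a tree
#'
#' The parse depth of a word is the number of edges between it and the root
#' of the dependency parse tree: the root has depth 0 and every dependent's
#' depth is its head's depth plus one.
#'
#' @param tree a [DependencyTree-class].
#' @return a [ParseDepthVector-class] with `source = "context_free"`
#'   covering the full sentence.
#' @export
nodeDepths <- function(tree) {
  stopifnot(is(tree, "DependencyTree"))
  h <- tree@head
  n <- length(h)
  depth <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- 0L
    j <- i
    while (h[j] != 0L) {
      j <- h[j]
      d <- d + 1L
    }
    depth[i] <- d
  }
  new("ParseDepthVector", sentenceId = tree@sentenceId, depths = depth,
      source = "context_free")
}

#' Landmark parse-depth vector for a sentence prefix
#'
#' Slices the context-free parse depths of a full-sentence tree to the first
#' `prefixLen` words. The 3-word prefix (determiner, subject noun, Verb1) of
#' the passive and active parses serves as the pair of landmarks in the
#' parse-depth model space against which incremental probe-estimated vectors
#' are compared.
#'
#' @param tree a [DependencyTree-class].
#' @param prefixLen number of words heard so far; must be in
#'   `1..nTokens(tree)`.
#' @return a [ParseDepthVector-class] of length `prefixLen`.
#' @export
landmarkVector <- function(tree, prefixLen) {
  stopifnot(is(tree, "DependencyTree"))
  prefixLen <- as.integer(prefixLen)
  if (prefixLen < 1L || prefixLen > length(tree@tokens))
    stop(sprintf("prefixLen %d out of range 1..%d", prefixLen,
                 length(tree@tokens)))
  full <- nodeDepths(tree)
  new("ParseDepthVector", sentenceId = tree@sentenceId,
      depths = full@depths[seq_len(prefixLen)], source = "context_free")
}

#' Read and write dependency trees as CoNLL-U
#'
#' Minimal CoNLL-U interface: the 10-column tab-separated format with one
#' token per line, sentence breaks on blank lines and `# sent_id` /
#' `# interpretation` comment lines. Only the ID, FORM and HEAD columns are
#' interpreted (HEAD 0 = root); the remaining columns are written as `_`.
#' Multiword-token and empty-node lines (IDs containing `-` or `.`) are
#' skipped on read.
#'
#' @param path file path.
#' @return `readConllu()` a list of [DependencyTree-class] objects.
#' @export
readConllu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trees <- list()
  tok <- character(); hd <- integer()
  sid <- NULL; interp <- "other"
  flush <- function() {
    if (length(tok)) {
      trees[[length(trees) + 1L]] <<- buildTree(
        tok, hd, interp, sid %||% sprintf("sentence%d", length(trees) + 1L))
    }
    tok <<- character(); hd <<- integer(); sid <<- NULL; interp <<- "other"
  }
  for (ln in lines) {
    if (!nzchar(trimws(ln))) { flush(); next }
    if (startsWith(ln, "#")) {
      kv <- sub("^#\\s*", "", ln)
      if (grepl("^sent_id\\s*=", kv))
        sid <- trimws(sub("^sent_id\\s*=", "", kv))
      if (grepl("^interpretation\\s*=", kv))
        interp <- trimws(sub("^interpretation\\s*=", "", kv))
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 7) stop("malformed CoNLL-U line: ", ln)
    if (grepl("[-.]", f[1])) next
    tok[length(tok) + 1L] <- f[2]
    hd[length(hd) + 1L] <- as.integer(f[7])
  }
  flush()
  trees
}

#' @rdname readConllu
#' @param trees list of [DependencyTree-class] objects (or a single tree).
#' @return `writeConllu()` the path, invisibly.
#' @export
writeConllu <- function(trees, path) {
  if (is(trees, "DependencyTree")) trees <- list(trees)
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in trees) {
    writeLines(sprintf("# sent_id = %s", tr@sentenceId), con)
    writeLines(sprintf("# interpretation = %s", tr@interpretation), con)
    n <- length(tr@tokens)
    writeLines(sprintf("%d\t%s\t_\t_\t_\t_\t%d\t_\t_\t_",
                       seq_len(n), tr@tokens, tr@head), con)
    writeLines("", con)
  }
  invisible(path)
}
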