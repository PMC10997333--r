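#' Corpus ratio measures of lexical constraints
#'
#' From per-sentence corpus tallies, derives the subject-noun thematic-role
#' ratios and the Verb1 subcategorization ratios:
#' agenthood = (agent + s) / (patient + s) and patienthood its reciprocal;
#' transitivity = (direct-object + s) / (other-SCF + s) and intransitivity
#' its reciprocal, with `s` an optional additive smoothing constant
#' (default 0, in which case a zero denominator is an error).
#'
#' @param counts data.frame with columns `sentence_id`, `agent_count`,
#'   `patient_count`, `do_count`, `other_scf_count` (all counts >= 0).
#' @param smoothing additive smoothing constant `s` (default 0).
#' @return the input data.frame with columns `agenthood`, `patienthood`,
#'   `transitivity`, `intransitivity` appended.
#' @export
ratioMeasures <- function(counts, smoothing = 0) {
  need <- c("sentence_id", "agent_count", "patient_count", "do_count",
            "other_scf_count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- counts[, c("agent_count", "patient_count", "do_count",
                   "other_scf_count")]
  if (any(cc < 0)) stop("counts must be non-negative")
  s <- smoothing
  if (s == 0 && any(cc == 0))
    stop("zero count with smoothing 0 makes a ratio undefined; ",
         "set smoothing > 0")
  counts$agenthood <- (counts$agent_count + s) / (counts$patient_count + s)
  counts$patienthood <- 1 / counts$agenthood
  counts$transitivity <- (counts$do_count + s) / (counts$other_scf_count + s)
  counts$intransitivity <- 1 / counts$transitivity
  counts
}

#' Interpretative-coherence indices
#'
#' The passive index multiplies subject-noun patienthood with Verb1
#' transitivity (both large when the passive reading is coherent); the
#' active index multiplies agenthood with intransitivity. The
#' non-directional index applies a logarithmic transformation to the ratio
#' measures before multiplying them — here fixed as
#' `log(agenthood) * log(intransitivity)` — which removes the directionality:
#' jointly swapping each ratio with its reciprocal leaves it unchanged.
#'
#' @param table data.frame holding `agenthood`, `patienthood`,
#'   `transitivity`, `intransitivity` (e.g. the output of
#'   [ratioMeasures()]).
#' @return the data.frame with `passive_index`, `active_index`,
#'   `nondirectional_index` appended.
#' @export
interpretationIndices <- function(table) {
  need <- c("agenthood", "patienthood", "transitivity", "intransitivity")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing ratio measures: ",
                         paste(miss, collapse = ", "))
  r <- table[, need]
  if (any(!is.finite(as.matrix(r))))
    stop("non-finite ratio measures; apply smoothing upstream")
  table$passive_index <- table$patienthood * table$transitivity
  table$active_index <- table$agenthood * table$intransitivity
  table$nondirectional_index <- log(table$agenthood) * log(table$intransitivity)
  table
}

#' Continuation-derived probabilities and contextual transitivity
#'
#' From sentence-continuation counts at two gates — immediately after Verb1
#' (`afterV1`) and immediately after the prepositional phrase (`afterPP`) —
#' derives the probability of a direct-object or prepositional-phrase
#' continuation (DO/PP probability, `afterV1`) and of a main verb
#' (MV probability, `afterPP`), plus the contextualized Verb1 transitivity
#' `DO_prob / (1 - DO_prob)` and its reciprocal.
#'
#' @param raw data.frame with columns `sentence_id`, `gate` (`"afterV1"` or
#'   `"afterPP"`), `n_responses`, `n_direct_object`,
#'   `n_prepositional_phrase`, `n_main_verb`.
#' @param epsilon clip for DO probabilities of exactly 0 or 1, which would
#'   make contextual transitivity infinite (default 1/2 a response:
#'   `0.5 / n_responses`); a warning reports any clipping.
#' @return data.frame per sentence with `DO_prob`, `PP_prob`, `MV_prob`,
#'   `ctx_transitivity`, `ctx_intransitivity`.
#' @export
continuationProbabilities <- function(raw, epsilon = NULL) {
  need <- c("sentence_id", "gate", "n_responses", "n_direct_object",
            "n_prepositional_phrase", "n_main_verb")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cnt <- raw[, c("n_direct_object", "n_prepositional_phrase", "n_main_verb")]
  if (any(cnt > raw$n_responses))
    stop("category count exceeds n_responses")
  v1 <- raw[raw$gate == "afterV1", ]
  pp <- raw[raw$gate == "afterPP", ]
  out <- data.frame(sentence_id = v1$sentence_id,
                    DO_prob = v1$n_direct_object / v1$n_responses,
                    PP_prob = v1$n_prepositional_phrase / v1$n_responses)
  mv <- data.frame(sentence_id = pp$sentence_id,
                   MV_prob = pp$n_main_verb / pp$n_responses)
  out <- merge(out, mv, by = "sentence_id", all.x = TRUE, sort = FALSE)
  p <- out$DO_prob
  clip <- p <= 0 | p >= 1
  if (any(clip, na.rm = TRUE)) {
    eps <- if (is.null(epsilon)) 0.5 / max(v1$n_responses) else epsilon
    warning(sprintf(
      "%d DO probabilities at 0 or 1 clipped by %.4g for contextual transitivity",
      sum(clip, na.rm = TRUE), eps))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  out$ctx_transitivity <- p / (1 - p)
  out$ctx_intransitivity <- 1 / out$ctx_transitivity
  out
}

#' Permutation test for a Spearman correlation
#'
#' Spearman's rho between `x` and `y` with a permutation p-value obtained by
#' permuting `y`: `p = (1 + #\{|rho_perm| >= |rho|\}) / (n_perm + 1)`
#' (two-sided on |rho| by default; one-sided available).
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (default) or `"greater"` (one-tailed on
#'   positive rho).
#' @return list with `rho`, `p`, `nPerm`.
#' @export
permutationSpearman <- function(x, y, nPerm = 10000L, seed = 1L,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 5L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input: Spearman's rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  set.seed(seed)
  stat <- function(r) if (alternative == "two.sided") abs(r) else r
  exceed <- 0L
  for (b in seq_len(nPerm)) {
    rp <- cor(rx, ry[sample.int(length(y))])
    if (stat(rp) >= stat(rho)) exceed <- exceed + 1L
  }
  list(rho = rho, p = (1 + exceed) / (nPerm + 1), nPerm = as.integer(nPerm))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control: flags hypotheses whose BH-adjusted p-value is below
#' `alpha` (equivalently p_(i) <= i/m * alpha up to the step-up rule).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `significant` (logical), `p_adjusted`, and `threshold`
#'   (largest rejected raw p, or 0 when nothing is rejected).
#' @export
fdrCorrect <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  padj <- stats::p.adjust(pvals, method = "BH")
  sig <- padj < alpha
  list(significant = sig, p_adjusted = padj,
       threshold = if (any(sig)) max(pvals[sig]) else 0)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t computed from group means, SDs and sizes
#' alone, with `df = n1 + n2 - 2`; used to check printed group contrasts
#' (e.g. direct-object subcategorization probabilities of the two verb
#' lists) without the raw per-item values.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries; SDs must be positive
#'   and sizes at least 2.
#' @return list with `t`, `df`, `p` (two-tailed).
#' @export
summaryTwoSampleT <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}
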