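---
title: "Incremental structural interpretation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incremental structural interpretation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(incstruct)
```

## The problem

During spoken comprehension a sentence's structure must be built
incrementally, before the input disambiguates it. The package centres on
reduced-relative ambiguities: in *"The dog found in the park was covered in
mud"* the fragment up to the prepositional phrase supports an **active**
reading (Verb1 = main verb, parse depth 0) and a **passive** reading
(Verb1 heads a reduced relative attached to the subject noun, parse
depth 2). `incstruct` provides the representational and statistical
machinery to track that interpretation in model space and to relate it to
simulated source-space neural data.

## Parse structures

A dependency parse is a rooted tree: each token points to its head, the
root is marked 0, and the parse depth of a word is its edge distance from
the root. Trees are validated on construction (single root, no cycles,
in-range heads) and exchanged as CoNLL-U (only ID/FORM/HEAD are
interpreted). Landmark vectors are the context-free depths of the first
three words (determiner, subject noun, Verb1): `(2, 1, 2)` passive,
`(2, 1, 0)` active.

Two conventions are fixed here because full-tree depths of auxiliaries are
genuinely underdetermined by the analysis itself:

- the word immediately after the prepositional phrase counts as the main
  verb and is the root of the passive parse (so the auxiliary *was* is the
  root in the worked sentence, and Verb1's head is the subject noun);
- prepositions attach to the verb they modify, their nouns to the
  preposition, determiners to their nouns.

These conventions are recorded in the fixture CoNLL-U files, not
hard-coded; only the Verb1 depths (2 passive / 0 active) are treated as
fixed facts of the two readings.

Context-free depths of an incremental prefix are the full-tree depths
sliced to the prefix: landmarks are static reference points, and
prefix-consistency (`landmarkVector(t, k)` is a prefix of
`landmarkVector(t, k + 1)`) is asserted in the tests.

## The structural probe

The probe is a linear map `B` (k × d) with predicted depth
`||B h||²` for embedding `h`. Training minimizes the per-sentence
length-normalized L1 loss between predicted and gold depths, averaged over
sentences — the established loss for this probe family (the squared-norm
parametrization already guarantees non-negative predictions). Choices the
probe family leaves open, fixed here and configurable:

- **Rank `k`**: default `d` (full rank).
- **Optimizer**: the L1 objective in the factor `B` defeats plain
  fixed-step gradient descent (the subgradient magnitude does not vanish
  near the optimum, and a fixed step stalls far from it). Training
  therefore runs an Adam-style adaptive phase (moment-scaled steps,
  decaying rate) to find the basin, followed by a monotone polish phase in
  which a step that would increase the loss is rejected and the step size
  halved; the accepted-loss trace is non-increasing by construction and the
  iterate converges geometrically inside the basin. On noiseless planted
  data this recovers the planted depths to near machine precision, which is
  the identifiability check in the tests.
- **Restarts**: 10 by default; the lowest-loss restart is returned and all
  restart transforms are kept so predictions can be averaged *in depth
  space* (the averaged depth vector, not an averaged transform, feeds all
  downstream measures).
- **Root accuracy tie-break**: a non-unique minimum counts as incorrect
  (strict reading of "the smallest depth is assigned to the main verb");
  ties are declared below a tolerance of 1e-9.

Positional contribution shuffles one position's depths across sentences
and reports the mean Spearman distance (1 − ρ) between original and
shuffled vectors. Constant vectors make rank correlation undefined; those
sentences are dropped with a warning, and an all-constant input returns
`NA`.

## Constraint measures

Ratios are definitional: agenthood = (agent + s)/(patient + s) with
patienthood its reciprocal, and likewise transitivity/intransitivity from
direct-object vs other-subcategorization tallies. The smoothing constant
`s` defaults to 0 with an explicit error on zero denominators — the
synthetic generator guarantees positive counts, so silent smoothing is
never needed by default. Passive index = patienthood × transitivity,
active index = agenthood × intransitivity (their product is 1 when built
from raw ratios), and the non-directional index is the product of
log-ratios, fixed by convention as `log(agenthood) · log(intransitivity)`;
the joint reciprocal swap leaves it unchanged, which is asserted as a
property.

Contextual transitivity from continuations is `p/(1 − p)` with the DO
probability `p`; boundary values 0/1 are clipped by half a response
(`0.5 / n_responses`) with a warning rather than propagating infinities.

Permutation Spearman tests permute `y`, use the add-one estimator
`(1 + #{|ρ*| ≥ |ρ|})/(B + 1)`, and default to two-sided on |ρ| — the
conservative reading for signed correlation maps; a one-sided mode is
available. FDR correction is Benjamini–Hochberg via `p.adjust`, checked
against a literal step-up implementation. The summary-statistics t-test is
pooled-variance with df = n1 + n2 − 2; a printed df of 117 for two
60-item lists is treated as a property of the verb lists (one item
excluded), so the check uses n = 60 and 59.

## Interpretation geometry

Interpretative mismatch is the cosine distance between an estimated
incremental depth vector and a context-free landmark of the same length —
scale-invariant, so it measures direction (structural shape), not overall
depth magnitude; zero-norm vectors are an error rather than silently 0.
Landmark distances along the unfolding sentence use Euclidean distance in
the 3-d model space by default: the model space is a geometric depth
space, and the cosine form is reserved for the mismatch measure where
direction is what matters; the metric is configurable and the trajectory
deltas telescope by construction. PCA of depth matrices is centered,
unscaled, with the sign fixed by making each component's
largest-magnitude loading positive. Model RDMs use absolute pairwise
difference for scalars and cosine distance for depth vectors; every RDM is
symmetrized and zero-diagonal by construction and carries its condition
order so mismatched orders are an error, not a silent misalignment.

## Searchlight RSA and cluster inference

Searchlights pair a 10 mm Euclidean sphere on the vertex mesh with a
±30 ms window (60 ms sliding window, centers at every sample by default,
stride configurable; windows are clipped at epoch edges rather than
dropped). Geodesic distances are not computed; a precomputed distance
structure can be emulated by supplying mesh coordinates accordingly.

Per searchlight the sentence patterns (vertices × window samples,
flattened) are whitened across vertices by the inverse square root of a
shrinkage covariance (Ledoit–Wolf-style intensity toward a scaled
identity) estimated from trial-mean-removed residuals within the same
searchlight; with an identity noise covariance the patterns are unchanged
up to scale. The data RDM is 1 − Pearson r between sentence patterns; a
constant pattern is reported as an error naming the sentences. Model fit
is Spearman's ρ over the lower triangle, so it is invariant to monotone
transforms of either RDM.

Group inference: one-tailed one-sample t over participants per
vertex × window (threshold at the `1 − p_vertex` t quantile, df =
participants − 1), spatiotemporal clusters scored by t-mass. Connectivity
is "spatial neighbors within the same window, same vertex across
consecutive windows", with the spatial neighbor graph defaulting to the
searchlight radius. The null is the maximal cluster mass over sign-flip
permutations of whole participant maps — the standard exchangeability
argument for a one-sample design; when the requested permutation count
reaches `2^participants` the flips are enumerated exhaustively with a
warning. The permutation t-statistics are computed in closed form from the
flipped means (the per-cell sum of squares is flip-invariant), which keeps
5000 permutations cheap. Family-wise error control is verified by
simulation in the tests (see problem sizes below).

## NMF and Granger causality

Each participant's model-fit map is z-scored per vertex over time
(the concatenation step needs a scale-free map; this is the normalization
chosen here), negatives are zeroed — negative model fits carry no
interpretable representational signal — and maps are concatenated along
time. Multiplicative-update NMF (Frobenius objective, non-increasing by
construction, asserted on the traces) is repeated 20 times per candidate
rank; the rank minimizing the best-restart RMS over 2…50 is chosen.

Granger causality stacks the two factor sets into one VAR, pooled across
participants as independent realizations (lagged rows never cross a
participant boundary); a per-participant mode is available but pooled
estimation matches the factor × time × participant input shape. The model
order is chosen by AIC (orders with fewer than twice as many rows as
predictors are not considered); an unstable VAR (companion spectral
radius ≥ 1) flags its connections rather than reporting statistics. The
statistic is the time-domain conditional GC: the log ratio of the
target's residual variance with the source's past excluded vs included —
invariant to separate linear rescaling of each series. Significance comes
from surrogates that cut the source series into contiguous windows of
length = model order (trailing samples dropped) and shuffle the window
order per participant; p-values use the add-one estimator, values below
0.005 are refined by a generalized Pareto fit (maximum likelihood via
`optim`) to the top 10% of surrogate exceedances, falling back to the raw
permutation p when the fit fails, and all connections are BH-FDR
corrected.

## What the synthetic generators emulate — and what they do not

- **Stimuli**: 60 sets × 6 sentences (2 targets per set) with dual parses
  over shared tokens, position labels and simple word-timing metadata.
  Tokens come from small recycled vocabularies; there is no claim of
  lexical realism.
- **Embeddings**: depths are planted exactly as `||B₀h||²` (plus optional
  Gaussian depth noise and a free null-space component). The scheduled
  depth blends the active and passive context-free depths with a
  per-sentence preference (high-transitivity targets 0.6–0.9 toward
  passive, low-transitivity 0.1–0.4) and resolves to the passive parse at
  the main verb — reproducing the qualitative garden-path signature
  (Verb1 depth rising toward 2) and distributed within-condition
  trajectories. Real contextual embeddings are not linear-exact, so
  passing probe tests show correctness of the estimator, not of any claim
  about real language models.
- **Counts**: a latent per-sentence DO probability (Beta, moment-matched
  to condition means 0.71 ± 0.16 and 0.44 ± 0.19) drives both corpus
  tallies and continuation counts, giving the condition gap in
  log-transitivity and the transitivity–DO-probability correlation the
  analysis assumes. Real corpus counts have heavier tails and
  frequency-dependent reliability, which is not modelled.
- **Epochs**: spatially correlated Gaussian noise (exponential covariance,
  15 mm length scale, temporally white) plus planted signals whose
  across-sentence geometry matches a target RDM via classical MDS
  (rank ≤ 10) mapped onto random orthonormal spatiotemporal patterns,
  scaled by effect size (default 2, i.e. planted per-cell signal SD twice
  the noise SD). Real E/MEG noise is temporally structured and the
  leadfield mixes sources; recovery results on synthetic epochs therefore
  demonstrate the inference machinery, not expected real-data power.
- Overlapping effects with different target RDMs are rejected rather than
  averaged.

All generators are deterministic under their seed; determinism is asserted
by identity of regenerated objects.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make the suite a few
minutes on one CPU while keeping the statistics meaningful: family-wise
error calibration uses 200 null data sets (12 participants, 50-vertex
mesh, 500 sign-flip permutations); planted-effect recovery uses 20 data
sets (60 sentences, 30 vertices, 12 participants, 300 permutations);
Granger direction specificity uses 20 simulations of 1200 samples with 120
surrogates. Full-scale runs (120 sentences, 5000 permutations, 1000
surrogates, rank search to 50) use the same code paths with the defaults
documented above.

## Known limitations

- No real-data ingestion beyond the documented text/array formats: E/MEG
  preprocessing, source inversion and forward modelling are out of scope.
- Spatial distances are Euclidean in source coordinates, not geodesic.
- The multivariate normalization estimates one covariance per searchlight
  from trial-mean-removed residuals; epoch-wise noise estimators are not
  implemented.
- Variance partitioning (partial-correlation RSA) between competing model
  RDMs is not implemented.
- The GPD tail refinement uses a fixed 10% exceedance fraction; no
  goodness-of-fit gate beyond maximum-likelihood convergence.
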