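---
title: "Comparing and combining reduced amino-acid alphabets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and combining reduced amino-acid alphabets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redalph)
```

## The problem

A *reduced* (simplified) amino-acid alphabet partitions the 20 standard
amino acids into groups of residues considered mutually similar. Dozens of
such alphabets have been published, derived from very different kinds of
evidence: substitution patterns in sequence alignments, structural
alignments, protein-block statistics, inter-residue contact potentials, and
the physico-chemistry of the isolated amino-acid molecules. Because each
study optimizes for its own task, the alphabets disagree in detail, and two
natural questions arise:

1. How similar are any two published alphabets to each other?
2. Does the *consensus* of many alphabets converge on a coherent global
   picture of amino-acid similarity, and does that picture agree with plain
   physico-chemistry?

`redalph` implements a matrix framework for both questions.

## The model

**Binary intra-group (B.I.G) matrices.** An alphabet is encoded as a 20 x 20
symmetric 0/1 matrix over the fixed letter order `ACDEFGHIKLMNPQRSTVWY`:
cell $(i, j)$ is 1 exactly when letters $i$ and $j$ share a group. The
diagonal (does a letter group with itself?) carries no information, so all
statistics run over the $20 \times 20 - 20 = 380$ off-diagonal cells.

**Alphabet similarity.** For two alphabets $A, B$ with B.I.G matrices
$M^A, M^B$,
$$ s(A, B) \;=\; \frac{1}{380} \sum_{i \ne j} \mathbb{1}\!\left[ M^A_{ij} = M^B_{ij} \right] , $$
a value in $[0, 1]$ (1 = identical partitions). Counting is exact integer
arithmetic; division by 380 happens once at the end, so every similarity is
an exact multiple of $1/380$ (matrix output is rendered at 4 decimal
places). The all-against-all matrix of a collection feeds both a dendrogram
of alphabets and a principal-components view of "alphabet space".

**Consensus.** Summing the B.I.G matrices of $n$ alphabets cellwise and
dividing by $n$ gives the consensus similarity matrix: each cell is the
fraction of studies grouping that pair. Its unit complement $1 - s$ is the
consensus *distance* matrix (0 = always grouped, 1 = never grouped).

**Dendrograms.** Distance matrices are turned into unrooted trees by
neighbor joining followed by ordinary-least-squares (OLS) branch-length
refinement on the fixed NJ topology. The trees express similarity, not
ancestry, so no rooting or outgroup logic exists anywhere; rooted
equal-rates methods such as UPGMA are deliberately not offered because
their assumptions are incoherent for this data type. Amino acids that are
rarely grouped with anything sit on long pendant branches without special
casing.

**Stability.** `jackknife_consensus()` drops one alphabet at a time,
rebuilds the consensus tree from the remaining $n-1$, and scores it against
the full tree with the branch score distance (square root of the sum of
squared per-split branch-length differences, an absent split counting as
length 0). A `squared` flag selects the no-root variant, since both
conventions circulate; the report records which one was used.

**Agreement of two views.** The distance between two 20 x 20 distance
matrices is the mean absolute cellwise difference over the 380 informative
positions. Its significance is assessed with a conservative Mantel-style
null: only the *row order* of one matrix is permuted (permuting rows and
columns together would destroy the within-row structure that both matrices
share by construction and so inflate apparent agreement). `n` uniform row
permutations are drawn with replacement from the $20! \approx 2.4 \times
10^{18}$ orderings, and the empirical p-value uses the add-one estimator
$(1 + \#\{d_{null} \le d_{obs}\})/(n + 1)$, which is never exactly 0.

## Worked example

```{r example}
col <- bundled_collection()
col

cm <- category_distance_matrices(col)
matrix_distance(cm$protein, cm$chemistry)

rt <- randomization_test(cm$chemistry, cm$protein, n = 20000, seed = 1)
rt

pca <- alphabet_pca(build_similarity_matrix(col))
pca

agglomerate_alphabet(build_consensus(col), 6)
```

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `n` (null replicates) | `randomization_test()`, pipeline | 100,000 | the batch size at which disjoint-seed null means agree to ~1e-3; 1,000,000 is reachable via `--n` for full-scale runs |
| `seed` | everywhere stochastic | required | all randomness flows from one seed through named per-stage substreams |
| `squared` | branch score distance | `FALSE` (square root) | both conventions exist in the literature; the square-root form is the one cross-checked against an independent implementation |
| `k` | `agglomerate_alphabet()` | — | cut level of the consensus hierarchy; any size 1–20 |
| `noise`, `n` | `generate_planted_collection()` | — | per-letter corruption probability and collection size for synthetic ground truth |

## The synthetic-data generator

`generate_random_alphabet()` draws a random partition with exactly `k`
non-empty groups: one random anchor letter seeds each group (so no group
can be empty) and every remaining letter is assigned uniformly. A pure
rejection sampler ("draw uniform labels, retry until all k appear") defines
the same idea but has acceptance probability $20!/20^{20} \approx 2 \times
10^{-8}$ at $k = 20$, so the surjective-by-construction draw is used
instead; it preserves the forced outcomes (k = 20 gives the singleton
partition, k = 1 the single group) and seed determinism.

`generate_planted_collection()` emulates a literature of studies measuring
the *same* underlying similarity structure with independent errors: each of
`n` copies of a base partition has each letter independently reassigned to
a uniformly chosen existing group with probability `noise`. What this
emulates well: independent, unbiased per-study error around a shared truth,
which is exactly the regime where consensus recovery can be tested against
ground truth. What it does not emulate: systematic biases shared by a
derivation method, correlated errors between studies by the same group,
heterogeneous alphabet sizes, or the real (unknown) generative process
behind published alphabets. Passing the planted-recovery tests therefore
demonstrates correctness of the machinery, not that real literatures are
this well behaved.

## The bundled 34-alphabet collection

`bundled_collection()` loads 34 reduced alphabets (29 derived from residues
within protein sequences/structures, 5 from individual amino-acid
physico-chemistry) spanning the five derivation categories. The grouping
strings are a *synthetic best-effort reconstruction* of the cited studies,
assembled from the literature rather than transcribed verbatim from any one
published table, and the file says so in its header. Quantities computed
from it are therefore faithful to the collection actually shipped, but can
differ from values printed for the original published compilation; the
reconstruction is somewhat more internally consistent than the original
literature appears to be (its alphabet space is closer to two-dimensional,
and its two category matrices are built from blockier partitions), which
shifts the headline matrix distance, the PCA variance split and the
randomization null accordingly.

## Numerical choices

- **Diagonal convention.** Similarity matrices store 1 on the diagonal,
  distance matrices 0, purely for display; no statistic ever reads the
  diagonal. After row permutation the randomized matrix is generally
  asymmetric and informative values land on diagonal grid positions; these
  remain excluded so every distance, observed or null, is a mean over the
  same 380 positions.
- **Normalization by 380.** The matrix distance divides the summed absolute
  difference by the 380 informative cells, i.e. it is a per-cell mean, and
  the same denominator is used for observed and null values.
- **NJ tie-break.** When several pairs minimize the Q-criterion (ties are
  exact for e.g. an all-equal distance matrix), the pair whose sorted
  representative labels are lexicographically smallest is merged; a merged
  cluster is represented by the smallest label it contains. This makes
  every tree, and hence every downstream artifact, byte-deterministic.
- **Negative OLS branch lengths** are permitted and reported; the branch
  score distance always uses raw fitted lengths.
  `clamp_negative_branches()` exists for display only.
- **OLS solve.** Branch lengths minimize the sum of squared differences
  between tree path lengths and input distances, solved by QR on the
  edge–path incidence system; a rank check guards the (theoretically
  impossible for binary trees) singular case.
- **PCA preprocessing.** Rows of the similarity matrix are the
  observations; columns are mean-centered, never variance-scaled, and the
  covariance is eigendecomposed (`stats::prcomp`). Centering follows from
  the requirement that the score cloud be mean-zero; the similarity (not
  distance) matrix is the input. A zero-variance input (all rows identical)
  is reported distinctly via `total_variance = 0` rather than as arbitrary
  fractions.
- **Exact rationals.** Alphabet similarities and consensus cells are ratios
  of integer counts; all comparisons in the test suite exploit this
  (e.g. every off-diagonal consensus cell times `n_sources` must round-trip
  to an integer).

## Problem sizes used in the test suite

The shipped tests run the full 34-alphabet analysis, 100,000-replicate
randomization batches (twice, with disjoint seeds, for the stability
check), 50 random additive matrices of 5–12 leaves for the NJ+OLS oracle,
and 100 planted collections of 20 alphabets at noise 0.1 for consensus
recovery. These sizes were chosen so the whole suite exercises every
code path at full statistical scale for the 20-letter problem while
completing in minutes on a single core.

## Known limitations

- The bundled collection is a reconstruction, not a transcription; see
  above.
- Consensus weighting is uniform across studies (as in the framework the
  package implements); there is no graded within-alphabet similarity.
- No topology search under least squares: the NJ topology is kept and only
  branch lengths are re-fit.
- The randomization test implements the cellwise-distance statistic only,
  not the classical Mantel correlation.
- Only the 20 standard amino acids are accepted; selenocysteine and
  pyrrolysine are out of scope by design.
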