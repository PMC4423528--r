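---
title: "Aligning enzymatic step sequences: model, objective and algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning enzymatic step sequences: model, objective and algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(essalign)
```

## The scientific problem

Metabolic maps describe which enzymatic reactions a pathway comprises and
which compounds connect them. Two pathways can perform related chemistry
while sharing few or no identical enzymes, because evolution frequently
*recruits* an enzyme of the same broad catalytic class rather than
duplicating an exact one. Comparing pathways therefore calls for a
representation that (a) linearizes the branching reaction graph into
comparable units and (b) measures enzyme similarity hierarchically rather
than as identity.

`essalign` implements this program. A metabolic map is modelled as a
directed graph of enzymes (edges record a compound produced by one enzyme
and consumed by another). Each map is decomposed into **enzymatic step
sequences (ESS)**: ordered lists of enzymes along root-to-leaf branches of a
breadth-first-search tree. Enzymes are represented by the first three levels
of their EC number (`class.subclass.sub-subclass`), so two kinases that
differ only at the fourth (substrate-specific) level look identical, and two
transferases of different subclasses look partially similar. ESS are then
aligned — in pairs by a genetic algorithm, in groups progressively — under
an entropy-based objective, and whole collections are compared, tested for
significance against shuffled sequences, and clustered.

## From KGML to sequences

`parse_kgml()` reads a KGML document: enzyme-type entries become graph
nodes, reaction elements supply substrates, products and reversibility, and
`maplink` relations mark compounds arriving from another map. A node is an
**initialization node** (BFS root) when

1. none of its substrates is produced by another enzyme of the map, or
2. at least one substrate is externally supplied *and* the node has at most
   two neighbors.

Each root generates one ESS per leaf of its BFS tree. Children are enqueued
in ascending node-id order, making the trees deterministic; exact duplicate
sequences (same map, root and steps) are collapsed.

```{r extract}
spec <- fixture_spec(n_maps = 2L, motif = c("5.3.1", "2.7.1"), seed = 1L)
maps <- generate_maps(spec)
coll <- bind_ess(lapply(maps, extract_ess))
ess_statistics(coll)
```

## The alignment objective

An alignment of $S$ sequences is a character matrix whose cells are EC codes
or gaps; columns that are entirely gaps are removed before scoring. The
objective — **minimized**, lower is better — is

$$\mathrm{O.F.} = 0.9\,H + 0.05\,GC + 0.05\,CI$$

with three ingredients:

* **Homogeneity** $H$: the mean over columns of
  $0.6\,E + 0.4\,\mathrm{Gaps}/(S-1)$, where $E$ is a weighted sum of
  normalized Shannon entropies of the three EC levels,
  $E = (15E_1 + 10E_2 + 5E_3)/30$. A gap counts as one extra symbol in the
  entropy; entropies are normalized by $\log_2 S$ (an alternative
  normalization by the number of distinct symbols is available via
  `scoring_control(entropy_norm = "symbols")`). The level weights make a
  first-level mismatch three times as expensive as a third-level one,
  encoding the biological intuition that recruiting an enzyme of a different
  EC class is a bigger step than fine-tuning substrate specificity.
* **Gap concentration** $GC$: mean internal gap-block length divided by the
  total number of internal gap positions; leading and trailing gaps are
  excluded, and $GC = 0$ when there are no internal gaps.
* **Column increment** $CI$: length of the longest unaligned sequence
  divided by the alignment width.

Reference values used throughout the tests: an identical gapless pair scores
exactly $0.05$ (only the $CI$ term survives), a fully distinct ungapped pair
of equal length scores $0.59$, and the column `[2.7.1, 2.7.2]` has EC
entropy $1/6$.

```{r hand}
objective(new_alignment(rbind(c("2.7.1", "1.1.1"),
                              c("2.7.1", "1.1.1"))))
column_ec_entropy(c("2.7.1", "2.7.2"))
```

**A note on the gap terms.** Read literally, the $GC$ formula equals
$1/\#\text{blocks}$: under minimization it *favors splitting* gaps into many
blocks, and $CI$ *favors wider* alignments, which is the opposite of the
stated intent of concentrating gaps and penalizing added columns. The
package implements the printed formulas as the default and exposes
`scoring_control(gap_concentration_mode = "inverted",
column_increment_mode = "inverted")` for the intent-matching variants. With
the 0.05 weights the choice rarely changes which alignment is optimal.

## The genetic algorithm

A candidate alignment is encoded as one binary mask per sequence over the
alignment columns (1 = enzyme, 0 = gap); decoding a mask against its
sequence reproduces the row, so EC content is invariant under every
operator. Defaults (`ga_params()`): population 100, crossover rate 0.9,
tournament selection of size 2, elitism, stop after 20 generations without
improvement, 10 independent replicates keeping the best result.

* **Initialization** draws widths uniformly on
  $[L_{\max}, L_{\max} + \text{extra}]$ and scatters each row's gaps
  uniformly; the trivially padded stack of the sequences is seeded into
  every population, so the result can never be worse than naive stacking.
  The default gap budget `extra = max(2, ceiling(Lmax/2))` is a package
  choice: optimal pairwise alignments under this objective rarely use more
  gaps than half the longest sequence, and the budget only affects the
  starting widths (mutation can grow alignments further).
* **Crossover** cuts the first parent at a column; the second parent is cut,
  row by row, just after it has consumed the same number of enzymes, and the
  recombined sides are padded with gap columns to stay rectangular.
  Self-crossover reproduces the parents exactly.
* **Mutation** picks a uniform (row, position): a gap is extended or removed
  with equal probability, and an enzyme position gets a gap inserted before
  it. The protocol is stated ambiguously in the source method ("1% mutation
  rate" vs "an individual will be mutated each generation"); the default
  policy applies one event per individual per generation
  (`mutation_policy = "per_individual"`), and
  `"per_position"` draws a Binomial(rows × columns, 0.01) number of events.
* All randomness flows from `ga_params(seed=)`; replicate $r$ uses sub-seed
  `seed + r`, and `ga_align()` canonically orders its inputs so that
  aligning (A, B) and (B, A) gives the same objective.

Two independent oracles guard the GA. `brute_force_align()` enumerates
*every* gap placement of two short sequences (exact because an alignment
without all-gap columns has at most $l_a + l_b$ columns) and is the global
optimum the acceptance tests compare against. `dp_align()` is a
Needleman–Wunsch minimization with substitution cost $0.6$ × two-sequence
column entropy and gap cost 1; it optimizes an additive surrogate, not the
full objective, so it is used as a consistency check (rank correlation with
the GA), not as ground truth.

```{r ga}
a <- ga_align(list(A = c("2.7.1", "1.1.1", "5.3.1", "4.1.2"),
                   B = c("2.7.1", "1.1.2", "5.3.1")),
              ga_params(seed = 1L))
a
a$score
```

## Collections: significance, clustering, depuration

`all_vs_all()` computes the symmetric matrix of best pairwise objectives
(optionally cached to a TSV so long runs are resumable). Significance is
assessed against shuffled collections: `shuffle_ess()` pools all EC tokens,
permutes them, and redistributes them into the original lengths, conserving
both the global composition and the length vector. The score threshold is
`mean - 3*sd` of the real scores (`significance_threshold()`); the analysis
of the original study used the cutoff 0.4, which the examples here adopt.

Clustering uses k-medoids directly on the fitness matrix: alternating
assignment/medoid-update restarted from `replicates` random medoid sets,
keeping the lowest total within-cluster dissimilarity. This in-package
implementation (rather than `cluster::pam`) mirrors the best-of-random-
restarts protocol and keeps every tie-break deterministic; a unit test
cross-checks partitions against `pam` on separable data. `elbow_select()`
scans $k$ and picks the maximal discrete second difference of the quality
curve, reporting all peaks. `depurate()` then removes members whose mean
fitness to their cluster-mates exceeds the cutoff — by default in a single
pass against the original membership, which makes the operation idempotent
(`cascade = TRUE` re-evaluates to a fixpoint instead).

```{r cluster}
blocks <- generate_ess_blocks(3, 4, 6, divergence = 0.1, seed = 1L,
                              n_outliers = 2L)
sim <- all_vs_all(blocks$collection, ga_params(seed = 1L))
el <- elbow_select(sim, k_min = 2L, k_max = 8L, seed = 1L)
el
model <- depurate(kmedoids(sim, k = el$k, seed = 1L), sim, cutoff = 0.4)
model
```

The injected outliers are half-length random sequences, which guarantees
their alignments against planted members are dominated by forced gap
columns (objective ≥ 0.5; see the fixtures section). Two resolutions are
then available, and the example shows the first: the elbow sees the
outliers as a small cluster of their own (`k = 4`), or clustering at the
planted `k = 3` lets `depurate()` remove them from whichever cluster they
join.

```{r cluster-depurate}
depurate(kmedoids(sim, k = 3L, seed = 1L), sim, cutoff = 0.4)
```

## Progressive multiple alignment

Within a cluster, sequences are aligned progressively. The guide order
starts with the most similar pair and appends the member with the lowest
mean fitness to the already-placed set. The first two sequences are aligned
with the pairwise GA; each later sequence is aligned against the existing
rows as a *frozen block*: the GA may insert whole gap columns into the block
and gaps into the new row, but the block's internal gap pattern never
changes ("once a gap, always a gap"). The full objective is evaluated over
all rows at every step, and the trivially padded solution is seeded, so each
extension is at least as good as stacking.

```{r msa}
members <- blocks$truth$ess_id[blocks$truth$cluster %in% 1]
m <- progressive_msa(blocks$collection, members, sim = sim,
                     params = ga_params(seed = 1L))
m
conserved_columns(m, min_identity = 0.8)
```

## Synthetic fixtures and their limits

No public accession reproduces the original KGML inputs, so the package
generates its own: random branching reaction graphs with a planted
contiguous enzyme motif, optional reversible reactions, external substrates,
and a guaranteed initialization node (`generate_maps()`), serialized as a
minimal KGML dialect (entries + reactions + maplink relations, no graphics)
that round-trips through `parse_kgml()`. For clustering experiments,
`generate_ess_blocks()` plants clusters around templates that differ in
first-level EC *class* at every position where the alphabet allows —
class distinctness, not mere code distinctness, is what guarantees a high
between-template score under the 15:10:5 level weights — diverging members
at a controlled fraction of positions; half of the substitutions change only
the third EC level, exercising the graded entropy weights. Injected outliers
are uniform random sequences of half the cluster length: a length mismatch
of $L - l$ forces at least that many maximal-cost single-gap columns into
any pairwise alignment, bounding the objective at $\ge 0.5$ for $l = L/2$
regardless of EC content, whereas *same-length* random sequences score
$\approx 0.4$–$0.46$ against anything — right at the conventional 0.4
membership cutoff — and are therefore not reliably separable outliers at
all. These fixtures make no claim
of biological realism (no degree-distribution modelling, no compound
reuse across maps); they exist to give every pipeline stage a ground truth.

The test suite and `scripts/acceptance.R` run the pipeline at desk scale —
3-code alphabets and lengths ≤ 4 where an exhaustive oracle is feasible,
3 × 6 planted clusters of length 6 for recovery experiments, 100-pair
DP-vs-GA comparisons — sizes chosen so the entire suite finishes in minutes
on one CPU while still exercising every contract.
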