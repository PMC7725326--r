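---
title: "Reconstructing pathway gain and loss across pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pathway gain and loss across pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtrace)
```

## The model

A metabolic pathway is treated as a set of *n* enzymes. For each enzyme
*i* and target genome *j*, the homology matrix holds the number `h_ij` of
distinct genes of genome *j* detected as homologues of enzyme *i* (BLAST
tabular input, e-value cutoff). The pathway's **fuzzy profile** is the
enzyme-wise mean

```
f_j = (1/n) * sum_i h_ij ,
```

an unbounded non-negative score: 0 means no member enzyme has any
homologue; values around 1 mean, on average, one homologue per enzyme;
larger values reflect duplication. Averaging is what buys robustness: a
spurious hit or a missed gene moves `f_j` by only `1/n`.

The fuzzy profile is binarized at a threshold `α` (presence iff
`f_j ≥ α`, inclusive). Discrete leaf states are then propagated to all
ancestors of a rooted phylogeny in a single bottom-up pass, with rules

* **R1** — children with a uniform assigned state pass it to the parent;
* **R2** — else the parent is PRESENT when `P − A > gain` *and* at least
  two child subtrees contain presence;
* **R3** — else the parent is ABSENT when `A − P > loss`;
* **R4** — else the subtree majority decides, ties going to ABSENT.

`P` and `A` tally present/absent leaves of the parent's subtree
(`mode = "leaf"`, default) or maximal uniformly-present/absent clades
(`mode = "event"`, a Dollo-flavoured reading in which each maximal clade
is one potential gain or loss). Both readings are provided because the
level at which "potential gains and losses" should be counted is a genuine
design choice; leaf counting is the default as the less aggressive of the
two. Gains and losses are reported on edges where the assigned state
changes; by construction a gain edge always runs absent → present and a
loss edge present → absent.

Assumptions worth keeping in mind: the tree is an input, taken as correct
and purely topological (branch lengths are ignored); homologue counts are
treated as presence evidence without orthology resolution; and the same
`α` applies to every pathway and genome of a run.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `evalue_cutoff` | `1e-6` | similarity-search acceptance threshold; hits above it are ignored |
| `alpha` | data-driven | presence threshold on fuzzy values (dimensionless, on the scale of homologues-per-enzyme) |
| `gain` | 5 | excess of presence over absence tallies required by R2 |
| `loss` | 2 | excess of absence over presence tallies required by R3 |
| `mode` | `"leaf"` | tally unit for R2–R4: subtree leaves or maximal clades |
| `aggregate` | `"max"` | pangenome column rule: max approximates searching the non-redundant union of strain proteomes; `sum` double-counts shared orthologues, `mean` dilutes strain-specific genes |

When `alpha` is not supplied, `default_alpha()` uses the grand mean of all
pathway × genome fuzzy values of the run. "Average over all genomes" could
also be read as the mean of per-genome column means; on a complete grid
the two coincide, and the `method` switch documents the distinction rather
than hiding it. The automatic value is deliberately crude — a single
threshold across taxa of very different evolutionary depth is the method's
main simplification, and `run_pipeline()` therefore logs the α actually
used in its manifest.

`α` is sensitive to the evolutionary span of the target set: closely
related genomes need a stricter threshold to expose their differences,
distant ones a permissive threshold. An all-zero fuzzy grid yields α = 0,
which `discretize_profile()` rejects, forcing an explicit choice.

## Behaviour of the rule cascade

Two properties of the completion chosen for R4 deserve explicit
statement, because both matter for interpreting results.

**The thresholds are inert under majority fallback.** R2 can only assert
presence where `P − A > gain ≥ 0`, i.e. where the majority rule would
assert presence anyway; R3 can only assert absence where `A − P > loss ≥
0`, again agreeing with the majority (ties are absent). R1 agrees with the
subtree majority by induction: a child assigned PRESENT always carries a
strict present-majority in its own subtree. Consequently the assignment
equals the subtree (or clade-count) strict majority for *every* setting of
`gain` and `loss`: the reconstruction is maximally insensitive to the two
thresholds. The rule cascade is still evaluated as stated — the parameters
are part of the method's interface and the `mode` switch changes results —
but users should not expect threshold sweeps to alter a fit. The practical
upshot of composite profiles is different and real: averaging over
enzymes makes the *leaf states themselves* far more stable under count
noise than any single-enzyme profile, which is demonstrable by
discretizing noisy ensembles (see the generator below). An alternative R4
(e.g. defaulting to absence whenever neither threshold is met) would make
the thresholds bite, but it contradicts the behaviour fixed by this
package's reference cases — a dominant present clade with a small absent
sibling must keep the root present even though the two-subtree condition
blocks R2 — so the majority completion was kept.

**Leaf-gain monotonicity holds for leaf counting only.** Flipping any
single leaf from absent to present can never flip a node from PRESENT to
ABSENT in `mode = "leaf"` (every subtree's `P − A` moves by +2). In
`mode = "event"` the same flip can *merge* three or more maximal present
clades into one, lowering the clade tally and legitimately flipping an
ancestor to absent; the event mode is therefore not monotone, which is a
property of clade counting, not a defect.

**Ties go to absence.** Absence is the harder claim biologically, but the
convention is visible in small balanced cases: two present leaves against
two absent leaves reconstruct an absent root with a gain into the present
clade, not a present root with a loss.

## The synthetic generator

`ensemble_spec()` fixes the study conditions: pangenome blocks of strains
arranged as clades on a caterpillar spine (strain clades polytomous by
default, balanced-bifurcating with `balanced = TRUE`), per-(pathway,
block) planted presence, and integer counts. Where a pathway is planted
present, a cell is `1 + Poisson(lambda_present − 1)` — mean exactly
`lambda_present` (default 2, matching the small counts, roughly 0–14, seen
in real enzyme-vs-genome matrices), support ≥ 1 so that a genome truly
encoding an enzyme always shows at least one homologue — then zeroed with
probability `dropout`. Where absent, a cell is 1 with probability
`epsilon`. In the noise-free limit the discretized profiles equal the
planted states exactly at `α = 0.5`, which is what makes planted-history
recovery a sharp test. `plant_event()` composes explicit histories: it
flips a clade, regenerates the affected cells deterministically, and
records the expected single event on the clade's parent edge.

The generator emulates block structure, planted clade-level histories and
count noise. It does **not** emulate horizontal transfer (events are
clade-consistent by construction), paralogous gene-family structure,
correlated noise between related strains, genome-size variation, or any
sequence-level process — so green tests certify the inference machinery on
clean block-structured inputs, not performance on real, messier matrices.

**Identifiability of planted events.** A bottom-up local-majority scheme
polarizes a single event on the edge above clade *C* only when the leaves
outside *C* form a strict majority of every ancestral subtree. On a
caterpillar of equal-size blocks the two deepest blocks violate this at
their first spine ancestor (a tie, which resolves to absent), and the
event is then smeared across two edges even without noise.
`recoverable_clades()` returns the clades satisfying the condition;
recovery experiments plant events there, and the limitation is inherited
by any analysis of clades that dominate their neighbourhood of the tree.

## Target-set diagnostics

Candidate target ensembles are scored on binarized cells (count > 0):
**entropy**, the normalized Shannon entropy of the present-cell fraction
(0 for homogeneous matrices, 1 at half presence); and **segmentation**,
one minus the normalized entropy of the distribution of adjacent-column
Hamming distances — 1 when all variation concentrates on a single column
boundary, 0 when it spreads evenly. Conventions: a matrix with no
column-to-column variation at all scores segmentation 1 (one perfect
segment; 0 would also be defensible, so the choice is documented), and a
two-column matrix with any variation scores 1 (a point mass is the only
possible gradient distribution). Columns must be ordered
block-contiguously for segmentation to be meaningful; `homology_matrix()`
orders them by block, then genome ID.

These two estimators are this package's own operationalization of
"contrast" and "alignment of variation with block boundaries"; no
published formula exists for them, so only their qualitative behaviour is
asserted and tested: scattered single genomes give high entropy and low
segmentation, a lone pangenome gives a homogeneous low-contrast matrix,
and block-structured layouts score strictly higher segmentation than the
same cells with shuffled columns in essentially all seeded replicates.
Absolute segmentation values shrink on wide matrices with scattered noise
(the gradient distribution gains many small atoms); comparisons should be
made at fixed shape, as the shuffle test does.

## Numerical and interface choices

* Duplicate (query, subject) hit rows collapse to the best e-value, so
  genes are counted, not alignments; self-hits count like any other hit,
  letting source genomes act as positive controls.
* Missing pathway enzymes are an error rather than zero-filled rows: the
  profile denominator is the declared pathway size, and silent omission
  would bias `f_j` invisibly.
* The discretization boundary is inclusive (`f_j = α` is presence).
* A pangenome's virtual leaf attaches at the root of its strains' clade;
  for a single-strain block it attaches to that strain's parent. A name
  collision with an existing leaf is an error, never a rename.
* BioPAX annotation is idempotent by replacement: at most one
  presence/absence comment per element, matching
  `^\$\$custom comment\$\$:(present|absent)$` exactly, datatype fixed to
  the XML-Schema string type. Stripping annotations restores a document
  canonically equal to the input.
* Sequences for protein references without an embedded sequence resolve
  from a local FASTA only; the package performs no network access.

## Problem sizes used in the test suite

The suite exercises: oracle equivalence against an independent naive
recursion on 1000 random trees of up to 12 leaves over the full
`{0..8}²` threshold grid and both modes; exhaustive leaf-gain
monotonicity over all `2^L` assignments for random trees with `L` = 6, 8
and 10; planted-event recovery on 100 noise-free five-block ensembles of
four strains each; threshold-grid constancy on 100 noisy
(`epsilon = dropout = 0.05`) ensembles; and segmentation ordering on 200
blocked-versus-shuffled pairs. These sizes were chosen to make the
properties sharp while keeping a full run under a minute; all scale
linearly if enlarged.

## Known limitations

* One global `α` per run; taxon-specific thresholds are only available as
  per-run overrides, although deep target sets would benefit from them.
* Presence/absence is binary — partially present pathways (a real and
  common situation) are visible in the fuzzy profiles but collapse at
  discretization.
* The reconstruction is a single bottom-up pass with no top-down
  smoothing, no probabilistic model, and no horizontal-transfer
  detection; an event on an edge is a parsimony statement, not a dated or
  mechanistic one.
* The gain/loss thresholds do not alter fits under the majority
  completion (see above); sensitivity analyses should vary `α`, the
  aggregation rule and `mode` instead.
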