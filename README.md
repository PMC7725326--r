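# pathtrace

Parsimony reconstruction of metabolic pathway evolution across pangenome
ensembles.

## The problem

Given sequenced genomes for a set of species and strains, which metabolic
pathways were present in their ancestors, and on which branches of the
phylogeny were pathways gained or lost? Gene-level ancestral-content
methods answer this one gene at a time and are sensitive to noise in
homology detection. `pathtrace` works at the level of whole pathways: the
signal of all member enzymes is pooled into one composite profile per
pathway, which is then reconstructed on the tree. Pangenomes — the union of
gene content over all strains of a taxon — enter both as extra "virtual
genome" columns of the data matrix and as extra leaves of the tree,
stabilizing presence calls against strain-level gene loss.

The package is aimed at comparative genomicists who have (i) similarity
search results (BLAST tabular output) of pathway enzymes against a
collection of target genomes, (ii) a map of genes to genomes and genomes to
pangenome blocks, (iii) pathway definitions (a TSV, or BioPAX Level 3
documents), and (iv) a rooted species/strain tree in Newick format.

## The method

1. **Homology matrix.** `h_ij` is the number of distinct genes of genome
   *j* hit by enzyme *i* with e-value ≤ 10⁻⁶ (`count_homologues()`).
   Pangenome columns aggregate member strains, by default with the
   cell-wise maximum (`aggregate_pangenome()`).
2. **Fuzzy pathway profile.** For a pathway with *n* enzymes,
   `f_j = (Σᵢ h_ij) / n` — the mean homologue count over member enzymes, an
   unbounded likelihood-of-presence score per genome
   (`fuzzy_profile()`).
3. **Discretization.** `d_j = 1` iff `f_j ≥ α` (inclusive boundary,
   `discretize_profile()`). When not supplied, α defaults to the average
   fuzzy value over all pathways and genomes (`default_alpha()`).
4. **Ancestral reconstruction.** A single bottom-up pass assigns
   PRESENT/ABSENT to every internal node (`pathtrace()`): uniform children
   propagate their state (R1); otherwise presence is assigned when the
   present-minus-absent tally exceeds the GAIN threshold and presence
   occurs in ≥ 2 child subtrees (R2), absence when the absent-minus-present
   tally exceeds LOSS (R3), and the subtree majority otherwise, ties to
   absent (R4). Tallies count subtree leaves (default) or maximal uniform
   clades (`mode = "event"`). Gain/loss events are the edges where the
   assigned state changes.
5. **Output.** States and events as TSV/JSON, and optionally one annotated
   BioPAX document per tree node, with presence flagged by the structured
   comment `$$custom comment$$:present` / `…:absent`
   (`annotate_states()`).

Target-set quality is quantified by `assess_target_set()`: the normalized
entropy of binarized cells (contrast) and a gradient-entropy segmentation
score that is 1 when all column-to-column variation sits on a single
boundary. Good target ensembles — several pangenomes rather than one, or a
scatter of unrelated genomes — show high contrast with variation aligned to
block boundaries.

A seeded generator (`ensemble_spec()`, `generate_ensemble()`,
`plant_event()`) produces block-structured synthetic ensembles with planted
gain/loss histories for testing and calibration.

## Worked example

Simulate four pangenome blocks of three strains, two pathways (6 and 9
enzymes), plant a loss of pathway `P1` in block `B3`, and run the chain:

```r
library(pathtrace)
spec <- ensemble_spec(n_blocks = 4, strains_per_block = rep(3, 4),
                      n_pathways = 2, enzymes_per_pathway = c(6, 9),
                      seed = 101)
ens  <- generate_ensemble(spec)
ens  <- plant_event(ens, "P1", "B3", "loss")
mat  <- aggregate_pangenome(ens$matrix, ens$blocks)
tree <- attach_pangenome_leaves(ens$tree, ens$blocks)
fz   <- fuzzy_profile_matrix(mat, ens$pathways)
fits <- pathtrace_all(tree, discretize_profile(fz, 0.5))
fits$P1
#> Parsimony pathway reconstruction for 'P1'
#>   tree: 16 leaves, 7 internal nodes (mode = leaf, gain = 5, loss = 2)
#>   root state: PRESENT
#>   events: 0 gain(s), 1 loss(es)
#>     LOSS on edge S2 -> B3
summarize_history(fits)
#>    pathway root_state gains losses gain_clades loss_clades
#> P1      P1    PRESENT     0      1                      B3
#> P2      P2    PRESENT     0      0
assess_target_set(ens$matrix)
#> target-set metrics (15 enzymes x 12 genomes, 4 blocks)
#>   entropy (contrast):        0.469
#>   segmentation (gradient):   0.711
```

The reconstruction reports `P1` as present at the root with exactly one
loss on the edge into the `B3` clade — the planted history — while `P2` is
present everywhere with no events. The same run is available end-to-end
through `run_pipeline()`, which also writes all intermediates plus a
manifest recording the parameters and the α actually used.

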