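---
title: "Inferring whole genome duplications from gene family phylogenies"
author: "wgdtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring whole genome duplications from gene family phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdtrace)
```

## The inference problem

Whole genome duplications (WGDs) double every gene in a genome; most
duplicates are subsequently lost again ("fractionation"), but a multi-member
gene family that retains many of its duplicates leaves a readable trace:
after a WGD, *many subtypes of the family duplicate on the same species-tree
branch at once*. A single duplicated gene, by contrast, is more plausibly a
single-gene or small-region duplication — especially when the two copies sit
in tandem on the chromosome. wgdtrace turns this argument into a pipeline:

1. **Reconcile** each rooted binary gene tree against a rooted species tree
   by last-common-ancestor (LCA) mapping. Every gene-tree node is mapped to
   the LCA (in the species tree) of its descendant species; a node whose
   mapping equals a child's mapping is a duplication. This mapping attains
   the minimum duplication count over all ancestor-consistent mappings,
   which the test suite verifies exhaustively against a brute-force dynamic
   program for every gene-tree shape on up to six leaves over three species.
2. **Place** each duplication on the species-tree branch *above* the mapped
   node: an LCA-mapped duplication precedes the radiation of the mapped
   clade and postdates the split from its sister, so the event happened "at
   the origin of" that clade.
3. **Classify** each family's copy pattern per branch: `ONE_TO_TWO` (one
   duplication node, two co-orthologs), `TRIPLET` (two duplication nodes,
   three copies, in either `(a,(b,c))` or `((a,b),c)` arrangement),
   `ONE_TO_TWO_TO_FOUR` (three duplication nodes in the balanced
   `((a,b),(c,d))` nest), or `OTHER`.
4. **Call** events per branch from the number of independently co-duplicated
   families and the pattern-class majority (below).
5. **Name** orthologs and paralogs, score exon–intron structure congruence,
   and classify sequence completeness as supporting evidence.

Losses are deliberately *not* reconstructed: the calling logic never uses
loss counts, only copy patterns and cross-family coincidence, so no
loss-parsimony machinery is needed.

## Calling rules and their parameters

`callEvents()` applies, per species-tree branch carrying duplications:

* `|families| < kMin` → `SINGLE_GENE_DUP`. The default `kMin = 3` is the
  smallest count that the converse argument ("only one or two duplicated
  families") excludes; it is exposed in `callConfig()` because the field
  threshold is a judgment call, not a measured constant.
* Otherwise, if no multi-copy pattern is present, or `ONE_TO_TWO` patterns
  outnumber all multi-copy patterns combined → `WGD`.
* Otherwise the multi-copy majority decides: more balanced
  one-to-two-to-four nests than triplets → `TWO_WGD` (two successive WGDs on
  the same branch); more triplets → `WGT` (a triplication); a tie →
  `AMBIGUOUS`. Ties are reported, not forced: distinguishing two nested
  WGDs from a hexaploidy on the same branch is exactly the case that
  additional genome data must settle.

Tandem paralog pairs (same scaffold, at most `tandemMaxGap = 1` intervening
gene) are flagged as corroborating single-gene-duplication evidence; tandem
flags never override the co-duplication count.

## Ortholog/paralog nomenclature

Duplications on internal (multi-species) branches open *numbered* ortholog
groups; duplications on terminal branches append *lowercase letters* within
the species. A family with four groups of which a species duplicated groups
2 and 4 therefore yields `11B1, 11B2a, 11B2b, 11B3, 11B4a, 11B4b` for that
species. Because no published numbering rule exists, groups are numbered in
canonical tree order — subtrees sorted by their lexicographically smallest
leaf label, then left to right — which makes names invariant under input
rotation and file order; an *anchor table* (`anchors =` in `assignNames()`)
pins specific published numbers when reproducing an existing nomenclature.
For the two ancestral class VIII branches, `assignClass8Series()` letters
A-branch homologs A, C, E, G, … and B-branch homologs B, D, F, H, …, so
subtype membership stays visible in the name.

## Gene-structure evidence

`parseGeneModel()` reduces CDS features to intron descriptors: the coding
offset *n* (coding nucleotides preceding the intron) and phase *p = n* mod 3.
The anchor convention is the residue containing coding nucleotide *n*+1,
i.e. alignment column of residue `floor(n/3) + 1`; phase-0 introns thus sit
naturally between residues. Congruence between two sequences is the Jaccard
index of their (column, phase) sets, with empty vs empty scoring 1; an
intron shared in position but differing in phase counts as *different* (the
stricter reading). A discriminating intron must be present in every member
of one subtype and absent from every member of the other. Patterns render
as one hyphen per residue column, a space per gap column, and a pipe before
each intron anchor, so homologous introns align vertically across rows.

Completeness: with observed length `L_obs` and expected length `L_exp`
(default: mean of designated complete sequences of the subtype), the missing
fraction `m = max(0, 1 - L_obs/L_exp)` classifies a sequence as complete
(`m = 0`), partial (`0 < m <= 0.05`, still usable for tree estimation) or
fragment (`m > 0.05`, inventory evidence only). The threshold comparison
carries a `1e-9` tolerance so integer cases landing exactly on 5% (e.g.
1482 of 1560 residues) classify as partial regardless of floating-point
rounding direction.

## What the simulator emulates

`simulateFamily()` evolves one gene lineage down the species tree. Along
each branch, every copy independently experiences exponential-waiting-time
single-gene duplication (`lambdaDup`) and loss (`lambdaLoss`), both per copy
per unit branch length. At a placed event, a WGD doubles each surviving copy
independently with retention probability `r`; a WGT adds two extra copies,
each retained independently with probability `r`. Per-copy (rather than
all-or-nothing) retention matches the patchy post-WGD survival seen in real
inventories, and it is what generates triplets from two nested WGDs when
one of four copies is lost. Event positions default to the branch midpoint
so that background losses can act both before and after the event. Each
(seed, family index) pair seeds its own RNG stream, making every family
individually reproducible and the whole dataset byte-identical across
re-runs. A retained WGT is emitted as two gene-tree nodes at the same point
(gene trees stay binary), which is precisely the unnested triplet pattern
the caller looks for.

The simulator emulates topology only: no sequences, no substitution model,
no branch-length realism, no gene conversion, and no distinction between
allo- and autopolyploidy. Passing the validation scenarios therefore shows
that the *inference logic* recovers what the *assumed generative process*
produced; it does not validate the generative assumptions themselves
against real genomes (rate heterogeneity, assembly artefacts and tree
estimation error are all outside the model).

## Validation scenarios and problem sizes

The package validates itself at sizes chosen to keep the full suite around
a minute while leaving no statistical doubt:

* **Oracle equivalence** — all 2,052 rooted binary gene-tree shapes on up to
  6 leaves over 3 species, against an independent brute-force minimum.
* **Congruent null** — 100 random species trees (4–12 taxa); congruent
  families must yield zero duplications and zero calls.
* **WGD placement** — 100 replicates of one WGD (r = 0.9) on an 8-species
  tree with background `lambdaLoss = 0.1` and `lambdaDup = 0.01`
  (single-gene duplications are rare in suitable marker families, but a
  nonzero rate keeps the false-positive check honest), 20 families,
  `kMin = 3`.
* **WGT vs two nested WGDs** — 100 replicates each at retention 0.9 with no
  background rates: the discrimination rests purely on fractionation
  patterns (see limitations).
* **Ancient subtypes** — three nested WGDs (r = 0.7, positions 0.2/0.5/0.8
  of the pre-divergence branch, background `lambdaLoss = 0.02`): the
  five-subtype `(((A,H),(C,E)),G)` pattern arises by fractionation alone
  with probability 2r⁴(1−r)² ≈ 0.044 per family, so a 100-seed scan finds
  it essentially always, and reconciliation places all its duplications on
  pre-divergence branches.
* **Structure fixture** — two groups of three gene models sharing all
  introns except one group-A tail intron: exactly one discriminating intron,
  within-group congruence exactly 1.

`scripts/acceptance.R` re-runs all of these from scratch against the
installed package and writes the measured quantities as JSON.

## Numerical and degenerate-input choices

* Polytomies are accepted in species trees but rejected in gene trees by
  default (`resolvePolytomies = TRUE` resolves left-to-right with a
  message): silent resolution would hide real uncertainty.
* Branch lengths are carried but never required; all inference is
  topological. Simulation requires lengths and defaults absent ones to 1.
* A family reduced to a single surviving gene reconciles trivially (its
  unary pass-through root is no event); an extinct family is an empty tree
  flagged `extinct`, not an error.
* Unlabelled internal species-tree nodes receive stable `N<id>` labels so
  branches are nameable in configurations and reports.
* Multiple independent duplication clusters of one family on the same
  branch classify as `OTHER`: they are evidence of duplication but of no
  specific genome-scale pattern.

## Known limitations

* **Loss blurs the triplet/nest distinction.** Losing one of the four
  copies of a one-to-two-to-four nest leaves a triplet, so under heavy
  post-event loss the `WGT` vs `TWO_WGD` majority vote degrades toward
  `AMBIGUOUS` and, eventually, the wrong verdict (at `lambdaLoss = 0.1` on
  the validation tree, roughly half the nested-WGD families lose at least
  one copy). The verdict should be read together with the reported pattern
  counts, not as a point estimate.
* Duplications whose descendants survive only in a subclade map below the
  true branch (the classic LCA-mapping bias); cross-family aggregation
  absorbs occasional misplacements but cannot correct a systematic one.
* Fragment placement is taken as user input (a fragment-to-subtype table);
  the package never re-estimates trees.
* No Ks distributions, synteny, or absolute dating: the pipeline times
  events only relative to speciations.
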