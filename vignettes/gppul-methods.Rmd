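---
title: "Methods: locus detection, pan-genome partitioning and carbohydrate utilization ecotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus detection, pan-genome partitioning and carbohydrate utilization ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gppulr)
```

## The problem

Butyrate-producing Firmicutes of the *Roseburia*/*Eubacterium rectale*
group ferment dietary fibre in the human colon, but - unlike the
well-studied *Bacteroides* - they lack Sus-type outer-membrane starch
utilization systems. Their carbohydrate-active genes are instead
organized into Gram-positive polysaccharide utilization loci (gpPULs):
gene clusters that couple degradative enzymes (glycoside hydrolases, GH;
carbohydrate esterases, CE; polysaccharide lyases, PL) to a carbohydrate
transport system (mostly ABC transporters, with GPH symporters, MFS and
PTS in smaller numbers) and a transcriptional regulator (typically
LacI- or AraC-family). gppulr implements the full inference chain that
turns annotated genomes into locus calls and strain-level carbohydrate
utilization ecotypes (CUEs), and ships generators and fixtures so every
stage is testable at desk scale without sequence databases.

## CAZyme calling from dual evidence

Two independent evidence streams identify CAZymes, each with explicit
filters:

* **HMM domain hits** (dbCAN-style `hmmscan` output): keep a hit when its
  E-value is at most 1e-3 for alignments shorter than 80 aa, at most
  1e-5 for alignments of 80 aa or more, and the HMM coverage exceeds 0.3
  (strictly).
* **Protein-search hits** against a GH reference annotated with EC
  3.2.1.- numbers (blastp-style 12-column output): keep a hit when its
  E-value is at most 1e-10, identity is at least 35% and bit score at
  least 200.

A gene with any accepted hit becomes a CAZyme call; HMM hits supply the
family (CBM families are recorded separately as binding modules), the
protein search supplies EC annotations. Where only an EC 3.2.1.-
annotation exists, the gene is classed GH without a family. Boundary
semantics are a deliberate choice: the published thresholds are phrased
as exclusions ("exclude E values > ..."), so we keep hits sitting exactly
on an E-value/identity/bit-score boundary and require coverage to exceed
0.3 strictly; all cutoffs are configurable through `filter_thresholds()`.
When HMM and protein-search evidence disagree, the HMM family is
preferred for carbohydrate-set assignment and the EC is retained
alongside - both are reported, neither is discarded.

## Carbohydrate sets

Counting genes by GH family is too coarse for substrate prediction
because several families are polyspecific. The package therefore uses a
two-tier map (`default_carb_set_map()`, editable YAML in
`inst/extdata/carb_sets.yaml`):

1. families whose members attack one substrate class map directly
   (e.g. GH13 to alpha-glucans, GH32 to fructans, GH43/GH51 to xylans
   and arabinans, GH28 to pectins, GH113/GH130 to beta-mannans,
   GH20/GH29/GH38/GH85/GH125 to host glycans);
2. heterogeneous families (GH1, GH2, GH3, GH5, GH25, GH42, GH76, CE1,
   CE2, CE3, CE12, ...) are deliberately unmapped at family level and
   resolve only through per-gene EC annotations.

Endo-1,4-beta-galactanases (GH53, EC 3.2.1.89) cleave the 1,4-beta-galactan
backbone of type-1 arabinogalactan, a substrate that could plausibly be
filed under xylans/arabinans, pectins or galactosides; they are assigned
exclusively to a dedicated "Type-1 Arabinogalactans" set and barred from
those three. This override is per-gene: other members of the same locus
keep their own sets.

## Pan-genome partitioning by bidirectional best hit

Orthologous groups (OGs) are built from cross-strain protein similarity
at fixed thresholds: identity >= 45% over >= 50% of the query, E-value
< 1e-5, bit score > 50, minimum group size two. For each ordered strain
pair the best hit per query is chosen by bit score (ties broken by
higher identity, then lexicographic subject id, for determinism); an
edge requires reciprocity; OGs are connected components of the edge
graph, so a group may span strains linked transitively. Genes in no
component are unique singletons. With the total strain count n, an OG
present in all n strains is core, in 2..n-1 variable, and singletons are
unique - an exhaustive, exclusive partition.

Choices made where the procedure was underdetermined: the thresholds are
applied *before* best-hit selection (configurable in principle via the
similarity table supplied); "50% of sequence" is read as query coverage;
within-strain (paralogue) records never contribute edges; the
quartet-tree refinement step of the original orthology tool is not
reproduced - the printed thresholds define a plain BBH procedure, which
is what the package implements and documents as an approximation.

`compute_similarities()` serves desk-scale inputs: global
(Needleman-Wunsch) alignments under a transparent +2/-1 substitution
matrix with affine gaps (open 10, extend 0.5), reporting identity as
matches over alignment length and coverage as query residues aligned
opposite subject residues. Because no search engine is run, the E-value
is a Karlin-Altschul-style surrogate (`m * n * 2^-score`) and the bit
score is the raw alignment score; both exist so the published threshold
set is exercisable end-to-end on synthetic proteins. Real similarity
tables in the same six-column layout can be supplied instead.

## Locus detection

Detection walks gene *ranks* - 0-based order along each contig, assigned
by ascending start coordinate with (start, end, gene_id) tie-breaks -
so gene distance is a count of intervening genes, strand-agnostic
(published locus drawings mix strands freely). The scanner has three
stages, with two integer parameters (`detection_params()`):

1. **Seeding.** Transporter systems are maximal rank-contiguous runs of
   transporter-component genes, split where the component family
   (ABC/GPH/MFS/PTS) changes; a lone component is a system of size one.
   A GH gene fewer than 11 genes from the nearest member of a system
   (strict `<`; a switch makes it `<=`) seeds a candidate locus.
2. **Extension.** Boundaries are runs of three adjacent genes with no
   carbohydrate-related annotation. Each contig is segmented at every
   such run, and segments are trimmed to start and end on
   carbohydrate-related genes; extending any seed gene-by-gene stops at
   exactly those boundaries, so overlapping seed extensions merge by
   construction (merge-then-validate - published multi-enzyme loci with
   two ABC systems imply this order). Runs of up to two hypothetical
   genes are tolerated inside a locus; three non-carbohydrate genes
   always terminate it.
3. **Validation.** A locus is emitted only with all three minimum
   components: a polysaccharide-degrading enzyme (GH/CE/PL - accessory
   carbohydrate-metabolism genes such as xylose isomerase count as
   carbohydrate-related for boundary purposes but cannot fill this
   slot), a transporter system, and a transcriptional regulator whose
   family is in the recognised vocabulary (LacI, AraC, TetR, NagC, AsrR,
   MCST, histidine kinases and response regulators; a two-component
   HK + RR pair counts once). Regulator genes with families outside the
   vocabulary are treated as non-carbohydrate genes throughout.

Substrate prediction unions the carbohydrate sets of a locus's member
enzymes. Because "reasonable confidence" is a judgement call, the
confidence flag is an explicit, configurable rule: confident iff the
union spans at most two distinct sets and at least half the member
enzymes received an assignment; the raw union is always reported
alongside. Cross-strain comparison calls two loci orthologous when at
least half of the smaller locus's genes share OGs with the other locus
(the overlap fraction is reported next to every call), and locus
families are components of that orthology graph.

## Ecotype clustering

Strain-by-GH-family or strain-by-set count matrices feed a Kendall
tau-b distance, `d = 1 - tau` (range 0..2; tau against a constant
profile is undefined and mapped to the neutral distance 1 with a
warning). Complete-linkage hierarchical clustering defines the CUEs; the
tree is cut at a requested `k`, or - when `k` is not given - at the
largest gap between consecutive merge heights, a reproducible stand-in
for cutting a heatmap by eye. Group significance is a PERMANOVA on the
same distance (999 permutations). The permutation stream uses a fixed
default seed (42) so the p-value is reproducible; note that any
permutation mapping each cluster onto itself reproduces the observed
F-statistic exactly, so with random streams the minimum p of 1/1000 is
occasionally missed through such ties - a property of the test, not of
the data.

PCoA is classical scaling: double-centre the squared distances and
eigendecompose; the first five axes are returned and negative
eigenvalues (expected, since 1 - tau is non-Euclidean) are reported
uncorrected. The published ordination phrase ("distances of the first
five eigenvectors") is ambiguous; we ordinate the distance matrix and
report five axes, which is the standard reading.

Per-ecotype enrichment uses a one-sided rank-sum comparison of in-group
versus out-of-group counts, with the p-value computed by exact
enumeration of all in-group subsets whenever feasible (always, at 11
strains) - the published analysis names no test for its enrichment
p-values, so an exact nonparametric choice is the least-assumption
concretization. Raw p-values are reported; apply `p.adjust()` for
multiplicity.

## Synthetic data and fixtures

The generator (`generate_genome()`) plants loci drawn from the published
locus-composition templates into a 200-gene background, each flanked by
at least three non-carbohydrate genes, with two kinds of decoy that must
never be called: a lone GH at least 11 genes from any transporter
component, and a GH-plus-transporter cluster lacking a regulator.
Internal locus order is randomized under two constraints (the locus
starts and ends on carbohydrate-related genes; every GH is within
seeding distance of a transporter component), so recall and precision of
1.0 on planted loci is a *contract* of the generator, and the test suite
enforces it across 100 seeds. Mock evidence rows pass the published
filters for every planted enzyme; a configurable fraction of background
genes receives deliberately failing rows. With
`include_enzyme_labels = FALSE` the enzyme labels are withheld so the
full pipeline - filters, calling, back-annotation, detection - must
recover the planted loci from raw evidence.

`fixture_table2()` encodes the ten confidently-predicted loci of
*R. intestinalis* XB6B4 and the four of *E. rectale* A1-86 exactly as
printed (dual-family entries become one gene with two family labels; the
one esterase entry printed with a qualifier letter is encoded as CE1).
Where the source drawings do not fix internal gene order, a fixed layout
(enzymes split around the first transporter system) is used and is
arbitrary by documentation; detection is insensitive to it. Pseudogenes
(e.g. a frameshifted transporter permease) are ordinary genes with a
`pseudo` flag, which the concordance report uses for attribution.
`fixture_growth_matrix()` transcribes the growth phenotypes of the ten
assayed strains over 14 substrates as booleans, resolving the one
garbled statement ("was not unable to grow") toward the surrounding
text's clear meaning.

Ecotype matrices are generated with 11 strains in planted groups of
4/3/2/2 (mirroring three species-level clusters plus one mixed pair),
a +5 count shift on each group's four signature columns over a baseline
of 2, and independent integer jitter of +/-1. Sixteen columns, all of
them group signatures, reflect that real carbohydrate-set profiles
differ between ecotypes across most sets; with signature columns sparse
among many noise columns, tied baseline pairs dominate the Kendall pair
counts and recovery of the planted partition is no longer guaranteed -
the generator's defaults are chosen so that planted structure is always
recoverable, which the suite verifies (adjusted Rand index 1.0 across
100 seeds).

What the synthetic data does *not* emulate: realistic nucleotide or
amino-acid composition, codon structure, contig fragmentation, gene
length variation, annotation error in the label table, and the
database-dependent breadth of real CAZyme complements. Passing the suite
therefore demonstrates algorithmic correctness at the stated conditions,
not expected performance on raw genome annotations, whose headline
counts depend on external databases and the deposited assemblies.

## Numerical and degenerate-input choices

* Overlapping genes keep distinct ranks via the (start, end, gene_id)
  sort, so ranking is deterministic.
* Filter idempotence and subset monotonicity are asserted properties.
* Best-hit and tie-break rules make BBH output invariant to the order of
  strains and of similarity records.
* `kendall_distance()` returns exact zeros on the diagonal; merge
  heights of the complete-linkage tree are non-decreasing by
  construction and asserted in tests.
* An all-zero distance matrix ordinates to all-zero coordinates; `k`
  larger than the strain count is an error; a single-cluster assignment
  has undefined (NA) significance.
* Problem sizes used by the shipped tests and scripts - 200-gene
  genomes, 100 detection seeds, 11 x 16 ecotype matrices, 1000-replicate
  null calibration at 199 permutations, 50-gene alignment fixtures - are
  the package's chosen desk-scale study conditions; all are plain
  function arguments.

## Known limitations

* BBH components approximate the original quartet-refined orthology;
  very divergent paralogues can chain groups together transitively.
* The shipped carbohydrate-set map covers the families and ECs needed
  for the encoded loci plus the canonical one-substrate families; other
  families are unassigned until the user extends the YAML.
* Substrate confidence is a heuristic rule, not a probability.
* The alignment-based similarity route is quadratic and intended for
  fixtures; real pan-genomes should supply precomputed similarity
  tables.
* Growth phenotypes are booleans transcribed from text, not OD curves,
  so concordance reports are qualitative.
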