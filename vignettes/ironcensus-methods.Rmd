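---
title: "Methods: censusing iron-oxidation and EET machinery in genome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censusing iron-oxidation and EET machinery in genome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironcensus)
```

## The problem

Neutrophilic iron-oxidizing bacteria (FeOB) move electrons from extracellular
Fe(II) across the outer membrane using c-type cytochromes: the fused
monoheme cytochrome-porin iron oxidase Cyc2, porin-decaheme complexes of the
Mto/Mtr family, and larger porin-multiheme-cytochrome conduits such as PCC3
and Uet. Because every c-type cytochrome binds heme covalently at a
CXXCH-family motif (CXXCH, CX3CH or CX4CH: a cysteine pair plus the
iron-ligating histidine), a motif census over a proteome is a cheap,
annotation-free detector of candidate cytochromes, and a comparison against
a non-iron-oxidizing sister group (nitrite oxidizers, NOB) highlights
machinery specific to the iron-oxidizing lifestyle.

`ironcensus` implements that comparative workflow as a reusable, fully
tested pipeline: heme-motif census, bidirectional-coverage clustering of
motif-bearing proteins, reference-based cluster classification,
synteny-based porin-cytochrome complex calling, metabolic marker profiling
with per-group prevalence summaries, genome similarity metrics (AAI, ANI,
16S identity), and a concatenated ribosomal-protein phylogeny. A
synthetic-cohort generator with planted truth makes every stage testable
without downloads.

## Motif scanning

`scan_protein()` reports non-overlapping motif hits. Anchor positions must
be literal `C`/`H`; wildcard positions accept any alphabetic residue
(ambiguity codes included); `*` never matches and no motif may span one
(internal stops split the scan). Overlapping candidates are resolved
greedily: leftmost start wins, the shortest span wins at equal start, and
scanning resumes past the selected motif. The rationale is biochemical —
two heme attachments cannot share a cysteine — and the policy is symmetric
across the three motif classes (no class is globally preferred). The
`overlap = "allow"` mode reports every candidate instead, for users who want
the un-collapsed census. The test suite holds the scanner to an independent
brute-force enumerate-then-select oracle on tens of thousands of random
sequences.

Default category bins for per-protein totals are 1, 2, 3, 4–9 and 10+ hemes;
the multiheme (MHC) flag defaults to ≥ 3 total hemes. Both are arguments,
since the interesting families span 1 to 35 hemes.

## Clustering and classification

Motif-bearing proteins are clustered from an all-vs-all local alignment
graph (BLOSUM62, affine gaps 11/1). An edge requires the aligned region to
cover at least 80% of *both* sequences (bidirectional coverage) plus a 30%
identity floor; setting `min_id = 0` recovers a pure-coverage mode. Two
exact-or-conservative prefilters keep the quadratic stage tractable: pairs
whose length ratio is below `min_cov` cannot satisfy coverage on the longer
sequence and are skipped exactly; pairs sharing fewer than 2% of distinct
4-mers are skipped heuristically (`prefilter = 0` disables this). The
4-mer screen can drop genuinely homologous pairs below roughly 30% identity;
at the divergences this package targets (≤ 15% per site) shared 4-mer
fractions are an order of magnitude above the threshold.

Clusters are built by greedy set-cover: the unassigned protein with the most
unassigned neighbours (ties: longer sequence, then lexicographic id) becomes
a centroid and absorbs its unassigned neighbours. The output is always a
partition and all tie-breaks are total orders, so the clustering is
deterministic. This is a deliberate, contract-equivalent stand-in for
cascaded large-scale clusterers: at cohort scale the stated contract —
bidirectional 80% coverage — is implemented exactly rather than
approximately.

Classification mirrors curatorial practice: a cluster containing a reference
("isolate") sequence takes its label directly; otherwise members are
searched against the labelled catalog (35% identity, 70% coverage) and the
majority label among qualifying members wins, with ties reported as
`ambiguous` and no qualifying hits as `unclassified`. Pangenome bins follow
the usual prevalence rules: strain-specific (one genome), near-core
(> 85% of genomes, strict), accessory otherwise.

## Complex calling from synteny

Porin-cytochrome complexes are called per genome from two signals: homology
of proteins to subunit-role references (with heme-count checks for
cytochrome roles — e.g. exactly 1 for Cyc2, exactly 10 for MtoA, ≥ 20 for
the periplasmic PCC3 cytochrome, 10–35 for the extracellular one) and gene
colocalization. The anchor is the complex's first required cytochrome role;
a complex is `complete` when every required role has a hit on the same
contig within `window` gene ranks of an anchor hit (default 15 — wide
enough to span the largest shipped architecture, the nine-gene Uet locus,
with margin). A duplicated variant role (the periplasmic PCC3 cytochrome)
upgrades the verdict to `complete-variant`; at least one but not all
required roles gives `partial`; none gives `absent`. Where several windows
qualify, the smallest rank span and then the lowest anchor rank is chosen,
making calls deterministic. Strand is recorded but not used: the
architectures the caller ships define colocalization, not orientation, and
imposing an orientation rule would be an assumption the evidence does not
support.

Shipped definitions cover Cyc2, the MtoAB core (MtoC/MtoD/CymA/MtrC
optional), PCC3, Uet (UetC porin optional — the architecture is observed
both with and without it) and the Slit-type periplasmic cluster (cytochrome
b + monoheme + diheme cytochromes required, hypothetical protein and
chaperone optional). All definitions are plain R structures and can be
edited or extended.

## Marker profiling

Metabolic markers (nitrite oxidation, respiration, denitrification, sulfur
oxidation, hydrogenases, carbon fixation/utilization, nitrogen fixation,
stalk formation, manganese oxidation) are detected by homology to catalog
references at 30% identity / 70% coverage, replacing external HMM engines
so the package is download-free; thresholds are arguments. A multi-subunit
marker is present when the fraction of subunits with a qualifying hit
reaches its rule (default 1.0, i.e. all subunits; the five-gene sox operon
uses 0.8). cyc2 and mtoA additionally carry their heme constraints.
Manganese-oxidase hits are flagged low-confidence: sequence similarity alone
is weak evidence for that function. Group summaries report
100 × (genomes in group with marker) / (group size), plus derived flags
(both/either iron-oxidation gene; denitrification to N2O).

## Genome similarity

AAI is the mean percent identity over reciprocal best protein hits
(candidate hits are screened by shared k-mers, the top candidates aligned,
and reciprocal pairs at ≥ 30% identity / 70% coverage retained). ANI is the
gene-based analogue over nucleotide best hits at ≥ 70% identity, with
rRNA/tRNA-tagged records excluded by default because their strong
conservation inflates the estimate. Both follow the published semantics of
the reciprocal-best-hit AAI and gene-based ANI tools rather than
whole-genome fragmentation schemes, which matters at cohort scale: each
unordered pair is aligned once with a canonical query choice, so matrices
are exactly symmetric and self-comparisons are exactly 100. Pairs with
fewer than 10 reciprocal hits carry a low-support flag, and no genus
thresholds are imposed — there are no well-supported AAI/ANI cut-offs for
genus delineation. 16S identity uses overlap (free-end-gap) alignment and is
only evaluated for sequences of at least 1,450 nt.

## Phylogeny

The tree is built from 13 ribosomal proteins (L19, L20, L28, L17, L9_C,
S16, L21p, L27, L35p, S11, S20p, S6, S9); markers present in fewer than
89.5% of genomes are dropped. Each marker is aligned with the package's
progressive aligner — 3-mer distances, a UPGMA guide tree, and
profile-profile global alignment with affine gaps (Gotoh recursion) —
processed in canonical name order so the result is input-order invariant.
No general-purpose MSA engine is a dependency; for the short, conserved,
nearly indel-free ribosomal markers the progressive profile aligner is
sufficient and keeps alignment deterministic and in-process.

Columns with gap fraction strictly above 0.70 are masked; the usual manual
end-trimming is automated by trimming end columns while their gap fraction
exceeds 0.5 (configurable, `NA` disables). Blocks are concatenated in fixed
marker order with absent genomes padded by gaps. Distances ignore columns
gapped in either row and take the Poisson correction d = −ln(1 − p)
(saturated pairs are capped at d = 10 with a warning); the tree is
neighbor-joining, with bootstrap support from seeded column resampling
mapped to edges by bipartition matching. NJ is exact on additive matrices,
which the tests exploit. Maximum-likelihood inference is deliberately out of
scope: the package's acceptance surface is clade recovery on synthetic
cohorts, not likelihoods, and NJ with bootstraps is transparent,
deterministic and fast at cohort scale. Trees are emitted unrooted; an
optional outgroup argument re-roots.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` draws a four-clade cohort — three FeOB-like groups
(Gallionella/Sideroxydans/Ferriphaselus analogs) and one NOB-like group
(Nitrotoga analog) — with:

* core and ribosomal gene families evolved hierarchically along the group
  tree (default group branches 0.06/0.05/0.08/0.12 with a 0.03 internal
  branch joining the two most closely related FeOB groups; within-group
  branches 0.02 per site);
* complexes placed per group at prevalences echoing the observed
  distributions (cyc2 0.83 in FeOB groups and absent in NOB; Mto 0.41;
  PCC3 biased to the Sideroxydans analog at 0.59; Uet exclusive to the
  Gallionella analog; the Slit cluster at 0.57; nxrAB at 0.85 in the NOB
  group only) and planted as adjacent genes, with 15% partial loci, 10% of
  placed PCC3 carrying a duplicated periplasmic cytochrome, and the UetC
  porin present in two thirds of Uet loci;
* a generic MHC family palette with heme counts 1, 2, 3, 4, 10, 11, 21, 27
  and 35 (NOB genomes draw only families below 10 hemes, echoing the
  observation that only FeOB encode ≥ 10-motif proteins);
* a planted FeOB:NOB ratio of motif-bearing protein counts (default 1.5,
  NOB mean 16): the number of generic MHC genes per genome is Poisson with
  a budget adjusted by the analytic expectation of complex-contributed
  motif proteins, so the configured ratio holds in expectation.

Two constructions make planted truth *exact* rather than expected:
background residues are drawn from an 18-letter alphabet excluding C and H,
and mutations never touch motif anchor residues, so a protein's heme count
is exactly its planted count and the scanner can be held to zero-error
recovery. Amino-acid substitution is uniform over non-identical background
residues; nucleotide genes are reverse-translated with a fixed codon table
(a separate divergence-ladder generator mutates nucleotides directly for
ANI calibration).

What the generator does **not** emulate — and hence what green tests do not
certify about real data: indels and domain rearrangements, horizontal
transfer and recombination, compositional bias (real proteomes contain
cysteines and histidines outside heme motifs, so real censuses include
borderline single-motif proteins the simulator never produces), genuinely
remote homology near the 30% identity floor, contamination and fragmented
assemblies, and rate heterogeneity across sites. The pipeline's thresholds
are exposed precisely so users can tighten or relax them against real
cohorts.

## Numerical choices and degenerate inputs

* Quality filter: retain at completeness ≥ 80 and contamination ≤ 7 —
  boundary values are retained because removal is defined by strict
  inequalities ("lower than" / "greater than").
* Identity is matches over aligned columns; coverage is the aligned span
  over each full sequence length; each unordered pair is aligned once
  (canonical query order) so symmetry is exact, not approximate.
* Zero reciprocal best hits yields an `NA` metric with a zero count, not an
  error; empty cohorts, empty motif sets and single-sequence alignments all
  return well-formed empty or trivial results.
* Saturated Poisson distances cap at 10 with a warning; masking uses strict
  `>` at the 0.70 boundary; unsorted bin edges are an error.
* All randomness (simulation, bootstrap) flows through explicit integer
  seeds; reruns are byte-identical, which the tests assert on the written
  artifacts.

## Problem sizes used by the test and acceptance runs

The shipped checks run cohorts of 3–20 genomes per group (proteomes of
roughly 90 genes), a 10,000-sequence scanner-oracle comparison, 200-gene
divergence ladders, and 100–200 bootstrap replicates — sizes chosen so the
whole suite exercises every stage end-to-end on one CPU in minutes while
keeping sampling tolerances (3 standard errors, pre-computed by repeat
simulation) meaningfully tight.

## Known limitations

Homology search is reference-based, so roles without a reasonably close
catalog entry are invisible — by design, this package ships a synthetic
catalog for testing and expects users with real cohorts to supply real
reference sequences in its place. The greedy clusterer is quadratic and
intended for motif-bearing subsets (thousands of proteins), not whole
pangenomes. Subcellular localization, structure prediction, HMM-based
annotation and maximum-likelihood phylogenetics are out of scope.
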