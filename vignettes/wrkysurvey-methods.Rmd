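---
title: "Methods and design notes for wrkysurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for wrkysurvey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkysurvey)
```

This vignette explains the models and procedures the package implements, the
parameters that matter, the numerical conventions, and what the synthetic
data does and does not emulate. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Domain identification and family classification

WRKY proteins are recognised by two motifs: a heptapeptide (canonically
`WRKYGQK`) and a downstream zinc finger. Identification here is fully
deterministic pattern matching rather than a profile-HMM search: the variant
set is small and discrete, exact matching makes every call reproducible and
testable against an exhaustive-window oracle, and no external binary is
needed. A config placeholder (`evalue_threshold`, default 1e-5) marks where
an optional HMM pre-screen would sit in a larger workflow; it is not used by
the scan itself.

Conventions and defaults:

* **Heptapeptide set** (`default_heptapeptides()`): `WRKYGQK` plus the
  variants `WRKYGKK`, `WRKYGEK`, `WKKYEDK` and `WKKYCEDK`. `WKKYCEDK` is
  treated literally as an eight-residue variant (the slashed notation
  sometimes used for it, `WKKY/CEDK`, denotes the same 8-mer). The set is a
  plain config vector so users can add rarer forms (`WSKY…`, `WVKY…`)
  without code changes.
* **Zinc-finger spacings**: C2H2 is `C x{4,5} C x{22,23} H x H`; C2HC is
  `C x7 C x23 H x C`. The finger search opens immediately after a
  heptapeptide and the first Cys must fall within `finger_search_window`
  residues (default 60, matching the canonical ~60-residue domain span).
  The leftmost first-Cys match wins; at the same Cys, smaller spacings are
  preferred and C2H2 beats C2HC on an exact tie, so results are unique.
* **Groups**: two complete C2H2 domains give group 1; one complete C2H2
  gives group 2; one complete C2HC gives group 3; anything else (no
  heptapeptide, no classifiable finger, unusual multi-domain architectures)
  is reported ungrouped with an explanatory note. This mirrors family
  surveys in which a small number of members — typically those with the
  `WKKYCEDK`-type heptapeptide and no canonical finger — stay outside the
  three groups. N- versus C-terminal finger sub-spacings of group-1 proteins
  (Cx4Cx22 vs Cx4Cx23) are recorded in the notes but deliberately not used
  for grouping.
* **"Full-length" filtering**: published surveys typically narrow
  non-redundant hits to full-length proteins without stating the criterion.
  The package's stand-in is `require_complete_domain`: a survivor must carry
  at least one complete heptapeptide + finger domain. Exact duplicate
  sequences collapse to the lexicographically smallest id.

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da). The isoelectric point uses a Bjellqvist-style pKa set (the one
common to pI web calculators), shipped as an editable table, and solves the
Henderson–Hasselbalch net-charge equation by bisection to |charge| < 1e-4.
The net charge is continuous and strictly decreasing in pH, so bisection on
[0, 14] always converges; a 0.001-pH grid scan serves as the independent
oracle in tests.

## Gene clusters and genome context

The cluster rule is the one standard in plant TF-family surveys: two
neighbouring family genes belong to one cluster when they are less than
200 kb apart and separated by no more than eight non-family genes; clusters
are maximal runs of at least two. Three points the rule's prose leaves open
are fixed as follows, and recorded in the survey metadata:

* **Distance** is the end-to-start intergenic gap (`next.start − prev.end −
  1`), not midpoint-to-midpoint — "separated by" reads most naturally as the
  gap between the genes.
* **Bounds**: "< 200 kb" is strict; "no more than eight" is inclusive.
* **Intervening genes** are those whose spans lie fully between the two
  family genes; genes overlapping either family gene do not count.

`detect_clusters()` refuses unsorted input rather than silently sorting, and
its output is checked against a brute-force pairwise-link plus
connected-components oracle on random layouts, along with a monotonicity
property (tightening either rule parameter never adds clustered genes).
GFF3 parsing goes through rtracklayer; multi-isoform genes keep the mRNA
with the most exonic bases.

## Promoter cis-elements

Promoters are the 1,500 bp upstream of the translational start (first CDS
base), reverse-complemented for minus-strand genes and truncated with a
warning at contig edges. Scanning is exact degenerate matching of IUPAC
consensus strings on both strands — the behaviour of the standard plant CARE
databases — with no mismatch tolerance. The dictionary ships as an editable
TSV (name, consensus, category over seven groups: essential, enhancer,
light, tissue, abiotic, hormone, other); variable-length elements are
represented by a canonical core, noted per entry. Correctness is defined
against the shipped file: the upstream literature names elements without
printing their sequences. Per-gene summaries count **distinct element
types** per category (an element present twice counts once), with raw
instance counts exposed alongside, since survey prose lists which elements a
promoter "contains".

## Ka/Ks and dating

The package estimates Ka (nonsynonymous substitutions per nonsynonymous
site) and Ks (synonymous per synonymous site) by Nei–Gojobori (1986)
counting with Jukes–Cantor correction, on codons threaded through a global
protein alignment. A maximum-likelihood codon model would add an external
dependency and fitting machinery out of proportion to this artifact; NG86 is
closed-form, transparent, and its accuracy is measured directly by
parameter-recovery simulations (planted rates recovered within 10% at 500
codons). The estimator name is recorded in the output metadata. Note the
letter assignment: Ka = nonsynonymous, Ks = synonymous — a known source of
prose errata in the survey literature.

Conventions:

* Synonymous site fractions are averaged over the two sequences; changes
  that create stop codons count as nonsynonymous, which keeps the identity
  S + N = 3 × (ungapped codon columns) exact.
* Codons differing at k positions average their difference counts over all
  k! minimal pathways, excluding pathways through stop codons; if every
  pathway is blocked, each position change is classified in isolation.
* p ≥ 3/4 sets a saturation flag instead of producing an estimate; Ks = 0
  flags the Ka/Ks ratio undefined rather than dividing by zero.
* Alignment: Needleman–Wunsch with BLOSUM62 and affine gaps (a gap of
  length L costs 10 + 0.5·(L−1)); traceback prefers diagonal over up over
  left, so alignments are unique. Scores are verified against an exhaustive
  alignment-enumeration oracle on short strings.

Dating uses T = Ks/(2λ) with λ = 6.1 × 10⁻⁹ substitutions per synonymous
site per year, the rate conventionally used for the common bean–soybean
split. At Ks between 0.2 and 0.3 this formula gives 16.4–24.6 Myr; published
figures of 16.1–24.2 Myr for that Ks window cannot be reproduced exactly
from the formula because the Ks endpoints actually used are not recoverable,
so the package treats only the formula itself as checkable.

## Phylogeny

Distances are p-distances with pairwise deletion (gap-containing columns
skipped per pair), mirroring the defaults of the classic NJ workflow in
MEGA; model-corrected distances are out of scope. Neighbor joining follows
the Saitou–Nei Q-criterion with two determinism guarantees: ties on Q break
toward the lexicographically smallest representative-label pair, and
negative branch lengths are clamped to zero with the deficit moved to the
sibling edge. NJ is exact on additive matrices — the property suite checks
path-length reproduction to 1e-9 on random 5–8-taxon trees and 4-taxon
topology choice against a least-squares oracle.

Bootstrap resamples alignment columns with replacement; support for each
internal split of the full-data tree is the percentage of replicate trees
containing that bipartition (counted via ape's bipartition machinery).
The default of 1,000 replicates follows standard practice; the seed defaults
to 1 and is always recorded.

Subgroup assignment (2a–2e, defined only within group 2) replaces a
by-eye tree reading with a deterministic rule: build an NJ tree over the
query plus a labelled reference panel (at least two references per tag),
return the tag of the smallest split side containing the query whose other
members share one tag; if no pure side exists, fall back to the nearest
reference by p-distance (ties broken by label) and flag the fallback.
Assignments on real data are panel-dependent — the published subgroup calls
rest on an unspecified set of soybean anchors — so the packaged tests use
synthetic panels with known truth, and real panels are user-supplied.

## qRT-PCR analysis

Relative expression follows 2^−ΔΔCT with ΔCT = CT(target) − CT(reference)
per replicate (paired by replicate index; reference default Skip16), ΔΔCT
between treatment and control, and the signed fold-change convention that
matches how such tables are printed: ratio r reported as +r when r ≥ 1 and
−1/r otherwise, so −2.62 means a 2.62-fold repression. Regulation calls use
|FC| ≥ 2 — the threshold applies to the signed magnitude, so −2.02 is a
down call. Significance is a two-sided Welch t test on the replicate ΔCT
values (*, p < 0.05; **, p < 0.01): the upstream convention marks stars
without naming a test, and Welch on ΔCT is the assumption-light standard
choice; it is recorded in the run metadata.

The four-sample design crosses genotype (drought-tolerant L, sensitive N)
with treatment (optimal irrigation OI, terminal drought TD). Summaries
count a gene once by the direction of its drought comparisons (LOI→LTD,
NOI→NTD), falling back to the genotype comparison (LOI→NOI) for genes with
only that call; genotype-differential genes are those with any LOI→NOI
call, and same-pattern genes have equal non-unchanged directions in both
drought comparisons. The packaged fold-change fixture indexes calls by the
table's fold-change column headers (its pattern labels disagree with the
headers for some rows; the headers are taken as authoritative).

## Synthetic data: what it emulates, and what it does not

Every generator is a deterministic function of (parameters, seed) and emits
a truth table alongside standard formats.

* `make_proteome()` plants class architectures in random background drawn
  from an alphabet without C, H or W. Since every heptapeptide starts with W
  and every finger anchors on C, planted motifs are provably the only
  matches — zero-false-positive fixtures by construction, not by rejection
  sampling. Subgroup classes are built around distinct flanking centroids
  (three point mutations per member) so phylogenetic assignment is
  learnable.
* `make_genome()` plants clusters whose member gaps are far below the 200-kb
  bound with at most three intervening filler genes, and separates every
  other family-gene pair by at least twice the bound, so the planted
  clustering is the unique answer under the rule.
* `make_ortholog_pairs()` plants synonymous and nonsynonymous single-nt
  substitutions on disjoint codons at Jukes–Cantor-inverted densities
  scaled by the NG86 site counts of the source sequence, giving target
  recovery in expectation.
* `make_qpcr()` holds the reference gene at CT 20 and offsets target ΔCTs by
  −log2(r) along the design paths; CT noise is Gaussian with default sd
  0.15 cycles and three replicates, matching a clean triplicate qPCR run.
* `make_promoters()` rejection-samples backgrounds until an independent
  regex-based IUPAC matcher (a separate code path from the Biostrings scan)
  finds no dictionary motif, then inserts concrete instantiations of the
  requested consensi. Complementary motif pairs (e.g. TGACG/CGTCA) produce
  the expected paired hits inside planted windows.

What the generators do **not** emulate: homology and duplication structure
(no gene trees, no segmental duplication), codon usage bias, indel
evolution, promoter compositional heterogeneity (CpG-like tracts), qPCR
amplification-efficiency deviations from 2, and real expression atlas
correlation structure. Passing the closed-loop suite therefore shows the
pipeline computes its definitions correctly on data satisfying its
assumptions; it does not validate biological discovery performance on real
genomes, and the genome-scale counts published for any particular species
(family sizes, group splits, cluster counts, Ka/Ks ranges) are not
reproduction targets of this package.

## Problem sizes and runtime choices

The test suite and acceptance script size their simulations to run
comfortably on a single CPU: 200 random proteins for the scanner oracle,
100 random layouts for the cluster oracle, 100 random promoters for the
IUPAC oracle, 20 pairs × 500 codons for NG86 recovery, 25 random 5–8-taxon
trees for NJ, and survey bundles with 24 proteins, 60-gene genomes, 5–10
ortholog pairs and 50–200 bootstrap replicates. These are the package's own
fixture sizes; all of them are parameters, and nothing in the
implementation depends on them.

## Known limitations

* Group-2 subgroup calls require a reference panel; no panel ships for real
  species.
* NG86 underestimates rates under strong transition/transversion bias or
  codon-usage skew, where an ML codon model would differ most.
* The pI calculation treats residues independently (no charge interactions
  or cysteine oxidation states), as all closed-form calculators do.
* The cluster rule's distance convention (end-to-start) is one of several
  defensible readings; it is flagged in output metadata so downstream users
  can tell which was applied.
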