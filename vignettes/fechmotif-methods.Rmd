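---
title: "Surveying [2Fe-2S] cluster motifs in ferrochelatases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying [2Fe-2S] cluster motifs in ferrochelatases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fechmotif)
```

## The scientific problem

Ferrochelatase closes heme biosynthesis by inserting Fe(II) into a porphyrin
macrocycle. A subset of ferrochelatases — all metazoan enzymes and a
scattered minority of bacterial ones — additionally coordinate a [2Fe-2S]
cluster through four cysteines. In sequence space those coordinating
cysteines sit in one of two places: an internal insertion of roughly 22–34
residues within the conserved fold, or a C-terminal extension beyond it.
Because the cluster's function is unknown, the natural first question is
distributional: across sequenced genomes, which lineages and which kinds of
organisms carry a motif-containing ferrochelatase (MCF)?

`fechmotif` implements that survey as a reusable, testable pipeline:

1. **Curation** — sequences are joined to genome metadata, oversampling is
   corrected by genus/order paring, fusion proteins are trimmed to a declared
   span, and candidates lacking the catalytic histidine (H263 in human
   numbering, required for proton abstraction from the porphyrin) are set
   aside as non-functional.
2. **Region annotation** — each sequence is globally aligned to a reference
   ferrochelatase and split into N-terminal extension, core, internal
   insertion(s) and C-terminal tail.
3. **Motif detection** — a PROSITE-subset scanner enumerates all matches of
   the consensus `C-X(1,11)-C-X(1,11)-C`; a sequence is called an MCF only
   when a match lies entirely inside an insertion or the tail.
4. **Statistics** — cysteine profiles, binned motif likelihoods, a binary
   logistic regression of motif presence on cysteine count, and
   cross-tabulations against phylum, environment, temperature class, oxygen
   requirement and ferredoxin (COG0633) co-occurrence.
5. **Phylogeny** — Jukes-Cantor corrected distances on core sequences,
   neighbor joining, column bootstrap, majority-rule consensus.

Because the original cohort's sequence accessions live in supplementary
material rather than in the text, the package ships a first-class
synthetic-data generator whose ground-truth labels let every stage be
validated exactly.

## The consensus motif and the scanner

The consensus `C-X(1,11)-C-X(1,11)-C` encodes three coordinating cysteines
with one to eleven arbitrary residues between neighbors. Two details matter
and are easy to get wrong:

* **X may be cysteine.** Motifs with an adjacent cysteine pair (the XCCX
  grouping, common in insertion motifs) must match, with the extra cysteine
  absorbed by a spacer. Consequently a sequence region can admit several
  spacer realizations pinning the literal cysteines to different positions.
* **Hits are counted per literal-position tuple.** The scanner enumerates
  every match by backtracking over spacer lengths, then collapses
  realizations that use the same literal cysteines; overlapping hits with
  different literal tuples are all reported. The retained realization is the
  shortest-spacer one.

The fourth coordinating cysteine is deliberately *not* part of the
consensus: in some proteins it lies too far away to include without
destroying specificity. Partial groupings (`CX(3)CC`, `CX(9)CC`), the
spaced `CXC` pair, the adjacent `XCCX` pair, a histidine-rich tail, and the
C-terminal CAB-domain motif `E-X(2)-N-X-R` are flagged separately as
evidence of vestigial or alternative coordination.

The scanner is validated against an independent exhaustive oracle that
simply enumerates all cysteine triples with spacings in [2, 12]; the suite
checks exact agreement on 1,000 random cysteine-enriched sequences.

**MCF calling** is strict: every literal cysteine of a hit must lie inside
a single insertion span or inside the tail. Hits elsewhere — including hits
straddling a region boundary — are recorded but do not qualify, mirroring
the survey's exclusion of motifs found between regions. When both an
insertion and a tail carry qualifying hits, the insertion is reported as
the qualifying location (it is the rarer, more strongly conserved state).

## Reference mapping

The original survey worked from a multiple alignment; this package instead
maps each candidate independently onto a reference ferrochelatase by global
pairwise alignment (Needleman–Wunsch–Gotoh, BLOSUM62, affine gaps with
opening −11 and extension −1, a gap of length $k$ costing
$\mathrm{open} + k\,\mathrm{extend}$). Pairwise mapping keeps each
sequence's coordinates independent of cohort composition and removes the
external aligner dependency; an aligned-FASTA path is retained for
gap-column pruning and tree building from precomputed alignments. The
traceback tie-break is fixed (diagonal, then gap-in-reference, then
gap-in-query) so results are bit-reproducible. The implementation is in
C++ for speed and is checked against brute-force enumeration of all global
alignments on short sequences.

Region calls derive from the alignment:

* residues aligned before the reference core start → N-terminal extension
  (any length);
* maximal runs of query residues aligned to reference gaps strictly inside
  the core → internal insertions, kept when at least `min_insertion = 15`
  residues long (observed insertions are 22–34 aa; 15 tolerates truncated
  variants);
* residues aligned after the core end → C-terminal tail, kept when at least
  `min_tail = 10` residues long (shorter stubs are absorbed into the core);
* everything else → core.

Both length thresholds are conventions — the survey identified regions by
eye from its alignment without stating cutoffs — and are configurable. The
reference core span must be supplied with the reference profile, since core
boundaries are a structural annotation, not something the survey defines
numerically. The spans are asserted, on every call, to partition the query.

The catalytic-histidine check reads the query column aligned to the
reference His position: a histidine passes; any substitution fails with the
observed residue; a query gap fails with reason "deleted". Records failing
the check stay in the per-record report with disposition `dropped:no_his`
(the survey enumerates its removals; silently deleting them would hide
dysfunctional duplicate copies).

## Genome paring

The survey corrected oversampling manually: one genome per genus, then at
most ten genomes per order spread evenly across families, preferring type
strains and genomes with characterized ferrochelatases. `pare_genomes()`
codifies those stated preferences as a total order so the operation is
reproducible: within a genus the winner is chosen by characterized-enzyme
flag, then type-strain flag, then ascending genome id; within an
over-populated order, families are cycled in ascending name order, taking
one genome per family per round (by the same priority) until the cap. Ties
the survey never specified — equally preferred genomes — fall back to
ascending genome id; this is our convention, not the survey's.

## Statistics

* **Binned likelihood.** For each cysteine-count bin the motif rate
  $\hat p = k/n$ is reported with the plain binomial standard error
  $\sqrt{\hat p(1-\hat p)/n}$ — the only formula consistent with the
  survey's reported ±0.27 at $n = 3$. Default bins are [0,3], [4,5],
  [6,10], [11,∞); the survey's prose bins overlap at six cysteines, so the
  boundary was resolved upward and the bins left configurable.
* **Logistic regression.** $\mathrm{logit}\,P(\text{MCF}) = \beta_0 +
  \beta_1\,\text{cys}$, fit by iteratively reweighted least squares;
  standard errors come from the inverse Fisher information at the optimum,
  and the 95% interval on the odds-ratio scale is the Wald interval
  $\exp(\beta_1 \pm 1.96\,\mathrm{se})$ (the survey reports a single lower
  confidence limit without naming a method; Wald is the default in the
  software it used). Complete separation is reported as non-convergence
  with the coefficients flagged, not hidden. The fit is verified against
  `glm()` and against a grid-search likelihood maximizer.
* **Cross-tabulations.** A genome counts as MCF-containing when *any* of
  its records qualifies, so duplicate-ferrochelatase genomes with one motif
  copy count once. Percent columns are rounded half-up to whole percents,
  which reproduces every printed table percentage; two denominator styles
  are supported (per-row share, and share of all MCF species).

## Phylogeny

Distances are proportions of differing sites under pairwise gap deletion
(complete deletion is a config choice the original tool does not document),
corrected with the generalized Jukes-Cantor formula for a $b$-state
alphabet, $d = -\frac{b-1}{b}\ln(1 - \frac{b}{b-1}p)$ with $b = 20$ for
proteins; $p \ge (b-1)/b$ is reported as saturation rather than silently
clamped. Neighbor joining follows the standard Q-criterion with two
reproducibility guarantees: exact ties in Q are broken by the
lexicographically smallest pair of node labels, and negative branch lengths
are clamped to zero. Bootstrap replicates resample alignment columns with
replacement (seed-deterministic), and the consensus keeps bipartitions
occurring in strictly more than half the replicates — above 50% retained
splits are automatically mutually compatible, but the builder adds them
greedily by descending frequency anyway so sub-threshold use is safe.
Supports are occurrence fractions stored as internal node labels in
Newick. The survey's tool-specific random seed (95,549) is not portable,
so it is carried as the package default seed for provenance rather than as
a claim of equivalence.

NJ correctness is tested by exact recovery (topology and branch lengths)
from random additive matrices, and cross-checked against `ape::nj`;
consensus topology is cross-checked against `ape::consensus`.

## The synthetic cohort

The generator emulates the structure of the surveyed cohort so pipeline
output can be compared with planted truth:

* a fixed cysteine-free 400-residue reference with the catalytic His at
  position 263 and core span 55–400; per-record cores receive ~2%
  substitutions (never creating a cysteine, never touching the His or
  region junctions);
* region frequencies 0.12 / 0.13 / 0.45 for extension, insertion and tail
  (56, 63 and 215 of 482 surveyed sequences), insertion lengths 22–34;
* cysteine counts Poisson with mean 4.4 truncated at 14 (the surveyed range
  and mean), with motif status drawn from
  $\mathrm{logit}\,P = \beta_0 + \beta_1 x$, $\beta_1 = \ln 2.61$ (the
  surveyed odds ratio) and $\beta_0 = -6.59$, chosen once so the marginal
  motif rate matches the surveyed ~18.5% of sequences — this also lands the
  [6,10]-bin likelihood near the reported 0.51;
* planted motifs are exact consensus instances (spacers uniform on 1–11),
  realizing the adjacent-pair XCCX variant half the time (the surveyed
  share), hosted in an insertion or tail (forced into one when the record
  has neither);
* background cysteines are rejection-sampled (cap 1,000 tries) so that no
  three of them can realize the consensus spacing — labels are exact by
  construction, never post-hoc;
* insertion-bearing records share thirty lineage substitutions, which is
  what makes them cluster in the trees, mirroring the single insertion
  clade in the surveyed phylogeny;
* genome metadata encodes the headline associations: aerobes are 72% of
  MCF genomes versus 46% of the rest, ferredoxin (COG0633) presence 77% vs
  55%, GC means 45 / 56 / 51% for insertion-MCF, C-terminal-MCF and
  non-MCF genomes, and environment/temperature classes drawn with
  MCF-conditional weights shaped like the surveyed tables.

Two motif models are available. The default `"logistic"` model generates
the cysteine-count association exactly (so coverage of the regression is
nominal); the `"conditional"` model instead draws motifs per region with
P(motif|insertion) = 0.95 and P(motif|tail) = 0.135, reproducing the
region-conditional rates at the cost of the clean logistic law. A single
mechanism cannot produce both the surveyed location split and the surveyed
regression; the default favors the statistical headline, and the location
split is exercised through the conditional model in tests.

One deliberate alignment-robustness device deserves mention: the residues
at segment junctions are resampled so they differ from their flanking core
residues. A one-column slide of an alignment gap run can only tie the true
alignment when a junction residue equals its flank (BLOSUM62 diagonals
strictly dominate their rows); the guard therefore makes the optimal gap
placement unique and the planted region spans exactly recoverable. Without
it, a handful of records per cohort would annotate with spans shifted by
one residue — a property of alignment ambiguity, not of the scanner.

What the generator does **not** emulate: realistic substitution processes
down a tree (NJ correctness is tested on additive matrices instead),
compositional heterogeneity, background cysteines outside the core, and
misannotation noise. Passing end-to-end tests therefore demonstrates the
pipeline's internal correctness on structurally faithful data, not
robustness to real-world annotation error.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: the default 500-record
cohort for end-to-end label recovery; 50 cohorts of 500 for Wald-interval
coverage (expecting ≥ 42/50 at nominal 95%); 1,000 random sequences for
scanner/oracle agreement; all pairs from a fixed set of fourteen length ≤ 7
sequences over a four-letter alphabet for aligner/oracle agreement; 100
random additive 6-taxon matrices for NJ recovery; and a 40-taxon, 100-
replicate bootstrap for the full tree protocol. These sizes were chosen to
exercise each property at meaningful scale while keeping a full run in the
low minutes on one CPU.

Other numerical conventions: IRLS converges on a maximum coefficient step
below 1e-8 within 50 iterations; weights are floored at machine epsilon;
gap-column pruning removes a column only when its gap fraction strictly
exceeds the threshold (a column gapped in exactly 95% of rows survives at
0.95); `his_rich_threshold = 0.15` for tail histidine-richness is our
convention (the survey gives none); and percent rounding is half-up.

## Known limitations

* Region annotation quality is bounded by pairwise alignment to a single
  reference; highly diverged sequences or references with unusual domain
  architecture may need a curated core span or a precomputed MSA.
* The strict all-literals-inside rule for MCF calling can classify
  borderline straddling hits differently from a by-eye assessment.
* The PROSITE subset covers literals, `X`, `X(n)` and `X(n,m)` only — no
  ambiguity classes or anchors.
* Newick serialization quotes labels, but exotic label characters inside
  quotes rely on `ape`'s parser.
* The consensus builder targets thresholds ≥ 0.5; below that, greedy
  compatibility resolves conflicts but is order-dependent in ways majority
  rule is not.
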