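# fechmotif

Survey pipeline for **[2Fe-2S] cluster cysteine motifs in ferrochelatases**.

Ferrochelatase inserts Fe(II) into a porphyrin to finish heme synthesis. A
minority of ferrochelatases — all metazoan ones and scattered bacterial
lineages — additionally bind a [2Fe-2S] cluster through four cysteines
located either in an internal 22–34 residue insertion or in a C-terminal
extension. This package implements the comparative-genomics workflow for
mapping that motif across a sequence cohort, for anyone who wants to run,
extend or stress-test such a survey:

* **Curation** — FASTA + genome-metadata ingestion, genus/order genome
  paring (one per genus; ≤ 10 per order, spread round-robin over families),
  fusion-protein trimming, and removal of candidates lacking the catalytic
  histidine (H263, human numbering), verified by global alignment to a
  reference ferrochelatase (Needleman–Wunsch–Gotoh, BLOSUM62, affine gaps).
* **Region annotation** — N-terminal extension, internal insertion(s),
  C-terminal tail and core, from the reference alignment.
* **Motif detection** — a PROSITE-subset scanner for the consensus
  `C-X(1,11)-C-X(1,11)-C` (X may itself be cysteine, so adjacent-pair XCCX
  motifs match), partial groupings (`CXC`, `CX(3)CC`, `CX(9)CC`), the
  CAB-domain tail motif `E-X(2)-N-X-R`, and histidine-rich tails. A record
  is a **motif-containing ferrochelatase (MCF)** only when all three
  literal cysteines of a hit lie inside an insertion or the tail.
* **Statistics** — cysteine profiles, binned motif likelihood with binomial
  SEs, logistic regression of motif presence on cysteine count
  (`logit P = b0 + b1·cys`, fit by IRLS, Wald CI on the odds-ratio scale),
  and cross-tabulations by phylum, environment, growth temperature, oxygen
  requirement and ferredoxin (COG0633) co-occurrence.
* **Phylogeny** — p-distances with pairwise gap deletion, generalized
  Jukes-Cantor correction (b = 20), neighbor joining with deterministic
  tie-breaks, column bootstrap, >50% majority-rule consensus with supports,
  Newick IO (`ape` trees throughout).
* **Synthetic cohorts** — a generator that plants regions, exact consensus
  motifs, background cysteines (rejection-sampled so they can never form an
  accidental consensus) and metadata associations, with exact truth labels
  for every record.

## Worked example

The `analysis/` scripts run the survey end-to-end on the default synthetic
cohort (500 records, seed 95549):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen_motifs.R
Rscript analysis/03_statistics.R
Rscript analysis/04_phylogeny.R
```

which prints (stage 2 and 3 output):

```
input 500 records: kept 486, dropped (no catalytic His) 14
MCF calls: 93 records, 93 genomes
His dispositions matching truth: 100.0%
MCF calls matching truth:        100.0%
binned motif likelihood (p_hat +/- binomial SE):
  [0,3]    n=179  p=0.02 (+/- 0.01)
  [4,5]    n=173  p=0.13 (+/- 0.03)
  [6,10]   n=132  p=0.50 (+/- 0.04)
  [11,Inf) n=  2  p=1.00 (+/- 0.00)
logistic fit: OR per added cysteine 2.56 (95% CI 2.11-3.10)
```

Reading: 14 of 500 candidates lack the catalytic His and are set aside as
non-functional; every disposition, region span and MCF call matches the
generator's planted truth; sequences with six to ten cysteines have a ~0.5
likelihood of carrying a qualifying motif; and each added cysteine
multiplies the odds of a motif by ~2.6 — the association the generator
plants (true odds ratio 2.61) and the regression recovers. Stage 4 builds
the core-sequence NJ/bootstrap/consensus tree and confirms the
insertion-bearing lineage forms a single clade.

The same machinery works on real data: `read_fasta()` +
`read_metadata()` + `fech_dataset()` + `run_pipeline()` with a
`reference_profile()` for your reference enzyme (sequence, catalytic-His
position, core span).

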