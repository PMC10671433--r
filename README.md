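# homeoshock

Transcriptome shock analysis for interspecific hybrids and allopolyploids.

When two parental genomes meet in a single nucleus — here the triploid
*Brassica* hybrid AAC formed from a diploid A-genome parent (AA, subgenome
A^r) and the allotetraploid *B. napus* (AACC, subgenomes A^n and C^n) —
gene expression reorganizes on two distinct axes:

- **Homoeolog expression bias (HEB):** within the hybrid, which member of a
  homoeolog pair is the stronger expresser, and whether that bias is
  conserved from, novel to, reversed against, or lost relative to the bias
  already present between the parents.
- **Expression-level dominance (ELD):** whether the *pair total* in the
  hybrid statistically matches one parent while differing from the other
  (dominance), lies between both (additivity), exceeds or undercuts both
  (transgressive up/down), or matches both (no change).

`homeoshock` implements the complete desk-side pipeline around these two
classifications: reciprocal-best-BLAST-hit homoeolog pairing, FPKM
conversion and expression binning, sample QC (Spearman correlation, PCA),
the pair-level Student t-test battery, the dominance decision table, the
3×3 per-homoeolog mechanism linkage (which homoeolog moved to produce a
dominance call), fold-change/FDR differential expression, and
hypergeometric term enrichment — plus a seeded synthetic-data generator
with per-pair truth states so that every stage is testable without
sequencing data.

## The statistics at the core

For each homoeolog pair, six expression contexts exist: A^rp and O^p (the
A^r gene in parent AA and its partner homoeolog O ∈ {A^n, C^n} in parent
AACC) and A^rh, O^h (the same genes in the hybrid). All comparisons are
equal-variance Student t-tests on log2(FPKM + 1) replicate values at
α = 0.05, with direction from the group means:

- **HEB:** A^rh vs O^h (hybrid state) and A^rp vs O^p (parental state);
  a pair is Ar-biased / partner-biased when p < α, else unbiased. The two
  states cross-classify into conserved / novel / reversed / lost bias.
- **ELD:** three tests — parents (A^rp vs O^p), hybrid total vs parent 1
  ((A^rh + O^h) vs A^rp) and hybrid total vs parent 2 — whose
  greater/less/ns outcomes map through a 27-row decision table to
  `no_change`, `additivity`, `ELD_P1_high/low`, `ELD_P2_high/low`,
  `transgressive_up/down`, or `ambiguous` (direction-conflicting
  patterns). The hybrid total is computed per replicate so variance is
  preserved.
- **Linkage:** A^rh vs A^rp and O^h vs O^p give each homoeolog an
  up/unchanged/down change; the ordered pair (one of nine cases) explains
  dominance mechanistically, e.g. `unchanged:up` = the A^r copy held its
  parental level while the partner was up-regulated.
- **Pairing:** genes are homoeologs when each is the other's best
  cross-subgenome BLAST hit at e-value ≤ 1e-20 (bit score, then e-value,
  then lexicographic tie-breaks).
- **DEG / enrichment:** |log2FC| ≥ 2 (pseudocount 1, boundary inclusive)
  with BH-adjusted p < 0.05; gene-set term enrichment by the upper-tail
  hypergeometric test with BH FDR ≤ 0.05.

## Worked example

Simulate a 2,000-pair experiment (3 replicates per species, 8-fold
effects, 0.5 log2 replicate noise, uniform truth mix) and run the whole
pipeline:

```r
library(homeoshock)
cfg <- run_config(sim = sim_config(2000, seed = 1), out_dir = "demo", seed = 1)
run <- run_pipeline(cfg)
writeLines(write_report(run))
```

Excerpts of the report this prints:

```
ELD category proportions:
  additivity: 226 (11.3%)
  ambiguous: 26 (1.3%)
  ELD_P1_high: 261 (13.1%)
  ELD_P1_low: 236 (11.8%)
  ELD_P2_high: 274 (13.7%)
  ELD_P2_low: 225 (11.2%)
  no_change: 230 (11.5%)
  transgressive_down: 262 (13.1%)
  transgressive_up: 260 (13.0%)

DEG counts (hybrid vs parents):
  hybrid_vs_parent1: up=238 down=585 ns=1177
  hybrid_vs_parent2: up=214 down=616 ns=1170

  exact category recovery: 0.927
```

With a uniform mix over the eight concrete truth categories, the observed
proportions sit near 1/8 each, the small `ambiguous` residue collects
direction-conflicting test patterns, and the confusion matrix against the
generator's truth shows 92.7% exact category recovery at n = 3 replicates.
Stage tables (`heb_calls.tsv`, `eld_calls.tsv`, `linkage_calls.tsv`,
summaries, DEG tables, QC, `manifest.json`) are written under `demo/`.

Real data enter the same way via `read_expression_matrix()` (TSV:
`gene_id`, `subgenome`, `length_bp`, one column per replicate),
`compute_fpkm()` for raw counts, and `homoeolog_pairs()` on BLAST
outfmt-6 files; `run_config()` accepts the file paths in place of a
simulation config.

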