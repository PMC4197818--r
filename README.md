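# dipdiff

Differential enrichment analysis for 5-methylcytosine (5mC) and
5-hydroxymethylcytosine (5hmC) affinity-capture sequencing
(MeDIP/hMeDIP-style libraries).

## What it does, and for whom

Affinity capture of modified DNA (antibody pull-down for 5mC, chemical
labeling + biotin for 5hmC) followed by sequencing yields read coverage
proportional to local modification density. Comparing such libraries
between conditions — e.g. control vs. demethylase-depleted cells —
requires calling *where* a mark is enriched, *where* it changes, and
*what* those changes hit: promoters, gene bodies, CpG islands (CGIs)
and their 2-kb shores, enhancers. `dipdiff` is a tested, reusable R
implementation of that analysis for epigenomics researchers, covering:

* **Island calling.** Tags (deduplicated reads extended to 300-bp
  fragments, counted by midpoint) are scored in 200-bp windows against
  a Poisson background with rate λ = w·N / (f·G) (window w, library
  size N, effective genome f·G, f = 0.854). Windows with upper-tail
  p < 0.2 score −ln p and are linked across gaps ≤ 600 bp; islands pass
  an E-value-derived score threshold (E = 1000, Monte-Carlo calibrated).
* **Differential regions.** Candidates are islands of the pooled
  library; each is tested with the exact conditional binomial
  a | a+b ~ Bin(a+b, N_A/(N_A+N_B)), BH-adjusted (q ≤ 0.01), with
  pseudocounted normalized fold change for reporting.
* **Annotation & change calls.** Regions map onto promoters (TSS±1 kb),
  5'/3' UTRs, (coding) exons, introns, TTS+1 kb flanks, CGIs, shores
  and enhancers; per-gene calls are stratified ≥4× vs 2–4×.
* **Profiles.** FPKM-scaled composite tag densities over TSS±5 kb /
  25–75% relative gene body / TTS±5 kb, and scaled interval profiles
  for CGIs+shores and enhancers.
* **Promoter classes.** HCP/ICP/LCP by sliding-window GC and CpG
  observed/expected (O/E = #CpG·L / (#C·#G)).
* **Overlap statistics.** Two-tailed Fisher exact tests with the
  conservative EASE modification (overlap cell decremented by one);
  expression tertiles; enhancer→nearest-TSS linkage within 20 kb.
* **Synthetic data.** A generator for toy genomes, annotations and
  capture libraries with planted enrichment truth, used throughout the
  test suite.

## Worked example

The one-command demo builds a toy genome (2 × 2.5 Mb, 120 genes, 60
CGIs, 40 enhancers), simulates 2 marks × 2 conditions with planted
structure — 5hmC at enhancer interiors with boundary dips, lost at half
the TSS-linked enhancers upon "TET depletion"; CGI-border 5hmC spikes;
promoter-CGI shore hypermethylation; repression of genes next to
enhancers that lose 5hmC — and runs the full pipeline:

```r
library(dipdiff)
res <- run_demo("demo", seed = 2, n_fragments = 4e4)
readLines(file.path(res$output_dir, "run_log.txt"))
```

```
dipdiff 0.1.0
island config: window_size=200 gap_size=600 fragment_size=300 effective_genome_fraction=0.854 evalue=1000 fdr=0.01 ...
5hmC siNTC: 39888 tags, 607 islands
5hmC siTET: 39887 tags, 628 islands
5hmC siTET vs siNTC: 9 significant differential regions
5mC siNTC: 39911 tags, 698 islands
5mC siTET: 39904 tags, 617 islands
5mC siTET vs siNTC: 13 significant differential regions
enhancer linkage: 9/9 linked genes repressed (EASE p=4.74e-10)
```

Reading the output: each library yields ~600 islands (at E-value 1000
most are tolerated background; the planted structure dominates the top
scores). The 5hmC contrast finds the enhancers that lost the mark; the
5mC contrast finds the hypermethylated promoter-CGI shores. Per-gene
calls land in `gene_change_table.tsv`:

```
gene_id    region_class  mark  direction  log2_fc  stratum  condition
gene_004   coding_exon   5mC   hyper      2.53     >=4x     siTET
gene_004   exon          5mC   hyper      2.53     >=4x     siTET
...
```

and the enhancer-repression association in
`enrichment/enhancer_repression_overlap.tsv`: 9 of 9 genes linked to
5hmC-losing enhancers are repressed (universe 120 genes, two-tailed
Fisher p = 9.6e-13, EASE p = 4.7e-10, odds ratio 1400) — the planted
repression is recovered.

## Command line

```sh
inst/cli/dipdiff demo --out demo --seed 2
inst/cli/dipdiff call-islands --reads a.bed --chrom-sizes chrom.sizes --out islands.bed
inst/cli/dipdiff call-diff --reads-a tet.bed --reads-b ntc.bed --chrom-sizes chrom.sizes --out diff.bed
inst/cli/dipdiff run-all --config config.json
```

## Documentation

See the methods vignette (`vignettes/dipdiff-methods.Rmd`) for the
statistical model, parameter meanings and defaults, what the synthetic
generator does and does not emulate, and design decisions.
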