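---
title: "dipdiff: models and methods for differential 5mC/5hmC capture-seq analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dipdiff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`dipdiff` analyses affinity-capture sequencing of cytosine modifications
(MeDIP-style 5mC capture, chemical-labeling 5hmC capture). The input is a
set of aligned short-read libraries, one per mark and condition, plus a
gene annotation, CpG-island (CGI) intervals, enhancer intervals, and an
expression table. The output is a set of enrichment islands per library,
differential regions between conditions, per-gene change calls
stratified by fold magnitude, composite tag-density profiles, and
gene-set overlap statistics.

Capture assays sequence fragments in proportion to their modification
content. The analysis model is deliberately simple and transparent: read
counts in fixed windows are treated as Poisson around a genome-wide
background rate, enrichment is a local departure from that rate, and all
between-sample inference conditions on totals so that no dispersion
parameter needs to be estimated from the (replicate-free) designs the
method targets.

# Tag model

Reads are filtered to unique alignments (MAPQ > 0 from SAM/BAM; BED
input is taken as already filtered). Duplicates are bounded per key
(chromosome, 5' start, strand): at most **1** read per position feeds
island calling, at most **2** feed density profiles. Two policies
coexist deliberately — the stricter one protects peak calling from PCR
artefacts, the looser one preserves dynamic range in profile averages.

Each read is then extended to the assumed fragment length (default
300 bp, matching sonication to < 400 bp) toward its 3' end, and the
**midpoint** of the (chromosome-clipped) fragment becomes the tag
position. Clipping before taking the midpoint keeps edge reads without
letting tags escape the chromosome. Density is expressed as FPKM
(fragments per kilobase of feature per million mapped fragments), which
removes both feature length and library depth.

# Island calling

Tags are counted in non-overlapping 200-bp windows. With library size
$N$ and genome length $G$, the background rate per window is

$$\lambda = \frac{w\,N}{f\,G}, \qquad w = 200,\ f = 0.854,$$

where $f$ is the effective (mappable) genome fraction. A window with
count $m$ is *eligible* when its Poisson upper tail
$P(X \ge m \mid \lambda)$ is below 0.2 (the upstream caller's default),
and scores $-\ln p$. Runs of eligible windows separated by at most
600 bp of ineligible territory are linked into **islands**; the island
score is the sum of member scores.

The score threshold is set by an E-value: the expected number of
background islands genome-wide at or above the threshold must not
exceed 1000. Rather than relying on asymptotic island-score theory, the
threshold is computed by a seeded Monte-Carlo simulation: ≥ 20
replicates of the effective genome are drawn as i.i.d. Poisson($\lambda$)
windows, islands are formed, and the smallest score whose expected
exceedance count is ≤ E is taken. The simulation uses a private fixed
seed, so results are deterministic and the threshold is monotone in E.
A unit test checks the threshold against a 10× longer independent
simulation.

With a control (input) library, each island must additionally beat the
depth-scaled control count under a Poisson test,
$\lambda_{\mathrm{ctrl}} = \max(c \cdot N_A/N_{\mathrm{ctrl}},\
\lambda \cdot k)$ for an island of $k$ windows with control count $c$,
with Benjamini–Hochberg control at FDR 0.01.

Default parameters — redundancy 1, window 200, fragment 300, effective
genome fraction 0.854, gap 600, E-value 1000, FDR 0.01 — are the
published settings for this assay family and are all overridable via
`island_config()`.

# Differential regions and why candidates come from the pooled library

Differential testing between samples A and B is an exact conditional
binomial test: for a candidate region with counts $a$ and $b$,
$a \mid a+b \sim \mathrm{Binomial}(a+b,\ N_A/(N_A+N_B))$ under the
null. p-values are BH-adjusted across candidates; significance is
$q \le 0.01$. The reported fold change
$\widetilde{FC} = \frac{(a+1)/N_A}{(b+1)/N_B}$ uses pseudocount 1 for
display only — never in the test.

**Candidate regions are islands called on the pooled (A+B) tag set.**
An earlier design — the union of islands called separately in each
sample — turned out to be statistically unsound: an island is, by
construction, a region with an unusually *high* count in the sample it
was called in, so among such candidates the conditional split is biased
toward that sample and the binomial p-values are anti-conservative. In
background-only simulations roughly 5% of union candidates reached
$q \le 0.01$. Selecting candidates on the pooled count removes the bias
exactly: the binomial test conditions on $a+b$, and the selection event
depends on nothing else. The acceptance suite verifies super-uniformity
of null p-values and zero null calls at $q \le 0.01$ in ≥ 9/10 seeds.
Both alternative candidate modes remain available via
`island_config(diff_candidates = )` for comparison.

# Gene regions, CGIs and change calls

From each gene's representative transcript (the longest per gene id,
ties to the smaller start) the package derives: the promoter
(TSS ± 1 kb), 5' UTR, exons, protein-coding exons, 3' UTR, introns, and
a 1-kb flank downstream of the TTS, all strand-aware. The promoter
definition is read as a symmetric ±1 kb window; the source material's
"−1 kbp to +1" lacks units on the downstream bound, and the symmetric
reading matches the TSS-centred analyses it accompanies.

CGI **shores** are up to 2 kb on each side of an island, truncated at
chromosome ends and at neighbouring islands, so islands and shores are
disjoint genome-wide. CGIs are classified by location with a fixed
priority — promoter if the island touches any promoter window, else
gene body if it touches any transcript, else intergenic — producing a
partition, as the per-class figures require.

A (gene, region class) pair is **called** when any significant
differential region overlaps the region class by ≥ 1 bp (no minimum
overlap fraction is defined anywhere upstream; 1 bp any-overlap is the
deterministic choice, stated openly). The call takes direction and
magnitude from the overlapping region with maximal |log2 FC| (ties:
larger overlap, then smaller start) and is stratified ≥ 4-fold
(|log2FC| ≥ 2) versus 2–4-fold (1 ≤ |log2FC| < 2); sub-2-fold regions
produce no call. A gene may be called in several region classes at
once — the per-region tabulations count regions, not exclusive genes.
Shore calls work identically per shore; the promoter-shore summary
reports, among genes whose promoter overlaps a CGI, the fraction with a
hypermethylated shore.

# Promoter CpG-density classes

Promoters are classified on the sequence from TSS−700 to TSS+200 with
500-bp windows stepped by 5 bp. Per window, GC fraction and the CpG
observed/expected ratio $O/E = \#CpG \cdot L / (\#C \cdot \#G)$ are
computed with ambiguous bases excluded from counts and from $L$. HCP:
any window with GC ≥ 0.55 and O/E ≥ 0.75; LCP: no window with
O/E ≥ 0.48; ICP otherwise. These are the published cutoffs of the
classification the assay literature delegates to. Classification is
invariant to reverse complementation (CpG and GC are strand-symmetric),
which is tested.

# Composite profiles

Gene profiles have three segments: TSS ± 5 kb in 100 absolute 100-bp
bins, the gene body from 25% to 75% of gene length in 50
relative-length bins, and TTS ± 5 kb. Minus-strand genes are flipped so
bins run in transcription direction. Per gene and bin, the count of tag
midpoints is FPKM-normalized by bin length and library size, then
averaged across genes; genes whose profiled body is shorter than one bp
per bin are skipped and counted. Scaled interval profiles (CGIs with
their shores, enhancers, exons) use 0–100% of the interval with
absolute flanks. Bin counts (100/50) are display resolution choices —
nothing upstream fixes them. Stored profiles are linear; `profile_log2()`
applies the `log2(density + 0.01 FPKM)` display transform. Profiles are
treatment-only (no input subtraction): nothing in the source methods
indicates input-corrected profiles.

Each profile carries per-segment raw tag totals so conservation (binned
mass = overlap-counted mass) can be checked exactly; the acceptance
suite does so, and verifies that planted TSS peaks, CGI-border spikes
and enhancer edge dips land in the correct bins.

# Overlap statistics and enhancer linkage

Set overlaps use the Fisher exact test with a **two-tailed** p-value
(sum of all tables with probability ≤ the observed table's, the common
software convention) and, for added stringency, the **EASE**
modification: the one-tailed enrichment p recomputed with the overlap
cell decremented by one (floored at zero). EASE is conservative by
construction and equals 1 exactly when the overlap is a single gene.
Odds ratios use the Haldane 0.5 correction when a cell is zero. Both
p-values are reported side by side, since figure-legend conventions for
which one is quoted vary.

Expression tiers (high/moderate/low) are tertiles of
baseline-condition expression — no numeric tier bounds exist upstream,
and tertiles make the three-way comparisons well defined; ties resolve
by stable input order. The differential-expression flag defaults to
|log2FC| ≥ 0.585 (1.5-fold), configurable.

Enhancers are linked to the gene whose TSS is nearest (distance 0 if
the TSS lies inside the enhancer; ties to the smaller transcript
start), discarded beyond 20 kb. The linked set of enhancers that lose
5hmC is tested for over-representation among repressed genes via
EASE/Fisher against the gene universe (all annotated genes by default —
the appropriate universe is genuinely ambiguous and configurable).

# The synthetic world

`make_toy_genome()` builds a deterministic toy genome (default 2 × 5 Mb,
300 genes of 2–10 exons, 150 CGIs, 100 enhancers) with planted truth:
promoter CGIs sit on HCP-class genes, body CGIs mid-gene, intergenic
CGIs and enhancers in intergenic gaps; a configurable subset of
enhancers is placed 2–8 kb upstream of chosen TSSs to serve as
enhancer–gene linkage truth; promoter sequences are constructed to
realize planted HCP/ICP/LCP labels (HCP: GC ≈ 0.65 random sequence,
O/E ≈ 1; ICP: GC ≈ 0.44, O/E ≈ 1; LCP: GC ≈ 0.44 with CpG dinucleotides
destroyed). Defaults reflect the stated assay geometry (50-bp reads,
300-bp fragments) and a size small enough for minutes-scale testing.

`simulate_capture_library()` draws fragment **midpoints** from an
inhomogeneous Poisson process with rate
`background_rate × fold(position)`; each fragment emits one 50-bp read
from its 5' end on a uniform strand. Evaluating the rate at the
midpoint (rather than the fragment start) is what makes `fold = 0`
regions contain no tag midpoints at all, which downstream recovery
tests rely on. When `n_fragments` is set, the draw is conditioned on
the total (multinomial over constant-rate segments), so the library
size is exact while window counts stay Poisson to within
goodness-of-fit tolerance. Every library's random stream derives from
`(seed, mark, condition)`, so adding a library never perturbs the
others.

What the generator does **not** emulate: sequencing errors, GC bias,
mappability structure, fragment-length variation, capture-efficiency
differences between kits, or biological replicate variance. A green
test therefore establishes the correctness of the computation under the
stated model — not the biological validity of any particular dataset.
Planted fold magnitudes are free simulation parameters: the source
assay reports no quantitative capture enrichment efficiency.

# Numerical choices and degenerate inputs

* Window eligibility threshold 0.2; E-value Monte-Carlo with ≥ 20
  replicates under a private fixed seed; thresholds compare with `>=`.
* Fragment clipping: clip the interval first, then midpoint.
* Empty libraries are errors wherever a rate or FPKM would be
  undefined; empty interval lists are errors for profiles (not empty
  profiles).
* Promoter sequences shorter than one classification window are
  classified whole, with a warning.
* `norm_fc` pseudocounts never enter a test; directions at exactly
  log2FC = 0 are labelled "hypo" but can never be significant.
* All BH adjustments use `stats::p.adjust(method = "BH")`.

# Known limitations

* No replicate-aware dispersion modelling: the conditional binomial
  model attributes all count variation to sampling. With biological
  replicates, a dedicated count model would be preferable.
* The island caller is a faithful re-parameterization of the
  window/gap/E-value approach, not a bit-exact re-implementation of any
  specific caller release.
* Differential calls inherit window granularity (200 bp); sub-window
  structure is not resolved.
* The enhancer linkage uses TSS proximity only; it will mis-assign
  enhancers that skip their nearest gene.
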