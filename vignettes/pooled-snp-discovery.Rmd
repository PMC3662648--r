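---
title: "Pooled-transcriptome SNP discovery: models, thresholds, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-transcriptome SNP discovery: models, thresholds, and what the synthetic benchmark shows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pikapool)
```

## The problem

`pikapool` implements SNP discovery from *pooled* transcriptome sequencing
of two populations — the design used for non-model organisms such as the
American pika, where RNA from a few individuals per population (here three
diploids per elevation) is combined into one sequencing library per
population. Allele frequencies are then estimated from read counts rather
than from genotypes, which brings three coupled statistical problems:

1. **Calling**: at what read depth, frequency, and base quality is a
   within-pool variant distinguishable from sequencing error?
2. **Cross-population contrast**: how should sites be classified when one
   pool shows variation and the other does not, given that "no variation
   observed" may simply mean "not enough reads"?
3. **Ascertainment**: with only `2n = 6` chromosomes per pool, how often
   does a genuinely polymorphic site *look* fixed?

The package answers these with an explicit, testable pipeline plus a
synthetic-data generator that knows the truth behind every read.

## The pipeline and its parameters

### Trimming

Reads carry per-base error probabilities $p_i = 10^{-q_i/10}$. After
optional exact adapter clipping and removal of five terminal bases from
each end, the retained segment is the contiguous run maximizing
$\sum_i (L - p_i)$ with quality limit $L = 0.05$ — the running-sum
("modified Mott") construction used by common trimmers. The segment is
empty when the maximum is non-positive, and reads shorter than 100 bases
are discarded. The commercial tool behind the original workflow documents
the same *parameters* (limit 0.05, 5 terminal bases, 100-base minimum) but
not its exact windowing, so the Mott interpretation is adopted here and
checked against an exhaustive $O(L^2)$ substring search, not asserted as
identical to the commercial implementation. Ties among maximal segments go
to the leftmost, then longest, for determinism. The operation order —
adapters, terminal trim, quality segment, length filter — is fixed here;
the original description lists the operations without ordering them.

### Mapping

Mapping is seed-and-extend and deliberately *ungapped*: exact 15-mer seeds
at the read's start, middle, and end propose diagonals on both strands;
each candidate is scored by direct comparison clipped at contig bounds. A
placement is accepted when identity (matches / aligned span) is at least
0.90 and the aligned span covers at least half the read — "similarity" and
"length fraction" in the sense the original mapper documents. Ungapped
alignment is a divergence from that gapped mapper, chosen because the
downstream caller handles substitutions only and the simulator emits no
indels; the error model of the mapper thus matches the error model of the
data. Reads with more than one best-scoring placement are flagged
ambiguous and excluded from pileups, which prevents paralog-driven false
SNPs — a hazard the exclusion rule resolves conservatively, since the
original workflow does not state how multi-mappers were handled.
Coordinates are 0-based internally and 1-based in every emitted table.

### Per-pool calling

A pileup column yields a call when, counting only bases with phred
quality ≥ 20, depth is at least 8 and at least two alleles each have ≥ 2
reads and ≥ 10% frequency. "Minimum central quality" is applied to the
variant base itself — the simplest defensible reading of a neighborhood
parameter whose exact semantics the original tool does not document.
Frequencies use the quality-passing depth as denominator, matching the
calling denominator.

### Cross-pool classification and divergence

Merged sites are classified as **a** (polymorphic in both pools), **b**
(polymorphic in one, fixed in the other), or **c** (fixed for different
alleles). A pool counts as *fixed* only when its quality-passing depth
reaches the same 8× bar with a single quality-passing allele; a site
polymorphic in one pool whose other pool fails that bar is
**undetermined** and excluded from category counts rather than silently
labeled fixed — the low-coverage-looks-fixed bias made explicit. The
divergence index is $D = |f_{high}(M) - f_{low}(M)|$ where $M$ is the
major allele of the *combined* pool counts (ties broken alphabetically;
the source description names only "the major allele"). $D = 1$ exactly
characterizes category c. Sites with more than two relevant alleles stay
in the table but are excluded from $D$ and the transition/transversion
ratio, which are biallelic summaries. Candidate panel SNPs require
$D \ge 0.5$ and a 200-base amplicon window inside the contig containing no
other merged SNP.

### Validation statistics

For a genotyped panel the package computes $H_o$ (heterozygote fraction)
and $H_e = 2pq$ — deliberately *without* the $2n/(2n-1)$ small-sample
correction, because the printed reference values for an all-heterozygote
group (1.00/0.50) are only reproducible with the uncorrected estimator.
The Hardy-Weinberg test is the exact conditional test: enumerate all
heterozygote counts compatible with the observed allele counts,
$P(h) = \binom{n}{n_{AA},\,h,\,n_{aa}} 2^h / \binom{2n}{n_A}$, and sum the
probabilities of configurations no more probable than the observed one.
Linkage disequilibrium uses a permutation test of the log-likelihood G
statistic on the genotype-pair table — a seeded, exactly reproducible
replacement for the Markov-chain method of the package originally used for
this step, testing the same null. "Sequential Bonferroni" is implemented
as Holm's step-down procedure (the procedure that name refers to), via
`stats::p.adjust`.

### Ascertainment

The probability that a site with population frequency $q$ looks fixed in a
pool of $n$ diploids is $(1-q)^{2n} + q^{2n}$ — 0.53 at $q = 0.1$, $n=3$.
`simulate_apparent_fixation()` additionally pushes the sample through a
finite-depth read layer and the calling thresholds; at 30× this *adds*
apparent fixation (e.g. 0.58 vs 0.53 at $q = 0.1$), quantifying how much
of the fixed-in-one-pool category is sampling artifact rather than
population differentiation.

## The synthetic benchmark

The generator's defaults define the study conditions used by the tests and
the analysis scripts:

| quantity | default | why |
|---|---|---|
| individuals per pool | 3 diploids | the pooled design being emulated |
| transcripts | 200 × ~1 kb (sd 250, min 200) | transcript-scale contigs at a desk-scale count |
| variable-site density | 0.005 / base | order of the observed SNPs-per-contig-base rate in the real high-coverage dataset |
| allele-frequency spectrum | per-pool Uniform(0,1); 2% of sites fixed-different | a neutral, assumption-light spectrum covering all three cross-pool regimes |
| depth | 30× per pool | the real dataset's ~33× mean coverage, rounded |
| read lengths | Normal(266.8, 60) / Normal(245.7, 60), clipped | the two real libraries' mean read lengths |
| substitution errors | 0.5% per base; correct bases Q30, errors Q10–30 uniform | exercises the Q20 filter from both sides |

Reads are single-end with uniform starts and lengths clipped at transcript
ends. Homopolymer indel errors — the signature artifact of the original
sequencing chemistry — are **not** modeled, because the pipeline calls
substitutions only; the simulator's error model deliberately matches the
caller's. Likewise tissue pooling structure is not modeled (it has no
allele-frequency consequence), alternate alleles are drawn uniformly, and
expression differences between pools are absent. Consequently passing
tests demonstrate correctness of the *computational* pipeline under a
matched error model, not robustness to indel errors, mutation-spectrum
bias, or expression-driven coverage asymmetry in real data. Two visible
consequences: the benchmark's transition/transversion ratio is ~0.5 by
construction (one uniform alternate per site; real transcriptome SNPs
show ~3.9), and its mean divergence (~40%) reflects the uniform spectrum
plus small-pool ascertainment, not the published 21%.

## What the benchmark shows — and a known ceiling

On the default benchmark (seed 20919) the pipeline maps >99.8% of reads to
their true origins, holds false calls at invariant columns to ~7×10⁻⁵
(<0.1%), and the partition identity |a|+|b|+|c|+|undetermined| = total
holds on every run. Detection of pool-polymorphic sites with ≥8×
quality-passing depth in both pools is 92.7% overall — and this is a
*statistical ceiling*, not an implementation gap: sites whose minor allele
sits on 1 of the 6 pool chromosomes need
$\Pr[\mathrm{Bin}(d, 1/6) \ge \max(2, 0.1d)] \approx 0.83$ at the
realized post-trimming depth $d \approx 28$, and such sites are ~40% of
per-pool-polymorphic sites under a uniform spectrum (theoretical mixture:
92.9%; observed: 92.7%). Raising detection materially would require deeper
sequencing or larger pools, not different code. The per-stratum numbers
are in `analysis/03_recovery.R`'s output.

## Numerical choices and degenerate inputs

* Segment/score ties in trimming: leftmost, then longest.
* Mapping ties: equal-scoring placements are reported at the lowest
  (contig, position) and flagged ambiguous.
* The high-coverage filter's "coverage greater than 5×" is implemented as
  ≥ with a `strict` switch, since the source wording is ambiguous.
* Exact-test p-values are clamped to 1 against floating-point
  accumulation; probability-ordering comparisons carry a 10⁻⁹ relative
  tolerance.
* Empty read sets flag the mean length undefined (NA) rather than 0/0;
  monomorphic loci return HWE p = 1 and are untestable for LD.
* Derived random streams: each generator stage draws from a seed derived
  as a stable function of the user seed, so stages are individually
  reproducible and jointly independent; all derived seeds stay below 2³¹.
* Problem sizes in the tests (6–200 transcripts, 5–30×) were chosen so the
  full suite exercises every stage at benchmark scale while completing in
  a few minutes on one CPU.

## Known limitations

* Gapped and spliced alignment, de novo assembly, indel calling, and
  multi-allelic divergence are out of scope.
* The redundancy classifier asks the overlap question (90% identity over
  half the shorter contig) by pairwise local alignment rather than by
  re-assembly, so its classes mirror, but are not identical to, what a
  re-assembler would report.
* The LD permutation test conditions on observed genotype margins; with
  very small groups its p-values are discrete and conservative.
* Read-name origin tags are the simulator's own convention; SAM ingest
  parses pool labels from them by default but accepts an explicit label.
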