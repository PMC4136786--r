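---
title: "Error-suppressed detection of circulating tumor DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-suppressed detection of circulating tumor DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdnaseq)
```

## The problem

Tumors shed DNA into the bloodstream. This circulating tumor DNA (ctDNA) is
a small subfraction of the total cell-free DNA (cfDNA) in plasma — often
well below 1% in non-metastatic disease — and carries the somatic point
mutations of the tumor it came from. Tracking those mutations in plasma by
deep targeted sequencing is attractive for disease monitoring, but two
obstacles dominate: cfDNA is short (fragment sizes peak near 180 bp) and
scarce, and the substitution error rate of short-read sequencing
(a few parts per thousand) sits orders of magnitude above the ctDNA
fractions of interest. Any credible pipeline must therefore suppress
errors aggressively and then test a very small mutant signal against an
honest estimate of the residual background.

`ctdnaseq` implements that pipeline end to end: synthetic cfDNA data with
known ground truth, overlap merging of paired-end mates, length-aware
PCR-duplicate consensus, genomic eligibility masking, background
noise-rate estimation with quality-cutoff optimization, pooled one-sided
Fisher-exact detection, and a Monte-Carlo simulator of the detection
limit.

## Error-suppression model

Two physical facts make error suppression possible.

**Overlapping mates observe the same bases twice.** A ~180 bp fragment
sequenced 2 x 100 bp is covered twice in the middle. `merge_pairs()`
aligns the reverse-complemented second mate against the first (best-match
offset, at least 15 bp of overlap, at most 10% mismatches — the merge
acceptance thresholds are this package's defaults, chosen as typical for
merge tools) and fuses the pair into one template-length read. Concordant
overlap bases keep their base with quality `min(q1 + q2, 45)`; discordant
bases (including N in either mate) are masked to N with quality 2. A
sequencer error in one mate is therefore either masked or never boosted.

**PCR duplicates observe the same molecule repeatedly.** Standard
single-end duplicate marking keys reads on the mapped start only. After
merging, every read's template length is known, so `duplicate_key()` keys
families on (chromosome, strand, 5' start, template length): two distinct
molecules that share a start but differ in length stay separate, which is
exactly the information a merged cfDNA library adds over classic
single-end data. `consensus()` then votes per column within a family: the
modal base is kept when at least 75% of the family carries it (inclusive,
so 3 of 4 passes; N members count toward the family size but never toward
the modal base), with quality equal to the sum of the qualities of the
reads carrying it, capped at 50; otherwise the column becomes N with
quality 2. Read-level (sequencer) errors are voted out in families of
three or more; family-level (PCR) errors are shared by the whole family
and survive — the consensus cannot remove them, only barcoding could.
Ties for the modal base necessarily fail the 75% rule, so no tie-breaking
is needed. We sum only the qualities of reads carrying the consensus
base, reading the boosted quality as "support from multiple independent
sources"; the boosted qualities feed the downstream quality filter only,
never the detection test itself.

## Eligibility mask

Positions are only informative where the genome maps uniquely and no
germline variation can masquerade as signal. `build_mask()` takes
low-mappability intervals, simple-repeat intervals and germline variant
positions (population SNPs and cohort de-novo calls alike) and removes
them, expanding the low-mappability regions by a 50 bp flank: a site
within 50 bp of a region with mappability below 1 is excluded. Interval
arithmetic rides on `GenomicRanges`; coordinates are 1-based closed
inside the package (the native GRanges convention) and convert at the
BED boundary via `rtracklayer`.

## Noise model and cutoff choice

The background noise rate at a set of tracked positions is
`mut / (mut + ref)` pooled over background samples — all samples that do
not carry the mutation in their tumor, with the tested sample itself
always left out. (The alternative denominator `ref` alone differs only at
order rate squared; we fix the `mut/(mut+ref)` form throughout.)
`sweep_cutoffs()` raises the per-base quality cutoff over a grid
(default 0-50, the consensus cap) and reports, per cutoff, the noise
rate, the fraction of reference reads retained, and the log2 ratio of
retained mutant to retained reference proportions. Because merge and
consensus boosting concentrate quality on multiply observed bases,
raising the cutoff removes mutant (error) reads preferentially.
`optimal_cutoff()` picks the noise-rate minimum, breaking ties toward
higher retention and then the smaller cutoff. The per-base score filtered
on is the consensus-boosted quality; any externally computed per-base
alignment-quality score can be substituted by writing it into the
fragment quality strings, keeping the scale pluggable.

## Detection

Per-site depths are far too shallow for per-mutation calling at the
fractions of interest, so `detect_ctdna()` pools all of a patient's
tracked sites and tests the pooled 2 x 2 table (sample vs background,
mutant vs reference) with a one-sided Fisher exact test, alternative
"sample fraction greater". The p-value is the exact hypergeometric upper
tail computed with `phyper`; the test suite checks it against both a
brute-force tail summation and `fisher.test`. The reported ctDNA fraction
is the raw pooled `alt / (alt + ref)` without background subtraction, and
no multiple-testing correction is applied across patients; the alpha of
the `detected` flag is configurable and defaults to 0.05. A sample with
zero mutant reads gives p = 1 by construction.

## Sensitivity simulation

`simulate_sensitivity()` asks: at ctDNA fraction f and input mass m, how
often would the pooled test fire? The pooled depth derives from the
input: m ng contains `m * 1000 / 3.218` haploid genome copies (3.218 pg
per haploid copy); multiplying by the capture efficiency (default 0.047,
the saturation estimate of the fraction of input molecules observable
after library preparation and capture), the number of tracked variants
(50 for an exome) and the fraction of data kept by the quality filter
(0.61 for the consensus pipeline at its optimal cutoff) gives the pooled
read count. In WGS mode a fixed per-site coverage (default 30x over 3000
variants) replaces the input-derived depth. Mutant reads are drawn
`Binomial(depth, f)` — sample noise is deliberately not added to the
draw; noise enters only through the fixed background table, by default
517,973 reads with `round(517973 * noise_rate)` mutant reads. Each draw
is tested with the one-sided Fisher test at alpha 0.05; sensitivity is
the fraction of 1000 iterations that fire, and `detection_limit()`
reports the smallest fraction reaching 95% sensitivity, log-linearly
interpolated between the bracketing grid points of the default 40-point
log grid over [1e-5, 0.05]. The kept fraction is applied to the depth
multiplicatively rather than by post-hoc read subsampling — equivalent
in expectation and cheaper. An empirical-pool mode draws the sampled
fraction from a finite read pool (default 4,733 reads) instead, which
quantizes very small fractions to zero; the binomial mode is the
default. With `common_random = TRUE` one set of uniforms is reused
across fractions, making the sensitivity curve exactly monotone — useful
for property tests.

Two consequences are worth noting. Doubling the input from 30 to 60 ng
improves the limit only marginally, because capture efficiency, not
input, is the binding constraint; going from 3 to 30 ng is a much larger
gain. And the detection limit degrades as the background noise rate
rises or the kept fraction falls, which reproduces the ordering of the
processing pipelines: the consensus pipeline (low noise, 61% kept) beats
the unfiltered standard pipeline and the quality-filtered standard
pipeline alike.

## The synthetic-data generator

Every stage above is testable without external data because
`simulate_library()` generates cfDNA libraries with full provenance.
Molecules are drawn uniformly over a random reference with
truncated-normal lengths — mean 180 bp, sd 40 bp, truncated to
[50, 250] bp. The size distribution of real cfDNA is known only as an
electropherogram peak near 180 bp; the truncated normal is this
package's parametric choice, and the upper bound is kept above twice the
read length so that a realistic tail of fragments is too long for their
mates to overlap. A molecule is tumor-derived with probability equal to
the configured ctDNA fraction and then carries the alternate allele at
every variant site it covers. Families are 1 + Geometric with mean 5
reads per molecule by default, emulating the ~80% duplicate rates of
deeply sequenced cfDNA captures (no family-size law is established for
real libraries; the geometric is a deliberate simple choice). PCR errors
are injected once per family at 1e-5 per base (a proofreading-polymerase
order of magnitude) and shared by all reads of the family; sequencer
errors are injected per read at 0.0029 per base, the substitution rate
observed in deep cfDNA sequencing. Base qualities are drawn N(36, 3)
rounded and clipped to [2, 41].

What the generator does **not** emulate: cycle-dependent quality decay,
error rates that depend on quality, GC and capture-bait bias, indels,
optical duplicates, and alignment ambiguity (reads are placed at their
true coordinates, standing in for an aligner over uniquely mapping
regions). Passing tests therefore demonstrate the correctness of the
algorithms and their statistical behaviour under a clean error model,
not performance on real data — in particular, real error processes are
position- and context-dependent, which is precisely why the background
pool in real use must come from cohort samples processed identically.

## Numerical and degenerate-input choices

* Overlap ties go to the longer overlap; merge acceptance needs >= 15 bp
  overlap and <= 10% mismatches; N counts as a mismatch when scanning
  and as discordance when merging.
* The 75% consensus rule is inclusive; quality sums cap at 45 (merge)
  and 50 (consensus); masked columns are always N with quality 2.
* Empty inputs return empty, typed results (`group_duplicates`,
  `consensus_reads`, `pileup_bases`); a zero-denominator noise rate is
  `NA` and `optimal_cutoff` refuses a table with no defined rate;
  a degenerate Fisher table gives p = 1.
* `fisher_one_sided` uses the `phyper` closed form rather than a
  summation loop: exact, vectorized, and stable for pools of half a
  million reads.
* Detection limits interpolate on the log-fraction scale because the
  sensitivity curve is close to linear in log f near the crossing.
* Monte-Carlo problem sizes in the tests (hundreds of molecules per
  library, hundreds of seeds, 1000 iterations per grid point) were
  chosen so the whole suite exercises every stage in a couple of
  minutes while keeping Monte-Carlo standard errors well inside the
  asserted tolerances.

## Reproducibility

`synth_config(seed = )` makes the generator bit-for-bit reproducible,
and `simulate_sensitivity()` consumes the ambient RNG stream, so
`set.seed()` before the call pins the whole curve. The acceptance script
(`scripts/acceptance.R`) recomputes the headline detection limits from
scratch at a caller-supplied seed.

## Limitations

The package tracks single-nucleotide variants only — no indels,
rearrangement breakpoints or copy-number signal. The consensus cannot
remove first-cycle PCR errors (that requires molecular barcodes), and
the simulator treats all tracked sites as exchangeable, ignoring
site-to-site depth variance beyond the binomial draw. Mappability is
consumed as pre-thresholded intervals; computing it from sequence is out
of scope. Tumor-tissue variant calling, alignment and base recalibration
are upstream of this package and assumed done.
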