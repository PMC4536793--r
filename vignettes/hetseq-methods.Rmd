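---
title: "Models and methods behind hetseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hetseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetseq)
```

# Scope

`hetseq` implements the computational core of a fission-yeast
regulatory-genomics workflow: identifying the RNA targets of an
immunoprecipitated RNA-binding protein from two-channel RIP-chip arrays,
calling differential expression in deadenylase mutants, quantifying
gene-set overlaps, measuring heterochromatin integrity as H3-normalized
H3K9 di-methylation occupancy from ChIP-seq, and confirming individual
loci by ΔΔCt qPCR.  Wet-lab steps, read alignment, decay-rate chemistry
and genome-browser rendering are out of scope: the package consumes
gene-level log-ratios, aligned reads (BED or SAM) and Ct tables.

Every stage has a seeded generator that produces its input with planted
ground truth, so the whole pipeline can be validated by recovery rather
than by eyeballing.

# RIP-chip target calling

Enrichments (IP versus total RNA) arrive as log2 ratios, one column per
biological replicate.  Each array is mean-centred over its non-missing
cells and converted to z-scores using the sample standard deviation
(`n − 1`); the n−1 choice is immaterial at array scale but is fixed so
results are exactly reproducible.  A transcript is called a target when
its z-score is *strictly* above the threshold (default 2.5) in at least
`k` of `n` replicates — both of two duplicates, or two of three
triplicates.  The rule is parameterized because both variants are in
routine use.  Strictness at the threshold is a literal reading; ties at
exactly 2.5 have probability zero on continuous data.

Transcripts with a missing z-score in some replicate are judged on the
remaining replicates against the same `k`: an undetected probe cannot
contribute evidence for or against.  Which probes count as "detected" in
the first place is a pre-filter that differs between platforms; `hetseq`
leaves it to the caller (missing cells in the input matrix), rather than
hard-coding an intensity cutoff.  Likewise, centring and the z-score
standard deviation are computed per array; computing them jointly across
arrays is a defensible alternative, but per-array is what makes calls
invariant to per-array offsets and gains, which is the property the
procedure relies on.

# Differential expression: one-class SAM

Each expression array is already a mutant/wild-type ratio, so the design
is one-class: the null hypothesis per gene is mean log-ratio zero.  The
moderated statistic is

\[ d_g = \frac{\bar m_g}{se_g + s_0} \]

with \(\bar m_g\) the mean replicate log-ratio, \(se_g\) its standard
error and \(s_0\) an exchangeability constant that stops genes with
accidentally tiny variance from dominating the ranking.

**Choice of \(s_0\).**  By default `hetseq` tunes \(s_0\) the way the SAM
method itself does: candidate values are quantiles of the gene-wise
standard errors, and the selected one minimizes the coefficient of
variation of the spread (MAD) of \(d\) across strata of \(se\).  A fixed
low quantile (say the 5th percentile) is available via
`s0_method = "quantile"`, but it barely regularizes the smallest-variance
genes, which leaves the null distribution of \(d\) with heavy t-like
tails and visibly inflates the tail counts that drive the FDR estimate;
with 3 replicates this costs most of the detection power at stringent
FDR.  The CV-minimizing rule is therefore the default.

**Permutation null.**  The null is built by sign-flipping whole arrays:
each permutation multiplies every column by an independent random sign,
which is exchangeable when the ratio noise is symmetric around zero.
Flipping cells independently per gene would be a mistake worth spelling
out: a truly regulated gene keeps all its replicates the same sign with
probability \(2^{1-n}\), so with 3 replicates a quarter of the planted
genes reappear in *every* permutation with \(|d^\*| = |d|\),
contaminating the null beyond repair.  Array-wise flips concentrate that
contamination into the rare all-same-sign permutations, which the
median across permutations then discards.

**q-values.**  For gene \(g\), the q-value is the median over
permutations of the count of null \(|d^\*| \ge |d_g|\), divided by the
observed count of \(|d| \ge |d_g|\), capped at 1.  Genes with
`q < fdr_threshold` (default 0.005) are called and reported separately as
up- and down-regulated by the sign of the mean log-ratio.  The contract
is at the level of FDR behaviour — calibration under the global null and
power on planted effects — not numerical identity with any particular
SAM implementation.

Loess normalization (`loess_normalize()`, built on `limma::loessFit`)
removes smooth intensity-dependent dye bias per array before testing;
median-centring is provided for stability-ratio inputs.

# Gene-set overlaps

For sets of sizes \(n_a\) and \(n_b\) in a universe of \(N\) genes the
expected random overlap is the hypergeometric mean \(n_a n_b / N\), and
significance is the one-sided (enrichment) Fisher exact p-value, equal to
the hypergeometric upper tail \(P(X \ge \text{observed})\).  Enrichment
is the only direction the pipeline ever claims, so the test is
one-sided; no multiple-testing correction is applied across panels, and
raw per-comparison p-values are reported.  The universe is a mandatory
argument: whether it is "all detected genes" or "the whole annotation"
changes both the expectation and the p-value materially, so no hidden
default is offered.

# ChIP-seq occupancy

Features are flat intervals (genes, islands, subtelomeric blocks,
centromeres, transposons, HOODs) in 0-based half-open coordinates; GFF3
input is converted at the boundary.  Features may overlap — islands
deliberately cover their host genes — and are never de-overlapped.

A read is assigned to every feature containing its *start* position.
The single-point rule makes counts additive, boundary behaviour exact,
and the treatment of overlapping features explicit (each receives the
read); midpoint assignment is available as an option.  Counting is
strand-agnostic.  RPKM uses the total aligned reads of the sample as the
per-million denominator, the most natural reading of per-million-reads
normalization; only primary alignments are counted from SAM input.

Methylation density is the feature's H3K9me2 RPKM divided by its histone
H3 RPKM, which cancels nucleosome occupancy; where the H3 signal is zero
the ratio is flagged undefined (`NA`), never zero.  Background is the
median ratio over all non-heterochromatin features, per replicate — the
median is robust to the small fraction of genes that genuinely sit under
islands.  A feature is *enriched* at `enrichment_factor` (default 2)
times background in every replicate, and *reduced* in a mutant when the
mutant/wild-type ratio of ratios is at most `1/reduction_factor`
(default 2) in every replicate pairing.  The source analyses describe
these calls only as "reproducible" and "clear"; the numeric factors are
this package's operationalization, are configurable, and are echoed into
every run manifest so they are auditable.  "Every replicate" is the
strictest reading of reproducibility; a k-of-n option is exposed.  H3
folds are computed in parallel so that methylation loss can be
distinguished from histone loss.

# The synthetic-data generators

One master seed drives deterministic per-generator substreams, so each
stage's input is bit-reproducible regardless of call order.

* **Genome** (`make_genome()`): two chromosomes with genes tiled at a
  1.5-kb pitch (1.2-kb bodies), four subtelomeric ends each split into a
  5-kb distal "nucleation" sub-block and a 10-kb proximal block, one
  16-kb centromere, a transposon and a HOOD block, and 21 candidate
  islands of 2 kb placed over host genes, two of which are non-coding.
  These proportions mimic a compact fission-yeast-like genome (5000
  genes over ~7.7 Mb at defaults).
* **Truth** (`plant_truth()`): 6 of the 21 islands are methylated (4
  over mRNAs, 2 over ncRNAs); in the mutant, 5 islands and all proximal
  subtelomeric blocks lose their methylation excess while distal
  sub-blocks and the centromere are untouched.  Bound targets (default
  50 of 5000) include the methylated-island hosts; a third of the
  up-regulated set is drawn from the targets so target/DE overlap is
  planted and detectable.
* **RIP-chip / expression**: Gaussian log2 noise (sd 0.5 and 0.3)
  around planted shifts of +3.0 (targets) and ±1.5 (DE genes; 75% up).
  An optional smooth additive dye bias along mean intensity exercises
  the loess step.
* **ChIP reads**: piecewise-constant read density — background 1,
  methylated domains 8-fold, lost domains retaining 20% of the excess in
  the mutant — sampled exactly via a multinomial over intervals, with
  uniform H3 and input channels (optionally a piecewise variable
  nucleosome profile multiplying all chromatin channels, which the H3
  normalization must cancel).  Reads are emitted as already-aligned
  50-bp coordinates; alignment is out of scope.  The default depth of
  8×10^5 reads per channel is chosen so that *both* channels of the
  me2/H3 ratio see at least ~200 expected reads per 2-kb island (~208
  for H3, ~1530 for H3K9me2): the ratio's sampling noise is dominated by
  its thinner channel, and island-level fold calls need that channel,
  not just the numerator, adequately covered.
* **qPCR**: Ct quartets constructed so the standard ΔΔCt computation
  returns the configured true ratio exactly at zero noise, plus
  per-well Gaussian cycle noise.

What the generators deliberately do **not** model: probe
cross-hybridization, spot-quality artefacts, PCR amplification and GC
bias, multi-mapping reads, fragment-length effects, or correlated noise
between replicates.  Passing recovery tests on this synthetic data
therefore demonstrates the correctness and calibration of the
*computations*, not robustness to every artefact of real arrays or
libraries.

# ΔΔCt quantification

The relative level of a target versus a reference locus between IP and
input fractions is \(2^{-\Delta\Delta Ct}\) with
\(\Delta\Delta Ct = (Ct_{t,IP} - Ct_{r,IP}) - (Ct_{t,IN} - Ct_{r,IN})\),
assuming PCR efficiency 2 with no efficiency correction.  Printed
versions of this formula sometimes typeset the exponent so that it reads
as the *sum* of the two deltas while still labelling it ΔΔCt; since the
label names the standard difference-of-differences method, that is what
`hetseq` computes, and the literal sum-of-deltas reading is available
behind `variant = "literal"` for comparison.  Replicate ratios are
aggregated by geometric mean (ratios are log-scale quantities); the
arithmetic mean is an option.  The ratio is invariant to a constant
cycle shift across all four wells (machine drift) and inverts exactly
when target and reference roles are swapped.

# Numerical and interface choices

* Internal coordinates are 0-based half-open everywhere; conversions
  happen only at file boundaries (GFF3, SAM).  This prevents
  off-by-one drift between modules.
* A constant z-score column yields all-zero z-scores rather than an
  error; a zero H3 denominator yields `NA`; a gene with fewer than two
  finite replicates gets `NA` statistics and is never called.
* `sam_fdr()` refuses to run without a seed and with fewer than 50
  permutations.
* Stage orchestration (`run_stage()`) validates all inputs before
  writing anything, writes result tables atomically into the output
  directory, and always emits a manifest echoing the seed and every
  parameter; manifests contain no timestamps so re-runs are
  byte-identical.

# Problem sizes used in validation

The shipped test-suite and the acceptance script exercise the pipeline
at the study scale the generators default to: 5000 genes with 50 planted
targets (10 seeds) for RIP-chip recovery; 5000 genes, 3 replicates and
100 permutations for FDR calibration (20 null seeds) and power (5
seeds); full default genomes with 8×10^5 reads per channel for ten
occupancy seeds; 10^4 Monte-Carlo draws for the expected-overlap law;
and exhaustive enumeration of every overlap instance with a universe of
at most 12 genes as the Fisher oracle.  These sizes were chosen as the
smallest that make the planted effects statistically unambiguous.

# Worked example

```{r demo, eval = FALSE}
library(hetseq)
report <- run_demo(seed = 1)
report
```

`run_demo()` generates a toy genome, runs every stage, and scores
recovery against the planted truth (see the README for the printed
output of this exact call).

# Known limitations

* The RIP-chip "detected RNAs" pre-filter and the universe used for
  overlap statistics are caller responsibilities; defaults cannot claim
  identity with any particular published gene list.
* The permutation FDR is a Monte-Carlo estimate; with 100 permutations
  the q-value resolution near zero is limited by the null tail counts,
  which is why seeds are mandatory.
* Occupancy thresholds (2-fold enrichment, 2-fold reduction) are
  reasonable defaults for strong heterochromatin signals, not universal
  constants; weak or graded domains will need re-tuning and the calls
  report the factors used.
* Multi-mapping reads are out of scope; SAM ingestion keeps primary
  alignments only.
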