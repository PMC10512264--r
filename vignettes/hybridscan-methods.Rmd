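---
title: "Methods: depth-based karyotyping, ancestry and LOH in hybrid genomes"
author: "hybridscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-based karyotyping, ancestry and LOH in hybrid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridscan)
```

Interspecific hybrids — budding yeast being the motivating system — carry two
parental subgenomes whose divergence ranges from roughly 10% to above 20% at
the nucleotide level. Such genomes are unstable: whole chromosomes are gained
and lost, one parent's contribution can dwindle to a small minority, the
mitochondrial genome resolves to a single (homoplasmic) donor, and
heterozygous regions collapse to one parent's alleles (loss of
heterozygosity, LOH). `hybridscan` implements the short-read analyses used to
quantify these phenomena, plus a synthetic cohort generator that makes every
stage verifiable by parameter recovery: each analysis is run on data whose
ground truth is known exactly, and is judged by whether it recovers the
planted parameters.

## Ancestry from diagnostic k-mers

Competitive mapping pipelines map reads against a concatenation of candidate
parent references and keep confidently placed reads (a mapping-quality
filter). `hybridscan` replaces the aligner with a *diagnostic k-mer index*:
every canonical k-mer (the lexicographic minimum of a k-mer and its reverse
complement; k odd so no k-mer is its own reverse complement) that occurs in
exactly one parent genome is indexed with its first occurrence position.
K-mers found in two or more species are counted but never used. At parental
divergence $d$, the chance that a k-mer window overlaps at least one
substituted site is $1-(1-d)^k$; at $d = 0.10$ and the default $k = 17$
about 83% of each genome's distinct k-mers are diagnostic, so a 100 bp read
typically carries dozens of informative k-mers.

A read is assigned to the species with the most diagnostic hits when that
count reaches `min_hits` (default 2) and leads the runner-up by
`min_margin` (default 2) — two independent diagnostic k-mers suppress hits
produced by sequencing errors, playing the role of the mapping-quality
cutoff. Ties and weak evidence yield `AMBIGUOUS`, zero hits `UNASSIGNED`,
and the three fractions close to one by construction. The read's placement
is the reference position of its first diagnostic hit minus that k-mer's
offset in the read; on collinear genomes this is exact for error-free hits,
which is ample for 10-kb windowing and marker genotyping but is not
base-level alignment.

Contribution estimates are read fractions over all reads of a sample.
A sample enters cohort analyses when at least 85% of its reads are
confidently assigned and exactly two species each hold at least 5% of the
assigned reads (the two-parent rule). The 85% threshold is the standard
high-quality-mapping cutoff for this analysis; the 5% minor-contribution
floor separates small introgressions from a genuine second parent and is a
configurable parameter, since no canonical value exists for where a
"significant" parental contribution begins.

Mitochondrial inheritance is classified against a separate index in which
every (species, clade) haplotype is its own unit — some species carry two
deeply divergent mitochondrial clades, and donor identification must survive
that. Reads are routed to whichever index scores them better, with the
mitochondrial index winning ties (organelles are heavily over-represented in
read sets). A species' mitochondrial score is the *maximum* over its clades,
and the majority donor is the argmax across species; samples with no
mitochondrial signal or an exact tie are flagged rather than called.
Concordance between the nuclear majority and the mitochondrial donor is
tested by comparing majority-nuclear percentages between concordant and
discordant samples with Welch's unequal-variance t-test
(Welch–Satterthwaite degrees of freedom); when either group has fewer than
two members the result is reported as `NOT_TESTABLE`, a value rather than an
error, since a one-member group admits no variance estimate.

## Read-depth karyotyping

Depth is computed in non-overlapping windows of nominally 10 kb per
(species, chromosome); the final window of a chromosome may be short and is
retained with width-weighting rather than dropped — small chromosomes are
precisely the objects of interest and discarding their terminal windows
would bias them. Windows whose mean depth strictly exceeds twice their
chromosome's mean window depth (one unit on the log2 scale) are masked as
suspected collapsed repeats and excluded from every downstream statistic.
The chromosome mean in this rule is computed in a single pass over all
windows including the candidate; an iterative variant that re-computes the
mean after each exclusion round is available behind a flag (`iterative =
TRUE`), the one-pass form being the default for determinism.

Chromosome depth sums the two homeologous subgenome means,
$D_c = D_{c,\mathrm{sp1}} + D_{c,\mathrm{sp2}}$. The genome-wide baseline
$D_G$ is defined as **twice** the width-weighted mean of all unmasked
per-subgenome window depths: it is the expected total (homeolog-summed)
depth of a euploid chromosome, so that $D_c / D_G = 1$ for a balanced
euploid chromosome regardless of overall coverage, and the aneuploidy rule
can be applied directly. A chromosome is called `GAIN` when
$D_c > 1.3\,D_G$ and `LOSS` when $D_c < 0.7\,D_G$, with *strict*
inequalities at both the 30% call threshold and the 2x mask threshold:
depth sitting exactly on a boundary is not evidence of change. A chromosome
whose windows are entirely masked on either side is flagged and excluded
from calls.

Note that a trisomy of a chromosome of length $L_c$ in a genome of haploid
size $L_G$ raises $D_G$ itself slightly; its expected relative depth is
$1.5/(1 + L_c/2L_G)$ rather than exactly 1.5. With the default karyotype
(largest chromosome 32 kb of 162 kb) the expectation stays above 1.36,
comfortably clear of the 1.3 threshold at 20x coverage, where the sampling
noise of a chromosome mean is below 1%.

Per-genome instability is summarized by the number of gains and losses
(genomes with both are flagged — a distinct category in cohort summaries),
the *sample* variance (n−1 denominator) of the chromosome totals $D_c$ —
genomes are treated as samples of a stochastic process; the population
variant is a one-line change — and the per-chromosome deviation
$\Delta_c = |D_c - D_G|$. The relationship between instability and
chromosome size is quantified by ordinary least squares of $\Delta_c$ on
$L_c$, per genome (requiring at least three chromosomes and non-degenerate
lengths) and pooled across genomes with Pearson's r and its two-sided p.
When all $\Delta_c$ are zero the slope is 0, r is reported as 0 by
convention and the fit is flagged. Cross-level heatmaps normalize each
chromosome column two-sidedly: 0 at the smallest cross mean, 0.5 at the
overall mean, 1 at the largest, so that crosses are comparable per
chromosome even when absolute depth scales differ.

## Alignment-free shared k-mers

Samples are profiled as sets of canonical k-mers observed at least
`min_count` times — the threshold is inclusive (a k-mer seen exactly five
times is kept at the default `min_count = 5`), counting is exact and
in-memory (a 17-mer profile of a desk-scale genome holds a few hundred
thousand 8-byte codes; no probabilistic sketches are needed below tens of
megabases), and `min_count = 2` provides the sensitivity variant while
`min_count = 1` suits assembled genomes. Pairwise distance follows the
alignment-and-assembly-free form

$$D_{ij} = -\tfrac{1}{k}\,\ln\!\left(\frac{S_{ij}}{\min(n_i, n_j)}\right),$$

with $S_{ij}$ the shared count and $n_i$ the profile sizes. Coverage-based
corrections used by some alignment-free estimators are deliberately not
applied; the raw shared counts are always exported so any downstream
distance can be recomputed. Zero-overlap pairs would be infinitely distant;
they are capped at 1.1 times the largest finite distance and flagged, so
matrices stay finite for export. Matrices are written as square PHYLIP or as
NEXUS TAXA/DISTANCES blocks — the input formats of neighbor-net software —
with labels sanitized to the formats' dialect; network layout itself is out
of scope. Cross-level statistics split sample pairs into intra-cross and
inter-cross sets and correlate per-cross mean shared counts with the
parental genetic distance of each cross (the realized mismatch fraction,
which the simulator controls exactly).

Two simulated genomes at divergence $d$ share an expected
$\approx (1-d)^k$ of their k-mers, so shared counts between genome pairs
decrease monotonically in divergence — the calibration property the tests
assert. Two hybrids of the *same* simulated cross, by contrast, carry
identical parental templates and differ only through sampling, so
intra-cross shared counts track union profile size; real cohorts add
strain-level variation the simulator does not model (see Limitations).

## Loss of heterozygosity

Because the simulator's divergence model is substitution-only, the two
parent genomes stay collinear and single-nucleotide markers are simply the
differing sites, enumerated chromosome by chromosome. Genotyping is a
pileup surrogate: for every assigned read the *base observed at each marker
position it covers* is compared with the two parental alleles (other bases —
sequencing errors — are ignored), giving per-marker allele depths. A marker
is homozygous for a parent when that parent's allele holds at least
`purity = 0.9` of the supporting depth, `HET` otherwise, and `NO_CALL`
below `min_depth = 3`. Base-level genotyping matters here: classifying
whole reads by species would blur every LOH boundary by up to a read length,
whereas the observed base flips at the first marker inside the tract, so
recovered breakpoints land within one inter-marker interval (~10 bp at 10%
divergence) of the truth.

LOH segments are maximal runs of at least `min_run = 10` consecutive
same-parent homozygous markers, uninterrupted by `HET` or opposite-parent
calls; `NO_CALL` markers are transparent — missing data is not evidence of
heterozygosity. The run length and purity defaults are chosen so that at
divergence 0.10 and 20x coverage the chance of a false run from sequencing
error is negligible (<1e-4 per chromosome: a spurious segment needs ten
consecutive markers each mis-genotyped at ≥90% purity); both are
configurable since marker density scales with divergence. Segment
coordinates span the first to last marker of the run (end = last marker
position + 1). Per-sample LOH burden is the percentage of the genome
covered by segments; cohort maps report, per 10-kb bin and retained-parent
direction, the fraction of samples in which at least half the bin is
covered by a matching segment, after excluding samples in which either
parent contributed less than 20% of the nuclear genome. An optional BED
exclusion list supports masking subtelomeric regions in real data; the
simulator does not model subtelomeres, so it defaults to off. Copy-number
aware LOH (hemizygosity) is not inferred.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions every recovery analysis runs under:

| parameter | default | rationale |
|---|---|---|
| karyotype | 8 chromosomes, 32–10 kb (162 kb haploid) | enough chromosomes for per-genome regressions; sizes span a 3x range so size-biased aneuploidy is detectable; desk-scale runtimes |
| parental divergence | 0.10 (range 0–0.25 supported) | the low end of the hybrid cross spectrum, the hardest realistic case for marker density |
| contribution | 0.5 (0.5–0.9 exercised in tests) | spans balanced to strongly skewed two-parent hybrids |
| coverage | 20x, 100 bp single-end, 0.1% error | typical short-read survey depth; at 20x a chromosome mean has <1% sampling error |
| mito | 5 kb, 10:1 mito:nuclear depth | organelle over-representation in whole-genome libraries |
| mito clades | 1 per species (two-clade species supported) | exercises the max-over-clades donor rule |

Divergence is applied per site independently (substitution-only, never to
the same base), so the realized mismatch fraction is Binomial-distributed
around the target and the two parents remain collinear — which is what the
LOH marker logic assumes. Reads are single-end with uniform start positions
and Poisson counts per template; expected depth of each template is
proportional to its copy number weighted by its parent's contribution,
normalized over the actual copy numbers (total yield is what a sequencer
fixes, so an aneuploid genome dilutes, rather than adds to, its siblings'
depth). Reads are drawn from the forward strand; all k-mer matching is
canonical, so assignment is strand-agnostic and this costs no generality in
depth statistics. Repeat inserts contribute `copy_count − 1` extra sampled
copies of their interval, emulating a collapsed repeat's depth spike without
altering the reference. Sequencing errors are uniform substitutions drawn
through R's RNG, so a seed fixes the cohort byte-for-byte — reruns of the
full pipeline with one seed hash identically, which the tests assert.

What the generator does **not** emulate, and hence what passing recovery
tests do not demonstrate about real data: indels and structural variants
(coordinates stay collinear), segmental aneuploidy (calling is
whole-chromosome), GC and mappability bias (no depth normalization is
needed or implemented — real data should be pre-normalized or
repeat-masked upstream), paired-end information, base-quality modeling,
strain-level polymorphism within a species (intra-cross k-mer sharing is
therefore more uniform than in real cohorts), heteroplasmic or recombinant
mitochondria, and subtelomeric repeat families.

## Numerical choices and degenerate inputs

* Strict inequalities at the ±30% call and 2x mask boundaries; equality is
  never evidence.
* One-pass masking by default; the iterative fixed-point variant is opt-in.
* Window widths weight all means; short terminal windows are retained.
* k is restricted to odd values in 11–25 so that 2k-bit k-mer codes remain
  exactly representable in doubles; 17, the operative value, is central.
* Distance caps (zero-overlap pairs), flagged rather than silently dropped;
  empty profiles flag their matrix rows as undefined.
* Degenerate inputs are values, not crashes: all-window-masked chromosomes
  are excluded and flagged, <2 chromosomes give `NA` variance, zero-variance
  regressions are flagged, single-member concordance groups are
  `NOT_TESTABLE`, all-unassigned samples have undefined majorities, and
  mitochondrial ties are flagged.
* Seeds: every stochastic operation takes an explicit seed, runs in a local
  RNG scope (the caller's RNG stream is untouched), and derives child seeds
  below 2^31.

## Problem sizes

Recovery analyses run on 162-kb genomes at 10–20x coverage with cohorts of
20–40 samples — large enough that chromosome-mean sampling noise (<1%) is
far from the 30% call threshold and marker counts reach the thousands, small
enough that the full test suite and the acceptance script each complete in a
few minutes on one CPU. All statistics are relative (depth ratios,
fractions, per-site rates), so they transfer to full-size genomes unchanged;
only absolute runtimes and memory scale with genome size.
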