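---
title: "Profiling small-RNA libraries with srnaprofiler: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling small-RNA libraries with srnaprofiler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaprofiler)
```

# Scope

`srnaprofiler` re-implements, as a tested and reusable pipeline, the
analysis of a classic two-library small-RNA sequencing design: one deeply
sequenced case library and one control library (here labelled after the
motivating application, a Klinefelter-syndrome versus healthy-control
comparison of PBMC small RNAs). The stages are

1. read preprocessing (quality filter, 5' contaminant removal, 3' adapter
   trimming, 18-30 nt length filter, tag collapsing),
2. exact-match genome mapping and a priority annotation cascade,
3. novel miRNA candidate calling from stem-loop evidence,
4. Audic-Claverie differential expression of known miRNAs,
5. rule-based miRNA target prediction with a duplex MFE-ratio criterion,
6. hypergeometric GO enrichment of predicted target genes.

Because the raw sequencing data behind the motivating study were never
deposited, the package ships a synthetic-data module that generates every
input with known ground truth, and transcriptions of the study's two
printed result tables, whose internal arithmetic the package re-derives as
a fixture check (`verify_reference_tables()`).

# Preprocessing model

Reads are modelled as insert + 3' adapter suffix, the way a short-insert
small-RNA library is actually sequenced. Each read receives exactly one
fate, decided in a fixed order: quality rejection (mean Phred < 20 or any
N; the upstream protocol's quality rule is not specified more precisely,
so a conventional mean-quality gate is used), 5' adapter contaminant
(prefix match over at least 8 bases with at most one mismatch), missing 3'
adapter (when the adapter is required), and length. The adapter matcher
accepts one mismatch per ten aligned adapter bases and takes the left-most
acceptable start; the minimum overlap is 6 nt. The insert length window is
the inclusive `[18, 30]`: the source protocol isolates 18-30 nt RNA and
its own result tables contain 20- and 24-nt matures, so exclusive bounds
would contradict the data; both bounds are configurable.

Collapsing identical inserts yields *tags* (sequence + count), the unit of
all downstream work. Conservation (raw reads = kept + each rejection
reason) is asserted inside `preprocess_reads()` itself.

# Mapping and annotation cascade

Tags are mapped to the genome by perfect full-length match on both strands
(`map_exact()`, a k-mer seed index with full verification; minus-strand
hits are reported in plus-strand coordinates of the matched span). The
test-suite cross-checks it against a naive full scan.

Each genome-matched tag receives exactly one category. Interval classes
are tried in the priority order rRNA > scRNA > snoRNA > snRNA > piRNA >
tRNA > repeat > exon/intron — the order in which the upstream protocol
lists its discard classes; no tie-break beyond listing order is documented
anywhere, so the order is configurable. Overlap is strand-aware (sense
annotation is the norm for these classes) and requires at least one base.
Tags that survive the cascade are compared by exact sequence against the
known mature-miRNA set; the remainder are `unannotated` and feed the novel
miRNA caller. Multi-mapping tags keep all hits and are categorized over
the union of their hits.

Interval files are BED6 on disk (0-based half-open) and 1-based inclusive
internally. The 1-based inclusive convention is confirmed by the reference
novel-miRNA table, where every printed precursor length equals
`end - start + 1`.

# Stem-loop candidate calling

The upstream study predicted novel miRNAs with Mireap, whose internal
algorithm is not published; the package therefore uses a deliberately
minimal, fully documented stem-loop caller. For every genomic hit of an
unannotated tag, candidate precursor windows extend the mature locus by up
to 80 nt on each side on a 5-nt grid, keeping windows of 60-100 nt. Each
window is folded with a hairpin-restricted energy DP (below); a candidate
is accepted when

* fold MFE <= -18 kcal/mol,
* the terminal loop is 3-20 nt,
* the mature lies entirely within one arm (never across the loop), and
* at least 14 mature bases are paired.

The best accepted window per tag (lowest MFE, then narrowest, then
left-most — a deterministic tie-break) is reported, with the candidate
count equal to the tag count. Candidates from the two conditions are
intersected by identical mature sequence plus overlapping precursor loci.

## Energy model

The folder restricts the structure space to a single stem-loop (one
terminal loop, a stem with bulges and interior loops, no multiloops or
pseudoknots) — exactly the evidence class used to nominate pre-miRNAs.
Constants, on a kcal/mol-like scale:

| term | value |
|---|---|
| pair strength G:C / A:U / G:U | 3.3 / 0.9 / 1.0 |
| stacked pair contribution | -(s1 + s2)/2 per stack |
| interior loop / bulge | +1.0 + 0.3 per unpaired nt (up to 6 nt per side) |
| terminal loop | +0.5 + 0.1 per loop nt |

Isolated pairs carry no stabilizing term, so unstructured sequences fold
to exactly 0. This is not a thermodynamic parameter set and absolute MFE
values of real precursors are out of scope (the reference table's printed
MFE column derives from sequences that are not reproducible here); what
the pipeline relies on — and what the tests assert — are relative
properties: perfect stems score far below the -18 threshold, homopolymers
score 0, and extending a stem by a complementary pair never raises the
energy. The DP is `O(n^2 B^2)` per window (`B` = maximum bulge span) and
is implemented in C++.

The same constant scale prices the ungapped miRNA:target duplexes of the
target-prediction module (stacked pairs plus +0.5 per interior mismatch
run, capped at 0). Rule vi uses only the *ratio* of the duplex energy to
the perfect-complement energy, so any internally consistent scale serves.

# Differential expression

Counts are normalized to reads per million (RPM): `count / total * 1e6`,
with the library total being all clean small-RNA reads. A zero count is
floored at 0.01 RPM before fold-change computation — the reference DE
table itself evidences this floor (a printed normalized value of 0.01 that
is far below the smallest attainable nonzero RPM at the reported library
sizes). Raw counts are never floored for the p-value.

The significance of a difference between counts `x` (case, library total
N1) and `y` (control, total N2) uses the Audic-Claverie count statistic:

$$p(x\mid y)=\left(\frac{N_2}{N_1}\right)^{y}\frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}$$

evaluated with log-gamma so million-scale counts do not overflow. The
source describes only this point probability; the package constructs
one-sided p-values as cumulative tails over `y` at fixed `x`, and a
two-sided p-value as twice the smaller tail, capped at 1. Each tail is
summed directly on its own side of the distribution mode, never through
`1 - (near one)`, so deep tails (p ~ 1e-200, which the reference table
contains) keep full relative precision. Because the tail convention of the
original analysis is not recoverable, printed p-values are not an
acceptance surface; the statistic itself is validated against brute-force
summation instead.

A species is called `up`/`down` when |log2 fold change| >= 1 **and** the
raw p <= 0.001 (the final criterion stated by the source protocol); an FDR
<= 0.01 gate (Benjamini-Hochberg) is available as the alternative, since
both thresholds appear in the protocol. One documented quirk: the
reference table's footnote defines fold change as log2(case/control), but
every printed row computes as log2(control/case). The pipeline reproduces
the numeric convention (`log2(control_std / case_std)`) and documents it
rather than guessing which was intended.

# Target rules

Sites are ungapped windows of the miRNA's length, scanned antisense over
every transcript; position 1 is the miRNA 5' base. The six rules: (i)
mismatch score <= 4 with G:U counting 0.5; (ii) no run of more than two
adjacent mismatches; (iii) no adjacent mismatches in positions 2-12; (iv)
no mismatch at positions 10-11; (v) score <= 2.5 in positions 1-12; (vi)
duplex MFE >= 75% of the perfect-complement MFE (inclusive).

Two design decisions the source leaves open: duplexes are ungapped because
the positional rules (iii-v) are ill-defined under gaps, and a G:U wobble
is a *pair* for the adjacency rules ii-iv while still contributing 0.5 to
the numeric caps — the source attaches the 0.5 only to mismatch
*counting*. A strictness switch (`gu_as_mismatch = TRUE`) flips wobbles to
mismatches everywhere for users who read the rules the other way.

# Enrichment

GO enrichment is the upper hypergeometric tail P(X >= k) of drawing k
term-carrying genes in a target set of size n from a background of N genes
with K carriers. The background defaults to every gene carrying at least
one GO annotation in the supplied map (the source's "reference gene
background" is unspecified; a user list can override it), and genes with
no annotation are excluded from both N and n. No GO-graph ancestor
propagation is performed — the source gives no evidence of it. Raw
p-values (flagged at p < 0.001, the threshold the source reports) and BH
FDR are both emitted.

# Synthetic data: what it emulates, and what it does not

The generator is the package's study stand-in, not a tuning knob. The
stock design (`default_design()`) fixes the conditions used throughout the
tests:

* 24 known miRNAs spanning four orders of magnitude (200,000 down to 100
  expected RPM), the most abundant dominating both libraries the way a
  let-7 family member dominates real PBMC libraries;
* 12 of them truly differential at 4-fold (six up, six down in the
  control-like condition), baselines 100-3,840 RPM;
* 5 novel matures carried on planted hairpins (designed RPM 500-3,000),
  present in both conditions;
* one fragment each of rRNA, tRNA, snoRNA, repeat and exon classes with
  matching annotation intervals, rRNA dominating, to exercise the cascade.

Reads are drawn from a multinomial over the design's expected RPM,
carry the full 3' adapter as sequenced, and receive 0.1%/base substitution
errors — never within the first 18 insert bases, so tag counting stays
deterministic at test scale. Planted hairpins embed the mature in one arm
against a reverse-complement arm with up to three designed mismatches.
Library sizes in the tests are 20,000-100,000 reads — within the 1e4-1e6
range the design targets and small enough that the complete suite runs in
minutes on one core; genome size is ~20 kb.

What passing tests therefore do **not** show: behaviour under realistic
quality-score noise, PCR duplication, multi-mapping at hg-scale genome
complexity, isomiR heterogeneity, or adapter dimer pathologies. The
simulator writes machine-readable truth tables precisely so that what *is*
asserted — conservation, exact recovery at zero error rate, >= 90% hairpin
recovery at >= 500 RPM over ten seeds, null false-call rate <= 1% and >=
90% power for 4-fold effects at >= 100 RPM — is checked against ground
truth rather than against the implementation itself.

# Numerical and testing choices

* All generators and the pipeline are deterministic given a seed; the
  end-to-end bundle is byte-identical on re-run and carries md5 checksums.
* Reference-table transcriptions keep typeset Unicode minus signs; the
  location parser normalizes them, which doubles as a parser test.
* Fold-change reproduction on the reference DE table is asserted to
  1e-4 absolute (the printed precision); the count-statistic tails are
  asserted to 1e-12 against direct summation for all x + y <= 50; the
  rule engine is compared exhaustively against a naive checker over
  reduced-alphabet duplexes through length 12.
* The DE null/power simulation uses 200 species on a log-spaced abundance
  ladder at 100,000 reads per library with a filler pool standing in for
  the non-miRNA read mass, 500 null replicates, 100 effect replicates.
* Tie-breaks (candidate window choice, tag ordering) are documented and
  deterministic, so order-independence holds by construction.

# Known limitations

* The hairpin energy model is ordinal, not thermodynamic; MFE values are
  comparable only within this package.
* The caller reports one candidate per tag (its best window over at most
  four genomic hits); paralogous precursor families collapse onto one
  locus.
* The annotation cascade decides on the union of hits, so one annotated
  locus outvotes any number of unannotated ones — the behaviour of the
  original discard-style filtering, but worth knowing for repeat-heavy
  tags.
* Single-library-per-condition designs have no biological replication;
  the Audic-Claverie statistic models sampling noise only, and the
  up/equal/down labels inherit that limitation.
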