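---
title: "Methods: two-library small RNA, degradome and qPCR analysis in chillmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA, degradome and qPCR analysis in chillmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillmir)
```

chillmir implements the computational pipeline used to identify
chilling-responsive microRNAs and their cleavage targets in a two-library
plant experiment: a chilling-treated (CT) and an untreated (NT) small RNA
library, each pooled over several sampling time points, together with
matched degradome (PARE) libraries and qPCR validation assays. This
vignette explains each stage's model and assumptions, the tunable
parameters and their defaults, and the design decisions taken where the
procedure admits more than one reasonable reading.

## Read cleaning and tag classification

Reads are trimmed at the first occurrence of the 3' sequencing adapter
(the insert is everything 5' of it); reads without a detectable adapter
are assigned to the `3ADT&length` class rather than silently dropped, as
are inserts outside the retention window. Two length windows coexist on
purpose:

* **retention window**, default 15--29 nt: what survives preprocessing and
  enters the composition table;
* **candidacy window**, default 19--24 nt: what may become a miRNA call.

Both are configurable (`run_config()`), because summary statistics are
conventionally reported on the wider window while miRNA identification
uses the narrower one.

"Junk" has no standard definition; the default rule removes reads whose
most frequent base makes up at least 80% of the insert (homopolymer-like
reads) or that contain a non-nucleotide character.

Unique tags are classified by exact substring search against the
contaminant sets in a fixed precedence order — rRNA, tRNA, snoRNA, snRNA,
other Rfam, mRNA, repeat — with the first hit winning; tags matching none
of the sets but mapping to the genome (either strand) are **clean**, and
tags matching nothing are discarded as `unmapped`. The precedence order is
a determinism device: a tag matching two sets must receive exactly one
label, and RNA-family databases are checked before the broader mRNA and
repeat collections. Matching is exact (0 mismatches) — the strictest
deterministic choice for synthetic-scale references.

Composition percentages are count/raw x 100 rounded **half-up** to two
decimals (`percent_of()`); half-up, not banker's rounding, is what
reproduces published summary tables of this kind digit-for-digit. One
quirk worth documenting: in published tables of this layout the
Rfam-subcategory rows sometimes report unique-read percentages against the
*total*-read denominator; the bundled reference fixture
(`inst/extdata/srna_library_stats.tsv`) records the denominator per row so
the recomputation check is explicit about it.

## Conserved miRNA identification

A candidate tag matches a known mature miRNA when an ungapped comparison
anchored at the 5' ends shows at most **1 mismatch within positions 1--16**
and at most **3 mismatches in total**. When the two sequences differ in
length the comparison runs over the shorter length and overhanging bases
are not counted as mismatches: the 5' end is the biologically conserved
part of a mature miRNA, so anchoring there and tolerating 3' raggedness is
the natural reading of a length-agnostic mismatch rule. The best match has
the fewest total mismatches, with lexicographic id order breaking ties
(determinism again).

Tags that match no known mature but sit verbatim inside a known hairpin
are "new flanking products": they are reported as conserved calls with a
`-p5`/`-p3` suffix according to the side of the hairpin they occupy,
mirroring the p5/p3 naming convention for such sequences.

## Novel miRNA identification

An unmatched clean tag is mapped exactly to the genome, and candidate
precursors are excised by extending the locus with every asymmetric
combination of flank sizes {20, 60, 120, 200} nt, clipped at chromosome
ends. Each window is folded and evaluated:

* the mature must lie entirely on one arm (no terminal-loop overlap);
* at most 4 unpaired mature positions against the star region;
* no asymmetric bulge larger than 2 nt inside the duplex;
* a star span derivable with a 2-nt 3' overhang.

These are the community structural criteria for plant miRNA annotation;
all four numbers are arguments of `evaluate_hairpin()`.

The hairpin-quality filter is the minimal folding free energy index:

AMFE = -MFE / length x 100,  MFEI = AMFE / GC%

and a precursor qualifies when **MFEI > 0.80** (strictly; `compute_mfei()`
treats 0.80 itself as a non-candidate). The MFEI formula is the standard
one from the plant miRNA prediction literature; only the 0.80 threshold is
specific to this analysis. Among windows that pass, the call keeps the
highest-MFEI window (lexicographic precursor id on ties). Novel calls are
named `PC-<n>-<arm>` ("predicted candidate"), numbered in the
deterministic tag order of discovery.

### The built-in folder

Thermodynamic folders (UNAfold, ViennaRNA) are pluggable backends, but the
reference folder shipped with the package is deliberately simple: a
dynamic program over nested (pseudoknot-free) structures minimizing a
per-pair stacking energy of G:C −3, A:U −2, G:U −1 kcal/mol with a
minimum hairpin loop of 3 nt, implemented in C++ and verified in the test
suite against exhaustive enumeration of all nested structures for
sequences up to 12 nt. A simple additive model keeps every downstream
number reproducible without an external dependency; its MFE values are
systematically larger in magnitude than thermodynamic ones, which is why
the MFEI threshold should be interpreted relative to the folder in use
(planted synthetic hairpins clear 0.80 by a wide margin under either).
`fold_rna(backend = "vienna")` delegates to RNAfold when it is on the
PATH. Traceback preference (pair > 5'-unpaired > 3'-unpaired > smallest
bifurcation) makes the reported structure, not just the energy,
deterministic.

## Two-library differential expression

With only one pooled library per condition there are no biological
replicates, so the comparison is a per-feature 2x2 count test: the table
(feature count, remaining clean reads) x (CT, NT) is tested with the
Pearson chi-square test (1 df, no continuity correction) and the
two-sided Fisher exact test (point-probability method). Counts are
normalized to counts per million clean reads for reporting, and the
effect size is log2(CT/NT) after adding a pseudocount (default 0.5
per-million units) so features present in only one library remain finite;
such features are additionally flagged by `in_CT`/`in_NT` presence and
the Venn partition. A feature is **significantly regulated** when both
p-values are below 0.05 *and* |log2(CT/NT)| >= 1. No multiple-testing
correction is applied by default, matching the raw-p convention of this
analysis style; `diff_expression(adjust = TRUE)` adds Benjamini-Hochberg
columns without changing the call.

The test suite checks the Fisher p-value against full hypergeometric
enumeration and verifies that the chi-square test keeps its nominal 5%
type-I error (within 3 percentage points) under a null simulation of two
identical multinomial libraries (1,000 features, 200 replicate pairs,
expected count 20 per feature).

## Degradome target calling

Degradome tags mark the uncapped 5' ends of cleavage products. Tags are
mapped to the transcriptome by exact sense-strand matching; a tag
contributes its count at the transcript position of its 5' end, and
multi-mapping tags count at every match (documented behaviour, shared by
tag-counting degradome tools). Abundances are scaled to **tags per
billion** (count / total mapped x 1e9).

Duplex scoring follows the penalty scheme: Watson-Crick 0, G:U wobble
0.5, mismatch or single-nucleotide bulge 1, with every penalty **doubled
in the core region, miRNA positions 2--13**. The scanner slides an
antiparallel window over the transcript; with `max_bulges = 1` (default)
site lengths of miRNA length ±1 are also tried, with the single bulge
placed to minimize the score. Sites with penalty <= 7 are kept — the
cutoff is not part of the published scheme, so 7.0 (a common convention
for this scoring family) is the documented, configurable default.

The expected cleavage position is the transcript base paired to **miRNA
position 10** (for an ungapped site, `site_start + site_length − 10`), and
a tag's 5' end must sit exactly there — no ±1 tolerance. Each profile is
summarized as a t-plot (per-position abundance, maximum, and median over
positions with *nonzero* abundance) and the site is classified:

| category | rule (site raw count x) |
|---|---|
| 4 | x = 1 (a single raw read) |
| 0 | x > 1 and the unique maximum on the transcript |
| 1 | x > 1, equal to a maximum attained at > 1 position |
| 2 | x > 1, strictly between the median and the maximum |
| 3 | x > 1, at or below the median |

Two readings required a decision. First, the published category-0 wording
is garbled relative to categories 1--3; the unique-maximum reading adopted
here is the one that makes the five categories a partition. Second, "below
the median" is read inclusively (<=) so categories 2 and 3 tile the range
cleanly; `categorize_site(median_rule = "strict")` gives the strict
alternative. The median is taken over nonzero positions because a
transcript's mostly-zero abundance vector would otherwise force the median
to 0 and empty category 3. A property test checks the classifier against
an independent rule trace over random profiles. Finally, `call_targets()`
reports one call per (miRNA, transcript, cleavage position) — the
best-scoring duplex — since bulged variants of the same site are the same
biological event.

## qPCR quantification

Ct tables are analysed by the 2^-ddCt method: technical replicates
(three per reaction by default) are averaged before dCt = Ct(target) −
Ct(reference); ddCt is taken against a calibrator sample whose expression
is defined as 1 (by convention the untreated library's first time point);
fold change = 2^−ddCt. One reference gene is used per assay type (5S
rRNA for miRNA assays, Actin for target genes). CT-versus-NT differences
per time point are tested on replicate-level fold changes with a Welch
t-test (pooled-variance optional); replicate aggregation by mean Ct and
the Welch default are standard practice where the original protocol says
only "t-test". Zero-variance degenerate groups are answered without a
division error (p = 1 for identical groups). No amplification-efficiency
correction is applied — the plain 2^-ddCt formula assumes efficiency 2.

## The synthetic-data generator

`gen_reference()` plants every ground truth the pipeline is later asked
to recover: hairpin precursors (perfect inverted repeats around each
mature, so they fold cleanly under any backend) embedded at recorded
genome loci; a known-mature/hairpin reference containing a configurable
subset of the planted matures (plus never-planted decoys); contaminant
reference sets per class with planted contaminant reads; transcripts
carrying exact reverse-complement target sites whose cleavage position is
the base paired to miRNA position 10; and per-sample qPCR fold changes.

Defaults emulate the pooled two-library design: 8 precursors (half in the
known set), pooled abundance 200 reads per miRNA in NT, planted CT/NT
fold changes cycling through {1, 4, 0.25, 1} (so both directions of
4-fold regulation and constants are present), contaminants at 40 reads
per class, 4 cleavage sites at 50 tags with fold changes {1, 4, 0.25, 1},
six time points (1, 4, 8, 12, 24, 48 h) whose per-time-point abundances
are integer splits summed back before read generation — the pooling is
explicit so that noise models can act per time point. Per-time-point
abundances before pooling are free parameters; no published values exist
for them. Reads are written as FASTQ with constant Q40 qualities;
sequences are RNA (U) internally, DNA (T) on disk, and readers
transliterate.

What the generator does **not** emulate: sequencing errors, quality-score
variation, ligation biases, expression dispersion across biological
replicates, or genome-scale reference complexity. Green recovery tests
therefore demonstrate the correctness of the algorithms under their own
assumptions — not the pipeline's sensitivity or specificity on real
sequencing data, where adapter variants, near-duplicate tags and
imperfect hairpins dominate the error budget.

Problem sizes: the bundled defaults (2 x 4 kb genome, 8 precursors, 6
transcripts of 500 nt, ~2,800 reads per library) were chosen so a full
end-to-end run, including folding all excised windows, completes in
seconds; the null-calibration simulation uses 1,000 features x 200
replicate library pairs. All sizes scale through `reference_params()`.

## Known limitations

* Exact-match classification and genome mapping make the preprocessing
  stages conservative; real references need mismatch-tolerant mapping.
* The built-in folder ignores stacking context, dangles and loop
  entropies; MFEI values are comparable only within one backend.
* The two-library tests treat pooled libraries as multinomial draws;
  without biological replicates the p-values quantify sampling noise, not
  biological variability.
* One single-nucleotide bulge per duplex is the only indel the scanner
  prices, per the published penalty scheme.
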