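---
title: "Methods and design of srnapipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of srnapipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`srnapipe` implements the classical provider-style small-RNA-seq analysis
for a three-library dormancy-release design in tree cambium: endodormancy
(SD8), ecodormancy (C5) and active growth (LD3). The unit of analysis is the
*clean tag* — a unique 18–30 nt sequence with one raw count per library. All
downstream statistics are functions of tag counts and library totals; there
are no biological replicates in the design, which is why expression testing
uses a count-based two-library statistic rather than a replicate-aware
model.

# Read cleaning

Reads are assigned to exactly one category, evaluated in a fixed order:
quality → 3' adapter presence → empty insert → 5' adapter contamination →
polyA → insert length. The order matters because a read must be
adapter-trimmed before its insert length can be judged. The published
accounting tables this mirrors never define "high quality", so the package
documents its own rule: a read is low-quality when its mean Phred score is
below 20 or more than 10% of its bases are N. Likewise undefined upstream
and therefore documented package choices:

* 3' adapter located by the first exact occurrence of its first 6 bases
  (`adapter_min_match`);
* polyA insert: a run of ≥ 6 A's and ≥ 70% A overall;
* inserts longer than 30 nt are counted as `adapter3_null` — the accounting
  table has no over-length category, and an adapter signal beyond position
  31 is indistinguishable from a missed adapter;
* reads already inside 18–30 nt with no adapter are treated as pre-trimmed,
  which makes cleaning idempotent on its own output.

The report enforces `high_quality = Σ removal categories + clean_reads` and
recomputes percentages (of the high-quality total) rounded half-up to two
decimals, the convention of the published tables; the bundled published
counts (`cambium_library_stats()`) round-trip exactly under this rule.

# Annotation hierarchy

Tags map to the genome by exact matching on both strands (`map_tags`), the
modern stand-in for the historical short-read aligner run with zero
mismatches. Classification assigns one category per tag with priority
miRNA > rRNA > tRNA > snRNA > snoRNA > repeat > exon > intron >
unannotated. Known-miRNA assignment is sequence-level (exact equality with
a mature reference after U/T normalization) and does not require a genome
hit, matching the way mature-reference matching is described independently
of genome mapping; the genome hits drive the remaining categories.
Multi-locus tags are counted once in the composition (per unique tag, as
the published table tallies them) with all loci retained in the records.
Ties between equal-priority features break on the lexicographically
smallest feature id, deterministically. The upstream study cites two
different mature-reference versions in different sections, so the reference
is a user input rather than a pinned version.

# Novel miRNA discovery

Unannotated mapped tags are clustered (gap ≤ 50 nt) and extended by 150 nt
per side — the flank default of MIREAP-style pipelines — clipped at
scaffold edges. Each window is folded and screened:

* mature length 20–23 nt;
* more than 5 reads in at least one library. The upstream phrasing ("all
  the unique sequences were identified in at least one library") is
  ambiguous about scope; it is implemented here as the count criterion
  applying within at least one library, and flagged as an interpretation;
* duplex criteria in the quantified Meyers-style form: ≥ 16 mature bases
  paired, ≤ 4 nt asymmetric bulge between mature and star, mature not
  spanning the loop;
* MFE ≤ −18 kcal/mol. The study reports only observed MFE means (−50 to
  −55 kcal/mol), never a threshold; −18 kcal/mol is the package's
  configurable acceptance bound, low enough to keep every plausible plant
  precursor and high enough to reject unstructured windows.

The mature arm is the most abundant member tag, ties broken 5'-most.
Candidates are deduplicated across loci and strands by mature sequence
(lowest MFE wins), making screening independent of input order.
`novel_mirna_stats` reports per-library counts, mean ± sample-sd MFE, and
the fraction of matures starting with 5' uridine (the AGO1-loading
signature; the generator plants 85% 5' U).

# The folding engine

The study used an external web folder; this package needs a deterministic,
dependency-free default, so it implements a Zuker-style dynamic program
(Rcpp) with a pluggable `backend` argument for an external folder.
The energy model is nearest-neighbor stacking for Watson–Crick and G:U
pairs from published stacking tables, with *linear* loop penalties — a
documented simplification of the full tabulated loop model:

* hairpin loop of n unpaired bases: 3.0 + 0.3 n kcal/mol (minimum n = 3);
* internal/bulge loop: 2.0 + 0.5 n, capped at 30 unpaired bases;
* multiloop: 3.4 + 0.4 per branch + 0.1 per unpaired base;
* external bases free; MFE is therefore always ≤ 0, and a sequence with no
  complementary stretches folds open at exactly 0.

The engine is validated two ways: the reported MFE must equal the
loop-decomposition energy of the reported structure, and on short
sequences (≤ 20 nt) it must equal exhaustive enumeration over all
pseudoknot-free structures under the same energy table (an independent
recursion in the test suite). Energies are means to a structural decision
here, not thermodynamic predictions: the absolute MFE values differ from
full Turner-model folders, which is why the acceptance threshold is a
package parameter and the published MFE means are not acceptance targets.

# Differential expression

Counts are normalized to reads per million; an exact zero is revised to
0.01 *after* normalization, and a miRNA below 1 RPM in every library is
removed. Fold change is `log2(normalized treatment / normalized control)`
with SD8 as control. Significance uses the Audic–Claverie statistic
p(y|x) with both cumulative tails C (y ≤ observed) and D (y ≥ observed)
reported. Numerical choices:

* the p-value always uses raw integer counts — the formula requires them —
  while the 0.01 revision affects only normalized values and fold changes;
* evaluation is in log-gamma space (no overflow into millions of reads);
  when the two library totals are equal and x + y ≤ 1000 the exact binomial
  closed form `choose(x+y, y) / 2^(x+y+1)` is used, which is exact in
  double arithmetic and makes the binomial-limit identity testable at
  machine precision;
* whichever tail is smaller is summed directly (the other follows from
  C + D = 1 + p(y|x)), avoiding catastrophic cancellation for extreme
  changes; the infinite upper sum truncates when the running term falls
  below 1e-12 of the accumulated mass (or underflows);
* the reported `p = min(C, D)` — the study prints both tails but never says
  which it reports; the smaller (one-sided) tail is this package's
  documented convention, and both are emitted;
* default thresholds p ≤ 0.01 and |log2FC| ≥ 1 (the study never defines
  "significant" numerically); no multiple-testing correction by default,
  as none is applied upstream, with an optional Benjamini–Hochberg switch.

# Target prediction and cleavage

The study delegated target prediction to a web service with unpublished
parameter values; this package adopts the classical plant target-rule
constants its citations describe: mismatch 1, G:U wobble 0.5, gap 2,
penalties doubled at miRNA positions 2–13, reporting cutoff 4. All five
constants are configurable. Scanning is ungapped-first with single-gap
(one-base bulge on either side) extension — bounded complexity at desk
scale. The scanner is a C++ window loop whose scores are re-derived per
hit by the R reference scorer (and checked for equality at run time); the
test suite additionally compares the scanner to brute-force rescoring of
every window. Cleavage is predicted between the two target bases pairing
miRNA positions 10 and 11 from the miRNA 5' end, the canonical RACE
signature; a gap across those positions makes the site indeterminate and
is an error, and the prediction is invariant to transcript padding.

# The synthetic world

The generator states the world once and the tests live in it:

* three libraries at 10^5 reads each — the lower end of the 10^5–10^6
  per-library scale, chosen for a one-CPU test budget;
* artifact fractions mirroring the published accounting (0.5% low quality,
  0.05% adapter-null, 0.02% empty insert, 0.15% 5' contamination, 1.3%
  short, 0.01% polyA), planted at exactly `round(fraction × depth)` reads
  so the cleaner's report can be compared to the manifest *exactly*;
* class composition mirroring the published annotation table (22% known
  miRNA, 23% rRNA, 4.5% tRNA, ~42% unannotated noise, the rest spread over
  snRNA/snoRNA/repeat/degradation);
* known-miRNA fold changes of {0, ±1, ±2} (log2) in C5 and LD3 versus SD8.
  The noise class absorbs the compositional slack so each planted tag keeps
  its nominal expected fraction in every library — planted fold changes are
  exact in expectation, not merely approximate;
* novel precursors built as arm + loop + reverse-complement arm, written
  into the genome so they genuinely fold under the package's own engine;
  85% of matures start with U;
* quality strings on a two-level model (Phred 40 / Phred 2) because "high
  quality" is undefined upstream; low-quality reads exist only to exercise
  the quality filter.

What a green test establishes: the pipeline recovers planted composition,
artifact accounting, fold changes (within ±0.3 at ≥ 100 expected reads),
and planted hairpins, while rejecting ≥ 80% of dinucleotide-shuffled
decoys. What it does not establish: behaviour on real sequencing error
profiles, isomiR heterogeneity, multi-mapping repeat families at genome
scale, or the biological truth of any specific study — the real libraries
behind the published tables were never deposited, so only their in-table
arithmetic is exactly reproducible, and the acceptance suite is built
around exactly that plus property-based checks.

Decoy construction: shuffling a precursor destroys the mature subsequence,
so decoys are evaluated at the same mature coordinates within the shuffled
precursor with the original counts carried over — the standard permutation
control for hairpin screening, isolating the structural criteria.

# Known limitations

* The folding model's linear loop penalties shift absolute MFE values
  relative to full nearest-neighbor folders; comparisons should stay within
  one engine.
* Exact-match mapping is exhaustive but not scalable to real genomes; it is
  faithful to the zero-mismatch contract at toy scale.
* One gap at most per target alignment; no conservation filtering or
  translational-inhibition prediction.
* The interpretation of "called with the correct sign" for planted changes
  is: significant (p ≤ 0.01) with the estimated fold change carrying the
  true sign — the |log2FC| ≥ 1 call threshold is itself a free parameter,
  so recovery is asserted on sign and magnitude error, not on the label.
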