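---
title: "miRPair: methods and design notes"
author: "miRPair authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRPair: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRPair)
```

## The analysis problem

miRPair implements the classical analysis chain for comparing microRNA
expression between **two** deep-sequenced small RNA libraries, one pooled
library per biological condition (here labelled A = treatment and B =
control). This design — common in early surveys of miRNA expression in
non-model organisms such as livestock ovaries — has no biological
replicates, so differential expression cannot be assessed with
replicate-aware count models (DESeq2/edgeR territory). Instead it relies
on an exact test for a pair of counts drawn from two libraries of known
sequencing depth.

The chain is: raw reads → quality/adapter cleaning → collapsing to unique
tags → priority-based annotation against contaminant ncRNA references and
a hairpin catalog → arm-level (miRNA / miRNA\*) count aggregation →
reads-per-million normalization → exact-test differential expression with
fold-change based significance labels → category and summary reporting.
A qPCR module covers the downstream validation arithmetic
(U6-normalized 2^−ΔCt^, Welch t-test, sign concordance).

## Read cleaning

`cleanReads()` applies a fixed filter cascade, each read removed by at
most one filter so the accounting identity
`totalRaw = cleanTotal + Σ removed` holds exactly:

1. **Quality**: a read fails when more than 20% of its bases are below
   Phred 20 or it carries more than 2 `N`s. Published descriptions of
   this step are typically just "low-quality reads were removed"; the
   thresholds here are explicit and configurable.
2. **5′ adapter contaminants**: reads whose 5′ end matches the first
   10 nt of the 5′ adapter with at most one mismatch. These arise from
   adapter–adapter ligation and carry no insert.
3. **3′ adapter trimming**: the best adapter occurrence maximizes the
   aligned overlap, then minimizes mismatches, then takes the leftmost
   position (a deterministic tie-break); the adapter may run off the read
   end provided at least 6 bases align with a mismatch rate ≤ 0.1. Reads
   without an acceptable match are discarded — in this library chemistry
   every genuine small RNA insert is shorter than the read, so a missing
   adapter indicates a longer, unwanted RNA.
4. **Length**: inserts outside 15–35 nt are removed, mirroring the PAGE
   size selection of small RNA library preparation. Pure-adapter reads
   (empty insert) are counted here.

The clean-read total is the normalization denominator; everything
downstream is driven by collapsed unique tags (`collapseReads()`, sorted
by descending count then lexicographically, so output is reproducible).

## Annotation

Tags are classified into one class each, in priority order
rRNA > tRNA > snRNA > snoRNA > repeat > miRNA > unannotated (the
contaminant order is configurable). This mirrors the standard workflow of
removing non-miRNA ncRNA matches before searching a miRNA catalog, and
makes the class assignment a partition: per-class read counts always sum
to the clean total.

Contaminant matching requires the whole tag to align inside a reference
with at most one substitution. miRNA matching (`matchTag()`) allows up to
2 substitutions — the usual tolerance for calling conserved miRNAs across
related species — and start offsets of ±2 nt to absorb isomiR-like 5′/3′
end variation, with no indels. Tie-breaks are: fewer mismatches, smaller
|offset|, negative offset, earlier catalog entry; a tag is never split
between equally good references. Whether an assigned tag is miRNA or
miRNA\* is decided by the catalog's annotated mature arm, never by
relative abundance, because star-dominant expression is a real phenomenon
worth detecting (star reads can exceed mature reads by orders of
magnitude).

Two deliberate gates:

* only tags of 18–26 nt are eligible for a miRNA call. Shorter tags make
  the shifted-overlap criterion so permissive (a 15-nt tag only needs a
  13-nt overlap) that random sequences occasionally hit an arm with ≤2
  mismatches; the gate keeps the false-assignment rate negligible while
  spanning every plausible isomiR length;
* hairpins with zero counts on both arms in every library are omitted
  from the count set, matching how such tables are reported.

`findDuplexPairs()` reports a hairpin when both arms are detected in the
same library — evidence of a processed miRNA:miRNA\* duplex.

## Differential expression

Counts are normalized to reads per million of the library's clean reads
(`NE = count / cleanTotal × 10⁶`). Two published conventions are applied
on the NE scale:

* zero substitution: an NE of exactly 0 is revised to 0.01, keeping fold
  changes finite for library-specific miRNAs;
* expression floor: a miRNA enters the analysis only when
  `max(NE_A, NE_B) ≥ 1` RPM. The floor deliberately uses the maximum:
  requiring both libraries would silently drop every library-specific
  miRNA (whose absent-library value is the 0.01 substitute), yet such
  miRNAs are a prominent part of the reported results.

The fold change is `log2(NE_A′ / NE_B′)` with A the treatment.

### The exact count test

For a miRNA observed `x` times among `N1` clean reads in library 1, the
probability of `y` occurrences among `N2` reads in library 2 is

$$p(y\mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

the classical exact statistic for pairwise library comparison of counts.
As a function of `y` this is a negative-binomial pmf with size `x+1` and
success probability `N1/(N1+N2)` — an identity the test suite uses as an
independent high-precision oracle while the implementation itself
evaluates the formula directly in log space (`lgamma`; safe for counts to
at least 10⁷).

Tail p-values: the lower tail `C = Σ_{k≤y} p(k|x)`, the upper tail
`D = Σ_{k≥y} p(k|x)`. Numerically, the smaller tail is accumulated
directly — the lower tail by log-sum-exp over `k = 0..y`, the upper tail
by the term recurrence
`p(k+1|x)/p(k|x) = ((x+k+1)/(k+1)) · (N2/N1)/(1+N2/N1)` summed until a
term falls below 10⁻¹⁷ of the accumulated sum — and the other tail is
recovered from the complement `C + D = 1 + p(y|x)`, clamped to
`[p(y|x), 1]`.

The default reported p-value is the doubled minimal tail,
`min(1, 2·min(C, D))`. Reports of this statistic typically print both
tail definitions without stating how they combine into the single
reported p; doubling the minimal tail is the conventional two-sided
choice and both one-sided options remain available (`sided =`). The test
always runs on **raw integer counts** — the 0.01 substitution exists only
on the NE scale; `x = 0` is perfectly valid input.

Significance labels follow the two-band convention: `**` when |fold
change| > 1 and p < 0.01, `*` when |fold change| > 1 and 0.01 ≤ p < 0.05,
otherwise `none`; "significantly differentially expressed" means any
non-`none` label. No multiple-testing correction is applied by default
(matching the workflow this reproduces); `adjust = "BH"` adds a
Benjamini–Hochberg column without changing labels.

Expression categories come from raw counts: A-specific
(`count_B = 0 < count_A`), B-specific (converse), else co-expressed.
Reported percentages are rounded half-up to two decimals
(`percentOf()`), reproducing the printed style of such reports exactly
(e.g. 471/617 → 76.34).

The doubled-minimal-tail test is conservative on discrete data: under a
Poisson null with equal rates and equal depths its rejection rate at
α = 0.05 sits near 0.03–0.05 (checked for rates 5, 50 and 500 with 10⁴
replicates in the acceptance suite).

## The synthetic-data generator

`generateCatalog()` and `simulateLibrary()` provide libraries with known
truth; they define the package's validation conditions rather than being
tunable test dials.

* **Hairpins**: 60–80 nt precursors, each with a 20–24 nt mature arm
  (lengths peaked at 22 nt, the Dicer product mode) and a star arm — the
  reverse complement of the mature arm offset by the 2-nt duplex
  overhang, with 1–3 planted mismatches, so arm pairs look like imperfect
  Dicer duplexes.
* **Abundances**: per-miRNA expected counts are log-normal
  (meanlog 0, sdlog 1.5), giving the heavy-tailed profile of real
  libraries where a handful of miRNAs dominate. The baseline draw is
  seeded separately (`abundanceSeed`) so a library pair shares its
  baseline; planted log2 effects and forced absences are per-library.
* **Mixture**: each read comes from a miRNA arm (star arm with
  probability 0.1 by default — stars are usually, not always, the minor
  product), a contaminant ncRNA fragment (5%, fragment lengths 15–19 or
  25–30 nt, away from the miRNA mode), a uniform random "unannotated"
  sequence (10%, 15–25 nt), or a 5′-adapter contaminant (1%). Defaults
  echo the composition of real ovary libraries, where miRNA reads
  dominate totals while unannotated sequences dominate unique tags.
* **Corruption**: per-base substitution errors (1%), 3′ jitter of −2..+2
  (peaked at 0), and a low-quality overlay (2%) exercised through an
  explicit knob rather than a sequencer error model. Quality strings are
  otherwise constant Phred 40.
* Reads are emitted 5′→3′ on the arm's sense strand (single-stranded
  library chemistry); the 3′ adapter is appended in full.

"Zero-noise" conditions (`zeroNoise = TRUE` in
`simulateExperiment()`) switch off **all** corruption *and* the
non-miRNA mixture components. Under those conditions annotation must
reproduce the generator's truth table exactly, and the test suite
asserts that it does, count for count. The mixture components are
excluded from the definition because random 15–17-nt tags can — with
small but non-negligible probability — legitimately satisfy the
mismatch-tolerant matching criterion and perturb a count by one; that is
a property of the matching rule, not an annotation bug, and the noisy
validation run covers the full mixture.

What the generator does **not** emulate: sequencer-specific error
profiles, ligation bias, PCR duplication, genomic transcription outside
the catalog, and isomiRs beyond the ±2 jitter window. Passing tests
therefore demonstrate the correctness of the analysis logic under
realistic count structure — not robustness to every artifact of real
sequencing data.

## Validation scales

The acceptance checks run at these problem sizes, chosen to exercise the
statistics at realistic counts while keeping a full run inside a few
minutes on one CPU: oracle grids over counts {0, 1, 5, 50, 500, 5000}
and depth ratios {0.5, 1, 1.19, 2}; closed-form checks for all counts
with x + y ≤ 200; null calibration with 10⁴ Poisson pairs per rate;
end-to-end recovery on paired 10⁵-read libraries over a 200-hairpin
catalog with 20 planted |log2FC| = 2 effects (on miRNAs with expected
count ≥ 100) and 10 library-specific miRNAs. On those conditions the
pipeline recovers expression categories exactly in the zero-noise run
and, in the noisy run, labels every planted effect significant with a
null positive rate of a few percent.

## qPCR validation arithmetic

Relative expression is `2^−(Ct_miRNA − Ct_U6)`. Technical replicates are
averaged on the Ct scale (where replicate error is approximately
additive) before exponentiation; each biological sample then contributes
one value, and groups are compared with Welch's unequal-variance t-test —
the safer default when only "t-test" is specified and group variances are
unknown. Degenerate inputs: two identical constant groups give p = 1;
constant but unequal groups give the smallest positive double (the t
statistic is unbounded). The concordance check compares only the *sign*
of the qPCR log2 ratio with the sequencing fold change, which is the
standard claim such validations support.

## Known limitations

* One library per condition: p-values reflect sequencing sampling only,
  not biological variance; they are anti-conservative as statements
  about populations. This is inherent to the design, not the
  implementation.
* No novel-miRNA discovery: hairpin prediction from genomic or EST
  context (secondary-structure based) is out of scope; the catalog is an
  input.
* No genome mapping; annotation is purely reference-set based.
* Count splitting for multi-mapping tags is not attempted; ties are
  resolved deterministically to the earlier catalog entry.
* The paired simulator shares one abundance baseline per seed; it does
  not model within-group biological dispersion.
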