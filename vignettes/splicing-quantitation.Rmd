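---
title: "Coverage-based quantification of alternative splicing with spliceQuant"
author: "spliceQuant maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based quantification of alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(spliceQuant))
```

## What the package does

`spliceQuant` detects and quantifies alternative-splicing differences
between two RNA-seq conditions without read-level isoform assignment.
It (1) catalogues candidate events from a transcript annotation alone,
(2) summarizes each event in each condition by two mean coverages — the
affected exon (`n`) against the remaining exons of its transcript
(`N`) — and (3) calls differential splicing with a plain 2x2 Pearson
chi-squared test filtered on both the P-value and the effect size.
Around that core it profiles 3'-splice-site sequence context, rebuilds
alternative 5'-UTR isoforms with uORF scanning, and ships a seeded
simulator so every stage is testable on synthetic data with known
inclusion levels.

## The event catalogue

Events are found by comparing every pair of transcripts of a gene,
using exact splice-junction coordinates rather than whole-exon
identity:

* **SE** (cassette): an internal exon of one transcript is absent, as
  an exact interval, from a second transcript whose corresponding
  flanking exons reproduce both junctions (upstream exon end and
  downstream exon start).
* **MXE**: two transcripts carry different internal exons between
  identical flanking junctions; each middle exon is absent from the
  other transcript and the two do not overlap.  Requiring *both*
  junctions to match is deliberately conservative — pairs matching on
  one side only would otherwise be double-counted as cassette events.
* **A5SS / A3SS**: two exons share one boundary, differ at the other,
  and the adjacent exon across the variable boundary shares its
  junction.  The affected interval is the differential extension; the
  donor/acceptor label follows the strand (a variable genomic-right
  boundary is a donor choice on `+` and an acceptor choice on `-`).

Events are deduplicated on (type, affected coordinates, flank-junction
coordinates, strand); the representative host-transcript pair is the
lexicographically smallest, which makes the catalogue invariant under
transcript reordering.  Internally all coordinates are 0-based
half-open; GTF/BED conversion happens only at the I/O boundary.  The
catalogue is annotation-only by design: novel-junction discovery from
reads is out of scope, as are retained-intron and alternative
first/last-exon classes.

## The n/N statistic and its test

For an event quantified on a coverage track, `n` is the mean per-base
depth over the affected interval (for MXE, the genomically first exon
of the pair) and `N` the mean depth over the exon union of the
inclusion-form host transcript minus all affected intervals — for MXE
both tandem exons are removed, so `n` and `N` never share bases.  The
inclusion ratio is `n / (n + N)`.  We prefer this bounded form: with
a constitutive depth `d` and inclusion level &psi;, the expected ratio
is &psi;/(1+&psi;) &isin; [0, 1/2], so a fixed ratio-difference
threshold of 0.1 is interpretable.  The unbounded alternative `n / N`
is available behind `ratioDef = "n_over_N"` for users who want the
raw coverage quotient.

Two conditions are compared per event by rounding the four mean
coverages half-up to integers, tabulating
`rbind(c(n_A, N_A), c(n_B, N_B))` and applying the canonical Pearson
chi-squared test (one degree of freedom, no continuity correction;
a zero row or column margin carries no evidence and yields P = 1).
An event is **significant** when P &le; 0.1 *and* the absolute ratio
difference exceeds 0.1; both defaults are exposed
(`comparisonThresholds()`).  No multiple-testing correction is applied
by default — the raw-P rule is the package's operating convention —
but Benjamini–Hochberg adjustment is available with `adjust = "BH"`,
in which case the adjusted P-value is filtered against the same
ceiling.

### Calibration and power

The chi-squared approximation treats the four cells as counts.  When
each cell is a Poisson coverage draw at depth ~50 the test is close to
nominal: in the package's null check (2,000 tables, equal inclusion in
both conditions) the fraction of P &le; 0.1 sits within the binomial
99% band around 0.1.  When `n` is instead a *mean* over an exon of L
bases its variance is depth/L, not depth, so on long exons the test is
conservative by roughly a factor of L — real events need a sizeable
ratio shift, not just any shift, to be called.  This conservatism is a
property of coverage-mean tabulation itself and is documented rather
than corrected; a test on the pipeline confirms the null rate on long
exons stays at or below nominal.

Power at the default depth of 50 depends strongly on the baseline
inclusion, which a closed-form analysis makes explicit.  For an
inclusion shift of 0.3, the expected table at baseline &psi;_B = 0.4
(i.e. 0.7 vs 0.4) is (35, 50; 20, 50), giving chi-squared 2.66 and
P &asymp; 0.103 — just outside the filter — whereas at baseline 0.2
(0.5 vs 0.2) the table (25, 50; 10, 50) gives chi-squared 4.82,
P &asymp; 0.028, with ratio difference 0.167, leaving headroom for
±1 rounding jitter in every cell.  The simulator therefore defaults
to &psi;_A = 0.5 vs &psi;_B = 0.2: a 0.3 shift placed where the
filters operate reliably at the default depth.  Under these
conditions recovery is essentially complete (the package's power
check requires &ge; 90% of 500 shifted events to be flagged, and the
mean estimated ratio to match &psi;/(1+&psi;) within ±0.03).

## Acceptor sequence context

For each event the window `-35..+5` is anchored at the affected
exon's 3' splice site: 33 intronic bases, the AG dinucleotide at
positions -2,-1, and 5 exonic bases (+1..+5); there is no position 0.
Minus-strand windows are reverse-complemented so all matrices read in
transcript orientation.  Windows lacking AG at -2,-1 are kept but
counted — annotations contain non-canonical acceptors — and flagged
per sequence.

Column-wise nucleotide fractions (ambiguous bases excluded per
column) are transformed to a **certainty** score

```
certainty = clamp(log10(100 * freq / 2.4), 0, 1.5)
```

i.e. the frequency in percent over a 2.4% background floor, log10,
clamped to [0, 1.5].  This convention reproduces the intended
anchors — 2.4% maps to 0, 24% to 1, and 100% saturates the stated 1.5
ceiling (log10(41.7) = 1.62 before clamping).  No single natural
log/percent convention reaches the ceiling exactly at frequency 1, so
the clamp is part of the definition; for comparability a conventional
information-content matrix (`clamp(2 + log2 freq, 0, 2)` bits) is
emitted alongside.  `pyrimidineProfile()` reports the per-position
C+T fraction with a summary mean over -20..-3, the polypyrimidine
tract.

## 5'-UTR reconstruction and uORFs

For events classified `5UTR` (affected interval strand-awarely
upstream of the CDS start of the inclusion host; any overlap with the
CDS reclassifies the event as `CDS`), the spliced 5'-UTR is assembled
with and without the alternative interval, guaranteeing
`len_included = len_excluded + alt_len`.  A **uORF** is an
ATG-initiated open reading frame wholly within the 5'-UTR: at least
two codons (9 nt including the stop, configurable) ending at a
TAA/TAG/TGA stop strictly before the CDS start.  ATGs whose frame
reads into the CDS are reported separately as N-terminal-extension
candidates rather than uORFs; overlapping uORFs are each counted from
their own ATG.  A 5'-TOP signature is scored as a transcript starting
with C followed by at least four pyrimidines — a deliberately simple
operational rule, reported but not used in any decision.

## The simulator

`simulateDataset()` writes a complete toy study: a single plus-strand
chromosome, one gene per event (two transcripts each), per-base
Poisson coverage for two conditions, and a truth table.  Defaults are
the package's reference study conditions:

* 8 CDS-region genes per event type (SE, MXE, A5SS, A3SS), 12 5'-UTR
  and 3 3'-UTR cassette genes — a 68/26/6 CDS/5'UTR/3'UTR event mix
  emulating the region distribution typical of mammalian splicing
  surveys — plus 10 no-event background genes.
* Constitutive depth 50; inclusion 0.5 (A) vs 0.2 (B) (see the power
  analysis above).
* Event-bearing transcripts get ~528 nt 5'-UTRs against ~227 nt for
  background genes, with the alternative exon contributing ~30% of
  the inclusion-form UTR — emulating the observation that
  alternatively spliced transcripts carry long 5'-UTRs.
* A planted acceptor motif (invariant AG, C-biased -3, C/T
  probability 0.85 over -20..-5) drawn per event at SE/MXE/A3SS
  acceptors; A5SS affected intervals start at a donor, so nothing is
  planted there.
* Each 5'-UTR event gene carries one planted uORF inside the
  alternative exon; the surrounding UTR sequence is scrubbed of
  spurious ATGs so the exclusion form is uORF-free by construction.

Coverage is generated per base: affected exons Poisson(&psi;·depth),
the MXE partner Poisson((1-&psi;)·depth), constitutive exons
Poisson(depth), introns 0 or Poisson(noise) in the contamination
mode.  Outputs are byte-identical for identical configurations
including the seed.  BAM emission peels the depth field into layers
of maximal positive runs, one perfect-match read per run, so BAM
coverage equals the bedGraph track *exactly* — fixed-length tiled
reads cannot reproduce an arbitrary Poisson field, and exactness is
what makes the cross-format check meaningful.

What the simulator does **not** model: fragment-length and GC biases,
sequencing errors, paired ends, biological replicates, minus-strand
gene geometry, and overlapping genes.  Passing tests on it therefore
demonstrate correctness of the event algebra, the estimators and the
decision rule under the stated sampling model — not robustness to
alignment artefacts in real libraries.

## Numerical choices and problem sizes

Rounding before tabulation is half-up (deterministic, unlike banker's
rounding); ratios with zero total coverage are recorded missing and
flag the comparison `low_coverage` instead of producing 0/0; ties in
deduplication resolve lexicographically.  The test suite exercises the
pipeline at the sizes the package treats as its reference workloads:
10,000 random tables for the chi-squared closed form, 200 random toy
genes against a brute-force enumeration oracle, 2,000 null tables for
calibration, 500 simulated events for power and for motif recovery,
and 1,000 random sequences for the uORF oracle.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
res <- simulateDataset(simConfig(seed = 1), dir)
models <- readGeneModels(res$gtf)
ev <- enumerateASEvents(models)
cmp <- runComparison(ev, models,
                     coverageFromBedgraph(res$coverage[["A"]], "A"),
                     coverageFromBedgraph(res$coverage[["B"]], "B"))
summarizeComparisons(cmp)
```

## Known limitations

The n/N statistic has no replicate model — condition labels denote
single libraries or pre-pooled coverage.  Coverage-mean tabulation
makes the chi-squared test conservative on long exons (see above).
Event classes are the four classical ones; intron retention is not
catalogued.  GTF is the only annotation dialect parsed; GFF3 is not.
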