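---
title: "Methods: non-reference insertion discovery and the augmented linear reference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-reference insertion discovery and the augmented linear reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuiforge)
```

## The problem

Short-read analyses align everything against a single linear reference
genome, so inserted sequence that is present in many individuals but absent
from the reference — a *non-reference unique insertion* (NUI) — is
invisible: reads deriving from it are discarded as unmappable. When de novo
assemblies of many individuals are available, these insertions become
callable with breakpoint resolution, and they can be spliced back into the
reference to produce an *augmented linear reference* that recovers those
reads without any change to the alignment-based analysis paradigm.

`nuiforge` implements that workflow end to end at desk scale: per-sample
insertion calling from assembly-to-reference alignments, cross-sample
clustering and representative selection, repeat/density filtering, linear
integration with a bidirectional coordinate map, reference gap closure,
optical-map concordance checking, discovery-saturation projection, and a
tissue-specificity statistic — plus a fully seeded synthetic cohort
generator with exact truth tables so that every stage is testable offline.

## The pipeline model

### Insertion calling

An insertion call records a reference footprint `[ref_start, ref_end)`
(zero-length for a pure insertion point), the inserted sequence in
reference-forward orientation, and its provenance. All coordinates are
0-based half-open, on disk and in memory; this makes the arithmetic for
zero-length footprints unambiguous (two insertion points at 100 and 101
share no base).

Calls arise from two sources, mirroring assembly-based SV callers:

* **within-alignment**: an insertion cigar run of length $\ge$ 10 bp;
* **between-alignment**: for adjacent blocks of a split alignment on one
  query, same chromosome and strand, with both anchors $\ge$ 1000 bp of
  aligned query and mapq $\ge$ 20, the insert size is the *query gap minus
  the reference gap*; a call is emitted when the reference gap is between
  0 and 10 kb and the size difference is $\ge$ 10 bp. Pairs with negative
  gaps (overlapping anchors) are skipped and logged, never trimmed — no
  trimming rule is defensible without realignment.

The anchor and reference-gap defaults are stand-ins at desk scale for the
unique-anchor logic of production assembly callers; all are configurable.
The 10 bp floor exists because smaller insertions are the domain of
ordinary indel callers.

### Components, scoring, representatives

Calls from all samples whose footprints overlap by $\ge$ 1 bp (transitively)
form a **component**. Components supported by fewer than two distinct
samples are discarded: requiring recurrence removes most spurious calls,
since two independent lineages rarely share a misassembly at one locus.

Within a component, each member's text is the inserted sequence padded with
50 bp of reference context on each side of the component span — but only
when some member exceeds 50 bp; short insertions share exact breakpoints and
align better unpadded. Texts are soft-masked (lowercase) by built-in
low-complexity and tandem detectors, multiply aligned, and scored over
*their inserted segment only*:

* match of an unmasked base **+2**, of a masked base **+0.2**;
* mismatch **−1**; undetermined base (N) **−0.5**; gap **0**.

The asymmetry is deliberate: long, fully resolved, non-repetitive sequences
win. A "match" is defined against the column consensus (most frequent
non-gap symbol, case-insensitive, ties to the lexicographically smallest);
whether the original method scored against a consensus or sum-of-pairs is
not specifiable from its description, and consensus is the simplest
deterministic reading — the scheme constants are kept separate so a
sum-of-pairs variant could be added without disturbing the interface.

Members are then clustered recursively: the highest scorer founds cluster 1,
every unassigned member with $\ge$ 80% identity (inclusive) to the founder
joins, and the process repeats on the remainder. Identity is computed by
global alignment of the two inserted segments (match +1, mismatch −4, N 0,
gap opening −4, gap extension 0) as *matched columns / shorter segment
length*; the shorter-length denominator makes a partial resolution of the
same insertion identical (1.0) to its full-length sibling, which is exactly
the grouping intent. Each cluster's top scorer becomes a representative NUI
unless its footprint is already covered by a better cluster's
representative; clusters supported by a single sample are not eligible
(recurrence is part of the NUI definition) and do not reserve footprint
space. Byte-identical candidates tie on score and fall to the alphabetically
first sample id, then haplotype id — everywhere, so the output is invariant
to input file order.

#### A note on the alignment engine

The multiple alignment is a deterministic center-star progressive alignment
(center = maximal summed pairwise score, "once a gap, always a gap"
merging), implemented over an Rcpp Gotoh aligner. The aligner maximizes the
pair (score, matched columns) lexicographically, which makes identity a
well-defined function of the two sequences rather than of traceback
tie-breaking; the test suite checks it against an independent pure-R DP
oracle. Production MSA tools would give different (not comparable) gap
placements; for the dozens of highly similar sequences in a component, the
center-star result is adequate and reproducible.

### Filters

Representatives then pass a fixed cascade (each removal is tagged with its
rule id, and the cascade is idempotent):

1. **tandem rule** — tandem-masked fraction > 80% *and* fewer than 100
   unmasked bases;
2. **low-complexity rule** — combined low-complexity/simple-repeat masked
   fraction > 80% *and* fewer than 100 unmasked bases;
3. **N rules** — more than 10 undetermined bases with fewer than 50
   resolved, or more than 100 undetermined with fewer than 100 resolved;
4. **200 bp window** — more than five representatives within any 200 bp of
   footprint starts removes the whole run (such pile-ups mark
   low-complexity artefact regions);
5. **50 bp window** — more than two within any 50 bp keeps only the single
   largest insertion (the plural in the source description is ambiguous;
   single-largest is the deterministic reading);
6. **breakpoint consistency** — a representative below 50 bp must have
   its exact insertion point shared by two distinct samples in its cluster
   (the tolerance is unstated in the source; exact match is the strictest
   defensible choice).

Windows are *sliding* (maximal runs over sorted starts), not fixed tiles.
The built-in detectors stand in for external repeat annotators: a
64 bp-window triplet-entropy detector (< 2.5 bits flags the window) and a
tandem scan over periods $\le$ 100 requiring $\ge$ 80% adjacent-copy
identity over arrays $\ge$ 20 bp. External annotation intervals, when
supplied, override both. On uniform random DNA the combined detectors flag
well under 10% of bases; their thresholds were fixed before any acceptance
measurement.

### The augmented reference and its coordinate map

Filtered NUIs are combined with reference gap fills; redundant fills
(one scaffold spanning several gaps) are deduplicated keeping the fill that
spans the most gaps, NUIs overlapping a retained fill are dropped, and the
remaining events are spliced left-to-right into each chromosome. An event
with a zero-length footprint becomes an `inserted` segment; an event with a
positive footprint (including every gap fill) becomes a `replaced` segment
whose reference bases are substituted wholesale — for overlapping or gapped
insertions the entire min-to-max breakpoint span is replaced. Overlap
between events at integration time is a hard error, never a silent merge:
upstream stages are responsible for resolution.

The mapping table tiles every augmented chromosome with
`collinear`/`inserted`/`replaced` segments carrying both coordinate systems,
serialized as a versioned TSV (chain-file semantics, but human-auditable).
Liftover is exact on collinear segments in both directions; positions inside
replaced footprints or inserted sequence are reported absent with a reason.
Three identities hold for every build and are enforced by tests: augmented
length = reference length + Σ(sequence − footprint); deleting inserted
segments and restoring replaced footprints reproduces the input FASTA
byte-identically; slicing any event's augmented interval returns its
sequence bit-exact. Augmented chromosomes keep their names by default
(a configurable suffix is available to prevent accidental mixed-reference
alignment); whether the published augmented references rename chromosomes
is not determinable, so it is left to the user.

### Gap closure

Reference N-gaps (excluding short-arm, telomere, and heterochromatin types,
which assemblies cannot recover) are closed by two routes: an insertion
call whose footprint spans the whole gap supplies a fill directly (with the
collinear run-in trimmed by the exact footprint-to-gap distances — valid
for end-anchored replacement calls, which is how spanning calls arise); or
the two 10 kb gap flanks are re-anchored onto a scaffold, requiring primary
alignments with mapq $\ge$ 30 to the same scaffold in consistent
orientation, and the sequence between the inner anchor ends becomes the
fill. A fill with no N is `closed`; residual N leaves it `minimized`. When
several samples close one gap the fill with the fewest N wins, ties to the
alphabetically first scaffold — the selection rule among donor samples is
not specified by the source method, so the package states its own.

### Validation and comparison

Optical-map concordance evaluates only NUIs $\ge$ 1 kb with no N (the
technology's resolution regime). Optical calls with a between-label
distance > 500 kb are discarded (size inference in sparsely labeled regions
is unreliable); label intervals are padded by ±5 kb (label-merging shifts
reported coordinates by up to one label); and a NUI's size is concordant
when within min(700 bp, 20%) of the optical size. Support from a different
sample counts — maps were not generated for every genome. External-callset
comparison labels a NUI `known` when an external insertion overlaps its
footprint by $\ge$ 1 bp with size ratio in [0.9, 1.1] (NUIs < 50 bp) or
[0.5, 2] (larger), bounds inclusive.

### Saturation and expression analyses

Rarefaction averages, over seeded random sample orderings, the cumulative
distinct NUI count as samples accumulate. Growth is projected by fitting
$f(n) = a\,n^b$ to the last ten points in log-log space; the projected
per-additional-sample yield is $f(N{+}1) - f(N)$. The power-law (Heaps-type)
form is this package's choice — the source defers its model to prior work —
and it is exact on proportional data while biased low on affine data with a
large shared core; a linear fallback handles nonpositive points.

Tissue specificity: genes with fewer than 10 combined raw counts are
excluded; counts are log2(x+1)-transformed; each tissue is tested per gene
with a Welch unequal-variance t-test against all other samples pooled;
p-values are Benjamini–Hochberg adjusted within tissue; a gene is
tissue-specific iff adjusted p < 0.05 and t > 3. Pooled-baseline,
within-tissue adjustment, and the +1 pseudocount are package decisions where
the source is silent. In-frame classification of an insertion is simply
size mod 3 = 0, summarized over the < 50 bp class where the 3 bp periodicity
of exonic insertions is visible.

## The synthetic world

The generator is a pure function of (config, seed) — two runs are
byte-identical. Its defaults state the simulated world used by the
acceptance suite:

* 2 chromosomes × 1 Mb; 2 N-gaps and 10 lowercase tandem tracts per
  chromosome;
* 12 samples; 60 recurrent events (each carried by an identical sequence at
  an identical position in 2+ samples) and 40 private events;
* event sizes from a three-mode mixture — short indel (10–50 bp, weight
  0.6), ~N(300, 30) (weight 0.3), ~N(6000, 500) (weight 0.1) — truncated to
  [10, 10000]; the two long modes emulate the high-copy-repeat peaks seen
  in real insertion size spectra;
* placements avoid gaps, chromosome edges, and each other by 3 kb, so
  anchors always satisfy the caller's defaults;
* noise-free truth alignments: events $\ge$ 1 kb are emitted as split
  (between-alignment) gaps, smaller ones as cigar insertion runs; optional
  reverse-strand storage, scaffold splits at collinear points, and per-copy
  N-run corruption.

What a green end-to-end test establishes: the calling arithmetic, grouping,
scoring, tie-breaking, filtering, and integration are exact on noise-free
input. What it does not establish: behaviour under real alignment noise,
misassembly chimeras, heterozygous breakpoint jitter, or repeat-mediated
ambiguity — none of which the generator emulates (read-level simulation is
out of scope). The expression generator draws log2 expression as Gaussian
(baseline uniform on [4, 10] log2 units, s.d. 0.5, planted shifts of 4) and
discretizes to counts; with baselines this far from zero the rounding is
negligible and a null simulation's raw p-values are uniform to within the
tested tolerance.

## Numerical choices and degenerate inputs

* Identity and alignment scores are integral under the default pairwise
  scheme; the Rcpp DP encodes (score, matches) in one 64-bit integer, so no
  floating-point ties arise.
* Zero-length footprints are expanded to 1 bp *only* for overlap tests;
  arithmetic identities always use the true footprint.
* Zero-variance genes make the Welch statistic undefined; they are skipped
  with a message rather than imputed.
* `read_fasta` converts IUPAC ambiguity codes to N (case-preserved) with a
  logged count instead of erroring: assemblies contain them, and N already
  has defined scoring semantics.
* Empty inputs (no calls, no exclusions, no external variants) are valid
  everywhere and produce empty, correctly-typed outputs.

## Known limitations

* The center-star MSA is not optimal for divergent components; components
  mixing genuinely different insertions at one locus rely on the identity
  clustering, not the MSA, to separate them.
* The built-in repeat detectors are deliberately simple; for real genomes,
  externally computed repeat annotations should be supplied and will
  override them.
* The growth projection underestimates yield when a large core of shared
  NUIs dominates the curve (affine, not power-law, growth).
* Pipeline scale targets desk-scale synthetic cohorts (megabase genomes,
  tens of samples); the per-component DP is quadratic in sequence length
  and alignment problems beyond ~3×10^8 cells are refused rather than
  approximated.
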