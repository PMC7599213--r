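# nuiforge

Discovery of **non-reference unique insertions (NUIs)** from de novo
assembly alignments, and construction of an **augmented linear reference**
that splices them — together with reference gap fills — back into the
genome with a bidirectional coordinate map.

## The problem

A single linear reference genome misses inserted sequence that is present
in many individuals but absent from the reference. Such insertions are
cryptic for read-based SV callers: the reads that derive from them simply
fail to map and are discarded. When per-individual de novo assemblies are
available, insertions become callable with breakpoint resolution as the
difference between a query gap and the corresponding reference gap
(`insert_size = q_gap − r_gap`), and the recurrent, unique ones can be
integrated into the reference so that standard aligners recover the lost
reads with no change of paradigm.

`nuiforge` is aimed at methods developers and genome-resource builders who
need this workflow as testable, deterministic, desk-scale software:

* **calling** — insertion cigar runs within alignments, plus
  between-alignment gaps of split alignments (anchors ≥ 1 kb, mapq ≥ 20,
  reference gap ≤ 10 kb, size ≥ 10 bp); blacklist / segmental-duplication /
  non-core-chromosome exclusions;
* **clustering** — components by ≥ 1 bp breakpoint overlap; singleton
  (one-sample) components discarded; 50 bp reference padding when a member
  exceeds 50 bp; soft-masked center-star multiple alignment; consensus
  global score per inserted segment (match +2 unmasked / +0.2 masked,
  mismatch −1, N −0.5, gap 0); recursive clustering at ≥ 80% identity
  (match +1, mismatch −4, N 0, gap open −4) with identity = matched
  columns / shorter segment; top scorer per cluster becomes the
  representative, alphabetical tie-break;
* **filters** — >80%-tandem and >80%-low-complexity rules with the
  100-unmasked-base escape, the 10 N/50-resolved and 100 N/100-resolved
  rules, the >5-in-200 bp and >2-in-50 bp sliding window rules, and a
  breakpoint-consistency rule for insertions < 50 bp;
* **build** — linear integration (inserted vs replaced segments), versioned
  TSV mapping table, exact liftover both ways, byte-identical reference
  reconstruction;
* **gap closure** — call-spanning fills and 10 kb flank re-anchoring
  (mapq ≥ 30), `closed` vs `minimized` by residual N;
* **validation / analysis** — optical-map concordance (±5 kb label padding,
  min(700 bp, 20%) size rule, 500 kb label-distance exclusion),
  known/novel comparison against external callsets (size ratio 0.9–1.1
  below 50 bp, 0.5–2 above), rarefaction with `a·n^b` growth projection,
  in-frame (size mod 3) classification, genic annotation with
  exon > 3'UTR > 5'UTR > intron priority, and Welch-t / BH tissue
  specificity (adjusted p < 0.05 and t > 3);
* **synthetic** — a seeded generator of references (N-gaps, repeat
  tracts), populations (recurrent + private insertions from a
  short/300 bp/6 kb size mixture), truth alignments (PAF), optical calls,
  and expression matrices, with exact truth tables.

See `vignettes/nuiforge-methods.Rmd` for the model, parameter rationale,
and limitations.

## Worked example

```r
library(nuiforge)

cfg <- nui_sim_config(seed = 7, chrom_sizes = c(chr1 = 300000L, chr2 = 300000L),
                      n_samples = 6L, n_recurrent = 10L, n_private = 6L)
cohort <- simulate_cohort(cfg)      # reference + assemblies + truth PAF
res <- run_discovery(cohort)        # call -> cluster -> filter
head(res$kept[, c("nui_id", "chrom", "ref_start", "insert_size",
                  "sample_id", "support_samples", "global_score")])
#>            nui_id chrom ref_start insert_size sample_id support_samples global_score
#> 1 NUI_chr1_178503  chr1    178503         292       S03               2          584
#> 2 NUI_chr1_203051  chr1    203051         302       S01               3          604
#> 3 NUI_chr1_243647  chr1    243647          49       S01               2           98
#> 4  NUI_chr2_45504  chr2     45504          20       S04               2           40
#> 5  NUI_chr2_56388  chr2     56388         347       S04               2          694
#> 6 NUI_chr2_125572  chr2    125572        5881       S03               3        11762
```

Each row is one representative NUI: `insert_size` is the inserted length
minus its reference footprint, `sample_id` the donor haplotype chosen by
the consensus score (alphabetically first on ties), `support_samples` the
number of distinct samples in its cluster (always ≥ 2), and `global_score`
the consensus alignment score (for a fully resolved, unmasked, recurrent
insertion this is 2 × length). Building and querying the augmented
reference:

```r
b <- build_hdr(cohort$ref, res$kept)
nchar(b$seq[["chr1"]])
#> 300643                                # = 300000 + 643 inserted bases
liftover(b$map, "chr1", 250000L, "ref2hdr")
#> $status "mapped"   $pos 250643        # shifted by upstream insertions

sets <- split(res$members$component_id, res$members$sample_id)
proj <- project_growth(rarefaction(sets, n_perm = 50, seed = 7), n_points = 6)
#> projected NUIs from one more sample: 0.9 (power fit)
```

The projection is ~1 for this nearly saturated toy cohort: most planted
recurrent events are already carried by several of the six samples.

## Command line

A thin CLI over the same functions ships in `inst/scripts/nuiforge`:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/nuiforge", package="nuiforge"))') \
    simulate --seed 7 --outdir fixtures/
# subcommands: simulate, call, cluster, filter, build, liftover, closegaps,
#              validate, compare, saturate, tissuespec, annotate
```

## Layout

* `R/` — formats (FASTA/PAF/versioned TSV), calling, clustering, filters,
  HDR build + liftover, gap closure, validation, analysis, synthetic data
* `src/align.cpp` — Gotoh affine pairwise aligner (lexicographic
  score-then-matches objective)
* `tests/testthat/` — unit + property tests with independent brute-force
  oracles; `test-acceptance.R` implements the acceptance criteria
* `scripts/acceptance.R` — acceptance report generator
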