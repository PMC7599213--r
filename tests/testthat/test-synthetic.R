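# The synthetic world: determinism, truth-table structure, and
# emit -> call round trips.

small_cfg <- function(seed, ...) {
  defaults <- list(seed = seed,
                   chrom_sizes = c(chr1 = 150000L, chr2 = 150000L),
                   n_samples = 4L, n_recurrent = 6L, n_private = 4L,
                   n_gaps_per_chrom = 1L, n_repeats_per_chrom = 2L)
  do.call(nui_sim_config, utils::modifyList(defaults, list(...)))
}

test_that("simulation is a pure function of (config, seed)", {
  cfg <- small_cfg(71)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ref, b$ref)
  expect_identical(a$truth, b$truth)
  expect_identical(a$samples, b$samples)
  # FASTA serialization is byte-identical too
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_fasta(a$ref, fa); write_fasta(b$ref, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different seed differs
  expect_false(identical(simulate_cohort(small_cfg(72))$ref, a$ref))
})

test_that("reference honors the gap and repeat spec", {
  cfg <- small_cfg(73, n_gaps_per_chrom = 3L)
  sim <- simulate_reference(cfg)
  expect_equal(nrow(sim$gaps), 6)
  for (i in seq_len(nrow(sim$gaps))) {
    g <- sim$gaps[i, ]
    seg <- substr(sim$ref[[g$chrom]], g$start + 1, g$end)
    expect_identical(seg, strrep("N", g$end - g$start))
  }
  # zero repeat density: detectors flag <10% of bases
  cfg0 <- small_cfg(74, n_repeats_per_chrom = 0L, n_gaps_per_chrom = 0L)
  sim0 <- simulate_reference(cfg0)
  expect_lt(mean(mask_flags(substr(sim0$ref[[1]], 1, 20000))), 0.1)
  # impossible gap spec errors
  expect_error(simulate_reference(
    small_cfg(75, chrom_sizes = c(chr1 = 5000L),
              gap_len_range = c(4000L, 4000L))),
    "exceeds")
})

test_that("carriers are exactly as configured", {
  cfg <- small_cfg(76)
  sim <- simulate_reference(cfg)
  pop <- simulate_population(sim, cfg)
  expect_equal(nrow(pop$truth), 10)
  rec <- pop$truth$kind == "recurrent"
  n_car <- lengths(pop$carriers)
  expect_true(all(n_car[rec] >= 2))
  expect_true(all(n_car[!rec] == 1))
  # expected representatives exclude all private events
  exp <- expected_representatives(pop)
  expect_equal(nrow(exp), sum(rec))
  # each event present in exactly its carriers' assemblies (events >= 20 bp
  # only: a 10-mer can appear in a 150 kb genome by chance)
  cohort <- simulate_cohort(cfg)
  for (i in which(cohort$truth$size >= 20L)) {
    ev <- cohort$truth[i, ]
    for (smp in names(cohort$samples)) {
      asm <- cohort$samples[[smp]]$assembly
      found <- any(vapply(asm, function(s) {
        grepl(ev$sequence, s, fixed = TRUE) ||
          grepl(revcomp(ev$sequence), s, fixed = TRUE)
      }, logical(1)))
      expect_identical(found,
                       smp %in% cohort$carriers[[ev$event_id]],
                       info = paste(ev$event_id, smp))
    }
  }
})

test_that("emit -> call round trip equals the truth table", {
  cfg <- small_cfg(77)
  cohort <- simulate_cohort(cfg)
  for (smp in names(cohort$samples)) {
    s <- cohort$samples[[smp]]
    calls <- call_sample(s$blocks, s$assembly, sample_id = smp)
    carried <- cohort$truth[vapply(cohort$truth$event_id, function(e) {
      smp %in% cohort$carriers[[e]]
    }, logical(1)), , drop = FALSE]
    carried <- carried[order(carried$chrom, carried$pos), , drop = FALSE]
    expect_equal(nrow(calls), nrow(carried))
    expect_equal(calls$ref_start, carried$pos)
    expect_identical(calls$sequence, carried$sequence)
  }
})

test_that("negative-strand and split-scaffold cohorts still round trip", {
  cfg <- small_cfg(78, reverse_strand_samples = c("S02", "S03"),
                   scaffold_splits_per_chrom = 2)
  cohort <- simulate_cohort(cfg)
  expect_true(any(vapply(cohort$samples, function(s) {
    any(s$blocks$strand == "-")
  }, logical(1))))
  for (smp in names(cohort$samples)) {
    s <- cohort$samples[[smp]]
    calls <- call_sample(s$blocks, s$assembly, sample_id = smp)
    carried <- cohort$truth[vapply(cohort$truth$event_id, function(e) {
      smp %in% cohort$carriers[[e]]
    }, logical(1)), , drop = FALSE]
    carried <- carried[order(carried$chrom, carried$pos), , drop = FALSE]
    expect_equal(calls$ref_start, carried$pos, info = smp)
    expect_identical(calls$sequence, carried$sequence, info = smp)
  }
  # empty truth: collinear single blocks, no calls
  cfg0 <- small_cfg(79, n_recurrent = 0L, n_private = 0L)
  cohort0 <- simulate_cohort(cfg0)
  s <- cohort0$samples[["S01"]]
  expect_true(all(grepl("^[0-9]+M$", s$blocks$cigar)))
  expect_equal(nrow(call_sample(s$blocks, s$assembly)), 0)
})

test_that("alignments parse as valid PAF after serialization", {
  cfg <- small_cfg(80)
  cohort <- simulate_cohort(cfg)
  f <- withr::local_tempfile(fileext = ".paf")
  s <- cohort$samples[["S01"]]
  write_paf(s$blocks, f)
  back <- read_paf(f)
  expect_equal(nrow(back), nrow(s$blocks))
  expect_equal(back$ref_start, s$blocks$ref_start)
  expect_equal(back$cigar, s$blocks$cigar)
})

test_that("optical simulation respects noise and carrier structure", {
  cfg <- small_cfg(81, size_weights = c(0.1, 0.3, 0.6))
  sim <- simulate_reference(cfg)
  pop <- simulate_population(sim, cfg)
  # zero noise: sizes exact
  oc0 <- simulate_optical_calls(pop$truth, pop$carriers, seed = 1,
                                noise_sd = 0)
  big <- pop$truth[pop$truth$size >= 1000, ]
  expect_true(all(oc0$insert_size %in% big$size))
  expect_equal(nrow(oc0),
               sum(lengths(pop$carriers[big$event_id])))
  # reproducible under seed
  oc1 <- simulate_optical_calls(pop$truth, pop$carriers, seed = 2,
                                noise_sd = 25)
  oc2 <- simulate_optical_calls(pop$truth, pop$carriers, seed = 2,
                                noise_sd = 25)
  expect_identical(oc1, oc2)
})
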