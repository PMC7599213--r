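# Sequence-content, window, and breakpoint-consistency filters.

test_that("repeat-content annotation: tandem, random, and N counting", {
  # 200 bp pure (AT)n: tandem fraction 1, nothing unmasked
  at <- strrep("AT", 100)
  ann <- annotate_repeat_content(at)
  expect_equal(ann$tandem_masked_frac, 1)
  expect_equal(ann$unmasked_count, 0)

  set.seed(31)
  rnd <- rand_dna_str(1000)
  ann2 <- annotate_repeat_content(rnd)
  expect_lt(ann2$tandem_masked_frac, 0.1)
  expect_lt(ann2$composite_lc_frac, 0.1)

  ann3 <- annotate_repeat_content("NNNNNACGT")
  expect_equal(ann3$n_count, 5)
  expect_equal(ann3$resolved_count, 4)

  # external intervals override detectors; bounds are checked
  ann4 <- annotate_repeat_content(rnd,
    tandem_intervals = data.frame(start = 0L, end = 900L))
  expect_equal(ann4$tandem_masked_frac, 0.9)
  expect_error(
    annotate_repeat_content(rnd,
      tandem_intervals = data.frame(start = 0L, end = 2000L)),
    "bounds")
})

test_that("the four sequence rules fire exactly per thresholds", {
  mk_ann <- function(tandem = 0, lc = 0, n = 0, len = 1000) {
    list(tandem_masked_frac = tandem, composite_lc_frac = lc,
         n_count = n, resolved_count = len - n,
         unmasked_count = round((1 - max(tandem, lc)) * (len - n)),
         length = len)
  }
  # rule 1 pass: frac 0.85 but unmasked 150
  a <- mk_ann(tandem = 0.85); a$unmasked_count <- 150
  expect_true(apply_sequence_filters(a)$pass)
  # rule 1 fail: unmasked < 100
  b <- mk_ann(tandem = 0.85); b$unmasked_count <- 90
  expect_identical(apply_sequence_filters(b)$failed, "trf80")
  # boundary: exactly 0.8 does not trip (> 0.8 required)
  c_ <- mk_ann(tandem = 0.8); c_$unmasked_count <- 50
  expect_true(apply_sequence_filters(c_)$pass)
  # rule 2
  d <- mk_ann(lc = 0.9); d$unmasked_count <- 10
  expect_identical(apply_sequence_filters(d)$failed, "lc80")
  # rule 3: 12 N, 40 resolved
  e <- mk_ann(n = 12, len = 52); e$unmasked_count <- 40
  expect_identical(apply_sequence_filters(e)$failed, "n10")
  # rules 3+4 pass: 150 N, 120 resolved
  f <- mk_ann(n = 150, len = 270); f$unmasked_count <- 120
  expect_true(apply_sequence_filters(f)$pass)
  # rule 4 fail: 150 N, 90 resolved (rule 3 passes: 90 >= 50)
  g <- mk_ann(n = 150, len = 240); g$unmasked_count <- 90
  expect_identical(apply_sequence_filters(g)$failed, "n100")
})

test_that("200 bp window rule removes dense runs wholesale", {
  set.seed(32)
  seqs <- vapply(rep(30, 6), rand_dna_str, character(1))
  reps <- make_reps("chr1", c(0L, 30L, 60L, 90L, 120L, 150L),
                    c(0L, 30L, 60L, 90L, 120L, 150L), seqs)
  out <- apply_window_filters(reps)
  expect_equal(nrow(out$kept), 0)
  expect_true(all(out$removed$rule == "window200"))

  # five within 200 bp: kept (> 5 required; no 50 bp trio either,
  # spacing 30 puts at most two starts in any 50 bp span)
  reps5 <- reps[1:5, ]
  out5 <- apply_window_filters(reps5)
  expect_equal(nrow(out5$kept), 5)
})

test_that("50 bp window rule keeps only the largest insertion", {
  set.seed(33)
  seqs <- vapply(c(20, 50, 90), rand_dna_str, character(1))
  reps <- make_reps("chr1", c(0L, 15L, 40L), c(0L, 15L, 40L), seqs)
  out <- apply_window_filters(reps)
  expect_equal(nrow(out$kept), 1)
  expect_equal(out$kept$insert_size, 90)
  expect_true(all(out$removed$rule == "window50"))

  # two within 10 bp: both kept
  reps2 <- make_reps("chr1", c(0L, 10L), c(0L, 10L),
                     vapply(c(20, 50), rand_dna_str, character(1)))
  expect_equal(nrow(apply_window_filters(reps2)$kept), 2)
})

test_that("breakpoint consistency applies only below 50 bp", {
  set.seed(34)
  mk_members <- function(starts, cluster_id, samples) {
    data.frame(sample_id = samples, haplotype_id = "1", chrom = "chr1",
               ref_start = as.integer(starts), ref_end = as.integer(starts),
               query_name = "q", query_start = 0L, query_end = 30L,
               strand = "+", sequence = strrep("A", 30),
               component_id = "chr1:100", cluster_id = cluster_id,
               stringsAsFactors = FALSE)
  }
  # 30 bp NUI, 3 samples, identical breakpoints: kept
  reps <- make_reps("chr1", 100L, 100L, rand_dna_str(30),
                    cluster_id = "chr1:100/c1")
  members <- mk_members(c(100, 100, 100), "chr1:100/c1",
                        c("S01", "S02", "S03"))
  expect_equal(nrow(breakpoint_consistency_filter(reps, members)$kept), 1)

  # all member breakpoints distinct: removed
  members2 <- mk_members(c(100, 101, 102), "chr1:100/c1",
                         c("S01", "S02", "S03"))
  res2 <- breakpoint_consistency_filter(reps, members2)
  expect_equal(nrow(res2$kept), 0)
  expect_identical(res2$removed$rule, "breakpoint")

  # 60 bp NUI with scattered breakpoints: rule not applied
  reps60 <- make_reps("chr1", 100L, 100L, rand_dna_str(60),
                      cluster_id = "chr1:100/c1")
  members3 <- mk_members(c(100, 101, 102), "chr1:100/c1",
                         c("S01", "S02", "S03"))
  members3$sequence <- strrep("A", 60); members3$query_end <- 60L
  expect_equal(nrow(breakpoint_consistency_filter(reps60, members3)$kept), 1)
})

test_that("repeat-type classification uses the 50% majority rule", {
  s <- rand_dna_str(300)
  fam <- data.frame(start = 0L, end = 260L, family = "Alu")
  expect_identical(classify_repeat_type(s, fam), "Alu")
  fam2 <- data.frame(start = c(0L, 150L), end = c(90L, 240L),
                     family = c("Alu", "L1"))
  expect_identical(classify_repeat_type(s, fam2), "none")
  expect_identical(classify_repeat_type(s, NULL), "none")
})

test_that("the filter cascade is idempotent and reconciles counts", {
  set.seed(35)
  # mix: clean NUIs, a dense 200 bp cluster, a 50 bp trio, a tandem NUI,
  # and an N-heavy NUI
  clean <- make_reps("chr1", c(1000L, 5000L), c(1000L, 5000L),
                     c(rand_dna_str(120), rand_dna_str(300)))
  dense <- make_reps("chr1", 2000L + c(0L, 20L, 40L, 60L, 80L, 100L),
                     2000L + c(0L, 20L, 40L, 60L, 80L, 100L),
                     vapply(rep(30, 6), rand_dna_str, character(1)))
  trio <- make_reps("chr1", 3000L + c(0L, 10L, 20L),
                    3000L + c(0L, 10L, 20L),
                    vapply(c(20, 40, 90), rand_dna_str, character(1)))
  tandem <- make_reps("chr1", 6000L, 6000L, strrep("AT", 60))
  nheavy <- make_reps("chr1", 7000L, 7000L,
                      paste0(strrep("N", 20), rand_dna_str(20)))
  reps <- rbind(clean, dense, trio, tandem, nheavy)
  reps$nui_id <- sprintf("NUI%03d", seq_len(nrow(reps)))
  # members grant every rep a 2-sample exact-breakpoint cluster
  members <- do.call(rbind, lapply(seq_len(nrow(reps)), function(i) {
    data.frame(sample_id = c("S01", "S02"), haplotype_id = "1",
               chrom = reps$chrom[i], ref_start = reps$ref_start[i],
               ref_end = reps$ref_end[i], query_name = "q",
               query_start = 0L, query_end = nchar(reps$sequence[i]),
               strand = "+", sequence = reps$sequence[i],
               component_id = reps$component_id[i],
               cluster_id = reps$cluster_id[i], stringsAsFactors = FALSE)
  }))
  res <- filter_nuis(reps, members)
  # reconciliation: kept + removed = input
  expect_equal(nrow(res$kept) + nrow(res$report), nrow(reps))
  expect_true(all(nzchar(res$report$rule)))
  # the tandem and N-heavy NUIs fail sequence rules
  expect_true(any(grepl("trf80|lc80", res$report$rule)))
  expect_true("n10" %in% res$report$rule)
  # idempotence
  res2 <- filter_nuis(res$kept, members)
  expect_identical(res2$kept, res$kept)
  expect_equal(nrow(res2$report), 0)
})
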