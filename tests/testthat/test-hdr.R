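# Augmented-reference construction, mapping table, liftover, round trips.

test_that("basic integration arithmetic", {
  set.seed(41)
  ref <- c(chr1 = rand_dna_str(1000))
  ins <- make_reps("chr1", 500L, 500L, rand_dna_str(100))
  b <- integrate_events(ref, ins)
  expect_equal(nchar(b$seq[["chr1"]]), 1100)
  # reference position 600 appears at augmented 700
  lo <- liftover(b$map, "chr1", 600L, "ref2hdr")
  expect_identical(lo$status, "mapped")
  expect_equal(lo$pos, 700)
  # position before the event maps to itself
  expect_equal(liftover(b$map, "chr1", 120L, "ref2hdr")$pos, 120)

  # replaced event: footprint 20, sequence 130 -> net +110
  rep_ev <- make_reps("chr1", 300L, 320L, rand_dna_str(130))
  b2 <- integrate_events(ref, rep_ev)
  expect_equal(nchar(b2$seq[["chr1"]]), 1110)
  expect_identical(liftover(b2$map, "chr1", 310L, "ref2hdr")$status,
                   "replaced")
  expect_identical(liftover(b2$map, "chr1", 305L + 10L, "ref2hdr")$pos,
                   NA_integer_)

  # overlapping events are a hard error
  both <- rbind(make_reps("chr1", 300L, 320L, rand_dna_str(60)),
                make_reps("chr1", 310L, 330L, rand_dna_str(60)))
  both$nui_id <- c("A", "B")
  expect_error(integrate_events(ref, both), "overlapping")
})

test_that("abutting events at half-open boundaries do not conflict", {
  set.seed(42)
  ref <- c(chr1 = rand_dna_str(500))
  fills <- data.frame(chrom = "chr1", ref_start = 100L, ref_end = 150L,
                      sequence = rand_dna_str(80), source_scaffold = "sc",
                      closure_status = "closed", n_gaps = 1L,
                      stringsAsFactors = FALSE)
  nui_abut <- make_reps("chr1", 150L, 150L, rand_dna_str(30))
  expect_equal(nrow(drop_conflicting_nuis(nui_abut, fills)), 1)
  nui_in <- make_reps("chr1", 120L, 120L, rand_dna_str(30))
  expect_message(out <- drop_conflicting_nuis(nui_in, fills), "removed 1")
  expect_equal(nrow(out), 0)
})

test_that("gap-fill dedup keeps the fill spanning the most gaps", {
  fills <- data.frame(
    chrom = "chr1",
    ref_start = c(100L, 100L, 400L, 380L),
    ref_end = c(200L, 200L, 500L, 520L),
    sequence = c(strrep("A", 120), strrep("C", 150), strrep("G", 100),
                 strrep("T", 160)),
    source_scaffold = c("s1", "s2", "s3", "s4"),
    closure_status = "closed",
    n_gaps = c(1L, 1L, 1L, 2L),
    stringsAsFactors = FALSE)
  suppressMessages(out <- dedupe_gapfills(fills))
  # same interval: tie on n_gaps -> longer fill (s2); nested: s4 spans 2 gaps
  expect_setequal(out$source_scaffold, c("s2", "s4"))
  # disjoint fills both kept
  dis <- fills[c(1, 3), ]
  expect_equal(nrow(dedupe_gapfills(dis)), 2)
})

test_that("100 random builds satisfy length, round-trip and extraction", {
  set.seed(43)
  for (rep in 1:100) {
    L <- sample(400:1200, 1)
    ref <- c(chrA = rand_dna_str(L))
    n_ev <- sample(0:6, 1)
    if (n_ev > 0) {
      starts <- sort(sample(seq(10, L - 30, by = 1), n_ev))
      # enforce non-overlap with room for footprints
      ok <- c(TRUE, diff(starts) > 25)
      starts <- starts[ok]
      n_ev <- length(starts)
      fp <- sample(0:10, n_ev, replace = TRUE)
      seqs <- vapply(sample(10:60, n_ev, replace = TRUE), rand_dna_str,
                     character(1))
      nuis <- make_reps("chrA", starts, starts + fp, seqs)
      nuis$nui_id <- sprintf("E%02d", seq_len(n_ev))
    } else {
      nuis <- make_reps("chrA", integer(0), integer(0), character(0))
    }
    b <- integrate_events(ref, nuis)
    # length conservation
    expect_equal(nchar(b$seq[[1]]),
                 L + sum(nchar(nuis$sequence) -
                           (nuis$ref_end - nuis$ref_start)))
    # string oracle
    expect_identical(b$seq[[1]], oracle_splice(ref[[1]], nuis))
    # event extraction is bit-exact
    ext <- extract_event_sequences(b)
    expect_identical(unname(ext[nuis$nui_id]), nuis$sequence)
    # reconstruction reproduces the reference byte-identically
    expect_identical(reconstruct_reference(b, ref)[["chrA"]], ref[[1]])
  }
})

test_that("liftover round-trips every collinear position of a random build", {
  set.seed(44)
  ref <- c(chrA = rand_dna_str(300))
  nuis <- make_reps("chrA", c(50L, 120L, 200L), c(50L, 140L, 200L),
                    c(rand_dna_str(25), rand_dna_str(40), rand_dna_str(15)))
  nuis$nui_id <- c("E1", "E2", "E3")
  b <- integrate_events(ref, nuis)
  all_pos <- 0:299
  fwd <- liftover_positions(b$map, "chrA", all_pos, "ref2hdr")
  # only the replaced footprint [120, 140) lacks an image
  expect_identical(which(fwd$status != "mapped") - 1L, 120:139)
  mapped <- fwd$status == "mapped"
  back <- liftover_positions(b$map, "chrA", fwd$pos[mapped], "hdr2ref")
  expect_true(all(back$status == "mapped"))
  expect_equal(back$pos, all_pos[mapped])
  # scalar API agrees with the vectorized one
  expect_equal(liftover(b$map, "chrA", 45L, "ref2hdr")$pos, fwd$pos[46])
  # augmented positions inside events have no reference image
  seg <- b$map[b$map$event_id == "E1", ]
  expect_identical(
    liftover(b$map, "chrA", seg$hdr_start, "hdr2ref")$status,
    "non_reference")
  expect_error(liftover(b$map, "nope", 1L, "ref2hdr"), "unknown chromosome")
})

test_that("mapping table round trips through the versioned TSV", {
  set.seed(45)
  ref <- c(chrA = rand_dna_str(400))
  nuis <- make_reps("chrA", 100L, 100L, rand_dna_str(50))
  b <- integrate_events(ref, nuis)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(b$map, f, "mapping")
  expect_identical(read_table(f, "mapping"), b$map)
})

test_that("name suffix decorates augmented chromosomes", {
  ref <- c(chr1 = strrep("A", 100))
  nuis <- make_reps("chr1", 50L, 50L, strrep("C", 20))
  b <- integrate_events(ref, nuis, name_suffix = "_hdr")
  expect_identical(names(b$seq), "chr1_hdr")
  expect_identical(reconstruct_reference(b, ref)[["chr1"]], ref[[1]])
})
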