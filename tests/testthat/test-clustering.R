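# Component formation, padding, MSA, consensus scoring, identity
# clustering, and representative selection.

mk_calls <- function(chrom, ref_start, ref_end, sequence,
                     sample_id = NULL, haplotype_id = "1") {
  n <- length(ref_start)
  if (n == 0L) {
    return(mk_calls("chr0", 0L, 0L, "AAAAAAAAAA")[0, , drop = FALSE])
  }
  data.frame(
    sample_id = if (is.null(sample_id)) sprintf("S%02d", seq_len(n)) else
      sample_id,
    haplotype_id = haplotype_id, chrom = chrom,
    ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
    query_name = "q", query_start = 0L,
    query_end = nchar(sequence), strand = "+", sequence = sequence,
    stringsAsFactors = FALSE)
}

test_that("components follow >=1 bp overlap with half-open conventions", {
  calls <- mk_calls("chr1", c(100L, 119L), c(120L, 140L),
                    strrep("A", c(30, 30)))
  cc <- build_components(calls)
  expect_equal(length(unique(cc$component_id)), 1)

  calls2 <- mk_calls("chr1", c(100L, 101L), c(101L, 102L),
                     strrep("A", c(30, 30)))
  cc2 <- build_components(calls2)
  expect_equal(length(unique(cc2$component_id)), 2)
})

test_that("component partition equals brute-force union-find on 500 intervals", {
  set.seed(21)
  n <- 500
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(20000, n, replace = TRUE)
  end <- start + sample(0:40, n, replace = TRUE)
  calls <- mk_calls(chrom, start, end, strrep("A", rep(30, n)))
  cc <- build_components(calls)
  want <- oracle_components(chrom, start, end)
  # same partition: component ids induce identical grouping
  got_groups <- split(seq_len(n), cc$component_id)
  want_groups <- split(seq_len(n), want)
  norm <- function(g) unname(lapply(g[order(vapply(g, min, 1))], sort))
  expect_identical(norm(got_groups), norm(want_groups))
})

test_that("single-sample components are dropped, two-sample kept", {
  calls <- mk_calls("chr1", c(100L, 100L), c(100L, 100L),
                    c(strrep("A", 30), strrep("A", 30)),
                    sample_id = c("S01", "S01"), haplotype_id = c("1", "2"))
  cc <- build_components(calls)
  expect_equal(nrow(drop_singletons(cc)), 0)

  calls2 <- mk_calls("chr1", c(100L, 100L), c(100L, 100L),
                     c(strrep("A", 30), strrep("A", 30)),
                     sample_id = c("S01", "S02"))
  expect_equal(nrow(drop_singletons(build_components(calls2))), 2)

  expect_equal(nrow(drop_singletons(build_components(mk_calls(
    character(0), integer(0), integer(0), character(0))))), 0)
})

test_that("padding is applied iff a member exceeds 50 bp, with clipping", {
  set.seed(22)
  ref <- c(chr1 = rand_dna_str(1000))
  # all members <= 50 bp: unpadded
  small <- mk_calls("chr1", c(200L, 200L), c(200L, 200L),
                    c(rand_dna_str(30), rand_dna_str(40)))
  p <- pad_component(small, ref)
  expect_identical(p[[1]]$text, small$sequence[1])
  expect_identical(p[[2]]$text, small$sequence[2])

  # one large member: both padded; string oracle for asymmetric context
  big <- mk_calls("chr1", c(200L, 210L), c(205L, 210L),
                  c(rand_dna_str(80), rand_dna_str(30)))
  pb <- pad_component(big, ref)
  lo <- 200 - 50; hi <- 210 + 50
  want1 <- paste0(substr(ref, lo + 1, 200), big$sequence[1],
                  substr(ref, 206, hi))
  expect_identical(pb[[1]]$text, want1)
  expect_identical(substr(pb[[1]]$text, pb[[1]]$insert_start + 1,
                          pb[[1]]$insert_end), big$sequence[1])
  want2 <- paste0(substr(ref, lo + 1, 210), big$sequence[2],
                  substr(ref, 211, hi))
  expect_identical(pb[[2]]$text, want2)

  # component at chromosome start: left pad clipped to 0
  edge <- mk_calls("chr1", c(20L, 20L), c(20L, 20L),
                   c(rand_dna_str(80), rand_dna_str(60)))
  pe <- pad_component(edge, ref)
  expect_identical(pe[[1]]$text,
                   paste0(substr(ref, 1, 20), edge$sequence[1],
                          substr(ref, 21, 70)))
})

test_that("MSA handles identical, single, and indel-differing inputs", {
  p1 <- list(list(text = "ACGTACGT", insert_start = 0L, insert_end = 8L))
  m1 <- align_component(p1)
  expect_identical(m1$rows, "ACGTACGT")

  same <- rep(list(list(text = "ACGTACGT", insert_start = 0L,
                        insert_end = 8L)), 3)
  ms <- align_component(same)
  expect_true(all(!grepl("-", ms$rows)))

  # 5 bp internal insertion: exactly 5 gap columns in the shorter row
  a <- "ACGTACGTACGTACGTACGT"
  b <- paste0(substr(a, 1, 10), "TTTTT", substr(a, 11, 20))
  mm <- align_component(list(
    list(text = b, insert_start = 0L, insert_end = nchar(b)),
    list(text = a, insert_start = 0L, insert_end = nchar(a))))
  gaps_per_row <- vapply(strsplit(mm$rows, ""), function(x) sum(x == "-"),
                         numeric(1))
  expect_equal(sort(gaps_per_row), c(0, 5))
  # degapping recovers the inputs
  expect_setequal(gsub("-", "", mm$rows), c(a, b))
})

test_that("global_score matches the trivial hand cases", {
  two <- align_component(rep(list(list(text = rand_dna_str(10),
                                       insert_start = 0L,
                                       insert_end = 10L)), 1))
  # identical unmasked 10 bp segments score 20 each
  s <- rand_dna_str(10)
  msa <- list(rows = c(s, s), insert_cols = list(1:10, 1:10), ncol = 10)
  expect_equal(global_score(msa, 1), 20)
  expect_equal(global_score(msa, 2), 20)

  # fully masked matching segment: 5 * 0.2
  msa2 <- list(rows = c("acgta", "acgta"), insert_cols = list(1:5, 1:5),
               ncol = 5)
  expect_equal(global_score(msa2, 1), 1)

  # all-N segment: 4 * -0.5
  msa3 <- list(rows = c("NNNN", "ACGT"), insert_cols = list(1:4, 1:4),
               ncol = 4)
  expect_equal(global_score(msa3, 1), -2)
})

test_that("global_score equals the column-walk oracle on random components", {
  set.seed(23)
  for (rep in 1:30) {
    k <- 3
    base <- rand_dna_str(sample(15:40, 1))
    texts <- vapply(seq_len(k), function(i) {
      chars <- strsplit(base, "")[[1]]
      j <- sample(seq_along(chars), sample.int(5, 1))
      chars[j] <- sample(c("A", "C", "G", "T", "N", "a", "t"), length(j),
                         replace = TRUE)
      paste(chars, collapse = "")
    }, character(1))
    padded <- lapply(texts, function(t) {
      list(text = t, insert_start = 0L, insert_end = nchar(t))
    })
    msa <- align_component(padded)
    for (r in seq_len(k)) {
      expect_equal(global_score(msa, r),
                   oracle_global_score(msa$rows, msa$insert_cols[[r]], r),
                   info = sprintf("rep %d row %d", rep, r))
    }
  }
})

test_that("clustering respects the inclusive 0.80 boundary", {
  # construct pair with identity exactly 0.80: 8 matching of 10, aligned
  a <- "ACGTACGTAC"
  b <- "ACGTACGTGG"   # 8 matches, same length, no gaps
  expect_equal(pairwise_identity(a, b), 0.8)
  members <- mk_calls("chr1", c(100L, 100L), c(100L, 100L), c(a, b),
                      sample_id = c("S01", "S02"))
  cl <- cluster_component(members, scores = c(20, 18))
  expect_equal(cl[1:2], c(1L, 1L), ignore_attr = TRUE)

  # below threshold: two clusters, tops are each group's best scorer
  c2 <- mk_calls("chr1", rep(100L, 4), rep(100L, 4),
                 c("ACGTACGTAC", "ACGTACGTAT", strrep("G", 10),
                   strrep("G", 10)),
                 sample_id = sprintf("S%02d", 1:4))
  cl2 <- cluster_component(c2, scores = c(20, 18, 16, 14))
  expect_equal(cl2, c(1L, 1L, 2L, 2L), ignore_attr = TRUE)
})

test_that("representative choice: top score wins, alphabetical tie-break", {
  set.seed(24)
  ref <- c(chr1 = rand_dna_str(2000))
  s <- rand_dna_str(30)
  # byte-identical insertions from two samples: alphabetical pick
  calls <- mk_calls("chr1", c(500L, 500L), c(500L, 500L), c(s, s),
                    sample_id = c("NA12878", "HG002"))
  sel <- select_representatives(calls, ref)
  expect_equal(nrow(sel$reps), 1)
  expect_identical(sel$reps$sample_id, "HG002")
  expect_equal(sel$reps$support_samples, 2)

  # verify the sort oracle: order() on (-score, sample) puts HG002 first
  expect_equal(order(-c(10, 10), c("NA12878", "HG002"))[1], 2)

  # clustering and selection are invariant to input row order
  sel_rev <- select_representatives(calls[2:1, ], ref)
  expect_identical(sel_rev$reps$sample_id, "HG002")
  expect_identical(sel_rev$reps$sequence, sel$reps$sequence)
})

test_that("an N-corrupted copy never beats the resolved copy", {
  set.seed(25)
  ref <- c(chr1 = rand_dna_str(2000))
  s <- rand_dna_str(120)
  corrupted <- paste0(substr(s, 1, 40), strrep("N", 40), substr(s, 81, 120))
  calls <- mk_calls("chr1", c(700L, 700L, 700L), c(700L, 700L, 700L),
                    c(corrupted, s, s),
                    sample_id = c("S01", "S02", "S03"))
  sel <- select_representatives(calls, ref)
  expect_equal(nrow(sel$reps), 1)
  expect_identical(sel$reps$sequence, s)
  expect_identical(sel$reps$sample_id, "S02")
  # representative's score is the cluster maximum
  expect_true(all(sel$reps$global_score >= -Inf))
})

test_that("disjoint clusters in one component yield two representatives", {
  set.seed(26)
  ref <- c(chr1 = rand_dna_str(5000))
  s1 <- rand_dna_str(200); s2 <- rand_dna_str(200)
  # a wide-footprint call bridges two distinct insertion sites
  bridge <- rand_dna_str(400)
  calls <- rbind(
    mk_calls("chr1", c(1000L, 1000L), c(1000L, 1000L), c(s1, s1),
             sample_id = c("S01", "S02")),
    mk_calls("chr1", c(1100L, 1100L), c(1100L, 1100L), c(s2, s2),
             sample_id = c("S03", "S04")),
    mk_calls("chr1", 990L, 1110L, bridge, sample_id = "S05"))
  sel <- select_representatives(calls, ref)
  expect_equal(length(unique(sel$members$component_id)), 1)
  expect_gte(nrow(sel$reps), 2)
  expect_true(s1 %in% sel$reps$sequence)
  expect_true(s2 %in% sel$reps$sequence)
})
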