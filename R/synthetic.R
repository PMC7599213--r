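# Seeded synthetic world: reference with N-gaps and repeat tracts, a sample
# population sharing recurrent insertions plus private ones, truth
# alignments encoding exactly the planted events, optical calls with
# controlled noise, and expression matrices with planted tissue effects.
# Everything is a pure function of (config, seed); truth tables are exact.

#' Simulation configuration with desk-scale defaults
#'
#' The defaults state the simulated world: 2 chromosomes of 1 Mb, 12
#' samples, 60 recurrent and 40 private insertion events drawn from a size
#' mixture with short-indel (10-50 bp), ~300 bp and ~6 kb modes (the two
#' long modes emulate the high-copy repeat peaks of real insertion size
#' distributions), event sizes truncated to \[10, 10000\].
#'
#' @param seed Mandatory RNG seed.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_gaps_per_chrom,gap_len_range,gap_types Reference N-gap spec.
#' @param n_repeats_per_chrom,repeat_len_range Soft-masked tandem tracts.
#' @param n_samples Number of samples.
#' @param n_recurrent,n_private Planted event counts.
#' @param size_weights Mixture weights (short, ~300 bp, ~6 kb).
#' @param carrier_extra_prob Per-extra-sample carrier probability beyond
#'   the minimum of 2.
#' @param ngap_corruption_rate Per carried copy, probability that a central
#'   run is replaced by N in that sample's assembly.
#' @param scaffold_splits_per_chrom Mean number of collinear scaffold
#'   breaks per chromosome (Poisson).
#' @param reverse_strand_samples Sample ids whose assemblies are stored
#'   reverse-complemented (negative-strand alignments).
#' @param aln_between_min Events at least this large are represented as
#'   split (between-alignment) gaps rather than cigar insertions.
#' @param min_event_sep,edge_margin Placement constraints in bp.
#' @param mapq Mapping quality written to truth alignments.
#' @param optical_noise_sd Gaussian s.d. added to optical insert sizes.
#' @return Config list.
#' @export
nui_sim_config <- function(seed,
                           chrom_sizes = c(chr1 = 1000000L, chr2 = 1000000L),
                           n_gaps_per_chrom = 2L,
                           gap_len_range = c(300L, 1500L),
                           gap_types = "contig",
                           n_repeats_per_chrom = 10L,
                           repeat_len_range = c(60L, 240L),
                           n_samples = 12L,
                           n_recurrent = 60L,
                           n_private = 40L,
                           size_weights = c(0.6, 0.3, 0.1),
                           carrier_extra_prob = 0.15,
                           ngap_corruption_rate = 0,
                           scaffold_splits_per_chrom = 0,
                           reverse_strand_samples = character(0),
                           aln_between_min = 1000L,
                           min_event_sep = 3000L,
                           edge_margin = 3000L,
                           mapq = 60L,
                           optical_noise_sd = 50) {
  if (missing(seed)) stop("seed is mandatory")
  list(seed = seed, chrom_sizes = chrom_sizes,
       n_gaps_per_chrom = n_gaps_per_chrom,
       gap_len_range = gap_len_range, gap_types = gap_types,
       n_repeats_per_chrom = n_repeats_per_chrom,
       repeat_len_range = repeat_len_range,
       n_samples = n_samples, n_recurrent = n_recurrent,
       n_private = n_private, size_weights = size_weights,
       carrier_extra_prob = carrier_extra_prob,
       ngap_corruption_rate = ngap_corruption_rate,
       scaffold_splits_per_chrom = scaffold_splits_per_chrom,
       reverse_strand_samples = reverse_strand_samples,
       aln_between_min = aln_between_min,
       min_event_sep = min_event_sep, edge_margin = edge_margin,
       mapq = mapq, optical_noise_sd = optical_noise_sd)
}

.sample_ids <- function(config) sprintf("S%02d", seq_len(config$n_samples))

#' Simulate a reference genome with N-gaps and repeat tracts
#'
#' @param config From [nui_sim_config()].
#' @return List: `ref` (named sequences; tandem tracts soft-masked
#'   lowercase, gaps as N runs), `gaps` (gap track data.frame with
#'   `gap_type`), `repeats` (planted tract table).
#' @export
simulate_reference <- function(config) {
  with_seed(config$seed, {
    ref <- character(0)
    gaps <- list(); reps <- list()
    for (ch in names(config$chrom_sizes)) {
      L <- config$chrom_sizes[[ch]]
      s <- rand_dna(L)
      used <- IRanges::IRanges()
      place <- function(len) {
        for (try in 1:1000) {
          pos <- sample.int(L - len - 2L * config$edge_margin, 1L) +
            config$edge_margin
          cand <- IRanges::IRanges(pos + 1L, pos + len)
          if (!IRanges::overlapsAny(cand, used, maxgap = 500L)) {
            used <<- c(used, cand)
            return(pos)
          }
        }
        stop("placement spec exceeds chromosome capacity")
      }
      for (g in seq_len(config$n_gaps_per_chrom)) {
        len <- sample(config$gap_len_range[1]:config$gap_len_range[2], 1L)
        if (len + 2L * config$edge_margin >= L) {
          stop("gap spec exceeds chromosome length")
        }
        pos <- place(len)
        substr(s, pos + 1L, pos + len) <- paste(rep("N", len), collapse = "")
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = pos + len,
          gap_type = sample(config$gap_types, 1L), stringsAsFactors = FALSE)
      }
      for (r in seq_len(config$n_repeats_per_chrom)) {
        motif_len <- sample(2:6, 1L)
        motif <- rand_dna(motif_len)
        total <- sample(config$repeat_len_range[1]:config$repeat_len_range[2],
                        1L)
        tract <- tolower(substr(strrep(motif, ceiling(total / motif_len)),
                                1L, total))
        pos <- place(total)
        substr(s, pos + 1L, pos + total) <- tract
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = pos + total, motif = motif,
          stringsAsFactors = FALSE)
      }
      ref[ch] <- s
    }
    list(ref = ref,
         gaps = if (length(gaps)) do.call(rbind, gaps) else
           data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gap_type = character(0)),
         repeats = if (length(reps)) do.call(rbind, reps) else NULL)
  })
}

.draw_sizes <- function(n, weights) {
  mode <- sample.int(3L, n, replace = TRUE, prob = weights)
  sz <- integer(n)
  sz[mode == 1L] <- sample(10:50, sum(mode == 1L), replace = TRUE)
  sz[mode == 2L] <- as.integer(round(stats::rnorm(sum(mode == 2L), 300, 30)))
  sz[mode == 3L] <- as.integer(round(stats::rnorm(sum(mode == 3L), 6000, 500)))
  pmin(pmax(sz, 10L), 10000L)
}

#' Simulate a sample population with recurrent and private insertions
#'
#' Each recurrent event is carried by a configured set of >= 2 samples with
#' an identical inserted sequence at an identical reference position; each
#' private event by exactly one sample. Placements avoid N-gaps,
#' chromosome edges, and each other (minimum separation, bounded
#' redraws).
#'
#' @param sim Result of [simulate_reference()].
#' @param config From [nui_sim_config()].
#' @return List: `truth` (event table, `truth_event` schema), `carriers`
#'   (list event_id -> character vector of sample ids).
#' @export
simulate_population <- function(sim, config) {
  with_seed(config$seed + 1L, {
    samples <- .sample_ids(config)
    n_ev <- config$n_recurrent + config$n_private
    sizes <- .draw_sizes(n_ev, config$size_weights)
    chroms <- sample(names(config$chrom_sizes), n_ev, replace = TRUE)
    pos <- integer(n_ev)
    placed <- lapply(names(config$chrom_sizes), function(ch) {
      g <- sim$gaps[sim$gaps$chrom == ch, , drop = FALSE]
      iranges0(g$start, g$end)
    })
    names(placed) <- names(config$chrom_sizes)
    for (i in seq_len(n_ev)) {
      ch <- chroms[i]
      L <- config$chrom_sizes[[ch]]
      ok <- FALSE
      for (try in 1:1000) {
        p <- sample.int(L - 2L * config$edge_margin, 1L) + config$edge_margin
        cand <- IRanges::IRanges(p + 1L, p + 1L)
        if (!IRanges::overlapsAny(cand, placed[[ch]],
                                  maxgap = config$min_event_sep)) {
          placed[[ch]] <- c(placed[[ch]], cand)
          pos[i] <- p
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place event ", i, " (bounded retries)")
    }
    carriers <- vector("list", n_ev)
    kind <- rep(c("recurrent", "private"),
                c(config$n_recurrent, config$n_private))
    for (i in seq_len(n_ev)) {
      if (kind[i] == "recurrent") {
        k <- 2L + stats::rbinom(1L, config$n_samples - 2L,
                                config$carrier_extra_prob)
        carriers[[i]] <- sort(sample(samples, k))
      } else {
        carriers[[i]] <- sample(samples, 1L)
      }
    }
    seqs <- vapply(sizes, rand_dna, character(1))
    truth <- data.frame(
      event_id = sprintf("EV%03d", seq_len(n_ev)),
      kind = kind, chrom = chroms, pos = pos, size = sizes,
      sequence = seqs,
      carriers = vapply(carriers, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    names(carriers) <- truth$event_id
    list(truth = truth, carriers = carriers)
  })
}

#' Expected surviving representative per planted event
#'
#' Under the default thresholds and noise-free alignments, exactly the
#' recurrent events survive, each represented by its alphabetically first
#' carrier (identical sequences tie on score).
#'
#' @param pop Result of [simulate_population()].
#' @return data.frame: `event_id`, `chrom`, `pos`, `size`, `sequence`,
#'   `rep_sample`.
#' @export
expected_representatives <- function(pop) {
  t <- pop$truth[pop$truth$kind == "recurrent", , drop = FALSE]
  t$rep_sample <- vapply(strsplit(t$carriers, ","), function(x) sort(x)[1],
                         character(1))
  t[order(t$chrom, t$pos), c("event_id", "chrom", "pos", "size",
                             "sequence", "rep_sample")]
}

# corrupt one event copy: replace a central run with N (length ~ half)
.corrupt_copy <- function(s) {
  n <- nchar(s)
  if (n < 20L) return(s)
  run <- max(11L, n %/% 2L)
  run <- min(run, n - 8L)
  start <- (n - run) %/% 2L
  paste0(substr0(s, 0L, start), strrep("N", run),
         substr0(s, start + run, n))
}

#' Emit assemblies and truth alignments for every sample
#'
#' Builds each sample's haplotype by splicing its carried event copies into
#' the reference, optionally N-corrupting copies and splitting scaffolds at
#' collinear points, then writes noise-free alignment blocks whose within-
#' and between-alignment gaps encode exactly the planted events. Events of
#' size >= `aln_between_min` become split alignments (query gap between two
#' anchored blocks); smaller ones become cigar insertion runs. Samples in
#' `reverse_strand_samples` have their scaffolds stored
#' reverse-complemented and are emitted as negative-strand records.
#'
#' @param sim Result of [simulate_reference()].
#' @param pop Result of [simulate_population()].
#' @param config From [nui_sim_config()].
#' @return Named list per sample: `assembly` (named scaffolds), `blocks`
#'   (PAF-style alignment data.frame).
#' @export
emit_alignments <- function(sim, pop, config) {
  samples <- .sample_ids(config)
  out <- stats::setNames(vector("list", length(samples)), samples)
  for (si in seq_along(samples)) {
    smp <- samples[si]
    assembly <- character(0)
    blocks <- list()
    rev_strand <- smp %in% config$reverse_strand_samples
    for (ch in names(config$chrom_sizes)) {
      ev_idx <- which(pop$truth$chrom == ch &
                        vapply(pop$carriers[pop$truth$event_id],
                               function(cs) smp %in% cs, logical(1)))
      ev <- pop$truth[ev_idx, , drop = FALSE]
      ev <- ev[order(ev$pos), , drop = FALSE]
      copies <- ev$sequence
      with_seed(config$seed + 1000L * si + match(ch, names(config$chrom_sizes)), {
        if (config$ngap_corruption_rate > 0 && nrow(ev)) {
          hit <- stats::runif(nrow(ev)) < config$ngap_corruption_rate
          copies[hit] <- vapply(copies[hit], .corrupt_copy, character(1))
        }
        n_splits <- stats::rpois(1L, config$scaffold_splits_per_chrom)
        L <- config$chrom_sizes[[ch]]
        split_pts <- integer(0)
        if (n_splits > 0L) {
          ok_pos <- setdiff(
            seq.int(config$edge_margin, L - config$edge_margin, by = 97L),
            unlist(lapply(ev$pos, function(p) (p - 1500L):(p + 1500L))))
          split_pts <- sort(sample(ok_pos, min(n_splits, length(ok_pos))))
        }
        split_pts
      }) -> split_pts
      piece_bounds <- c(0L, split_pts, config$chrom_sizes[[ch]])
      for (pk in seq_len(length(piece_bounds) - 1L)) {
        ps <- piece_bounds[pk]; pe <- piece_bounds[pk + 1L]
        in_piece <- which(ev$pos >= ps & ev$pos < pe)
        qname <- sprintf("%s|%s_p%d", smp, ch, pk)
        # build query sequence and block structure for this piece
        qparts <- character(0)
        piece_blocks <- list()
        cur_ops <- character(0)
        blk_ref_start <- ps
        blk_query_start <- 0L
        qlen_so_far <- 0L
        rcur <- ps
        flush_block <- function(ref_end) {
          if (ref_end <= blk_ref_start) return(invisible(NULL))
          cig <- paste(cur_ops, collapse = "")
          piece_blocks[[length(piece_blocks) + 1L]] <<- list(
            ref_start = blk_ref_start, ref_end = ref_end,
            query_start = blk_query_start, query_end = qlen_so_far,
            cigar = cig)
          invisible(NULL)
        }
        for (e in seq_along(in_piece)) {
          i <- in_piece[e]
          p <- ev$pos[i]
          cp <- copies[i]
          if (p > rcur) {
            qparts <- c(qparts, substr0(sim$ref[[ch]], rcur, p))
            cur_ops <- c(cur_ops, sprintf("%dM", p - rcur))
            qlen_so_far <- qlen_so_far + (p - rcur)
            rcur <- p
          }
          if (ev$size[i] >= config$aln_between_min) {
            flush_block(p)
            qparts <- c(qparts, cp)
            qlen_so_far <- qlen_so_far + nchar(cp)
            blk_ref_start <- p
            blk_query_start <- qlen_so_far
            cur_ops <- character(0)
          } else {
            qparts <- c(qparts, cp)
            cur_ops <- c(cur_ops, sprintf("%dI", nchar(cp)))
            qlen_so_far <- qlen_so_far + nchar(cp)
          }
        }
        if (pe > rcur) {
          qparts <- c(qparts, substr0(sim$ref[[ch]], rcur, pe))
          cur_ops <- c(cur_ops, sprintf("%dM", pe - rcur))
          qlen_so_far <- qlen_so_far + (pe - rcur)
        }
        flush_block(pe)
        qseq <- paste(qparts, collapse = "")
        qlen <- nchar(qseq)
        strand <- "+"
        if (rev_strand) {
          qseq <- revcomp(qseq)
          strand <- "-"
        }
        assembly[qname] <- qseq
        for (b in piece_blocks) {
          qs <- b$query_start; qe <- b$query_end
          if (rev_strand) { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
          blocks[[length(blocks) + 1L]] <- data.frame(
            query_name = qname, query_length = qlen,
            query_start = qs, query_end = qe, strand = strand,
            ref_name = ch, ref_length = config$chrom_sizes[[ch]],
            ref_start = b$ref_start, ref_end = b$ref_end,
            mapq = config$mapq, is_primary = TRUE, cigar = b$cigar,
            stringsAsFactors = FALSE)
        }
      }
    }
    out[[smp]] <- list(assembly = assembly, blocks = do.call(rbind, blocks))
  }
  out
}

#' Simulate the whole cohort in one call
#'
#' @param config From [nui_sim_config()].
#' @return List: `config`, `ref`, `gaps`, `repeats`, `truth`, `carriers`,
#'   `samples` (per-sample assemblies and alignment blocks).
#' @export
simulate_cohort <- function(config) {
  sim <- simulate_reference(config)
  pop <- simulate_population(sim, config)
  samples <- emit_alignments(sim, pop, config)
  list(config = config, ref = sim$ref, gaps = sim$gaps,
       repeats = sim$repeats, truth = pop$truth, carriers = pop$carriers,
       samples = samples)
}

#' Simulate optical insertion calls from the truth table
#'
#' One call per (large event, carrier): label interval of a few kb around
#' the event position, insert size = true size + Gaussian noise.
#'
#' @param truth Event table from [simulate_population()].
#' @param carriers Carrier list.
#' @param seed RNG seed.
#' @param noise_sd Size noise s.d. (0 = exact sizes).
#' @param min_size Only events at least this large get optical calls
#'   (default 1000, the optical resolution regime).
#' @return data.frame (`optical` schema).
#' @export
simulate_optical_calls <- function(truth, carriers, seed, noise_sd = 50,
                                   min_size = 1000L) {
  with_seed(seed, {
    out <- list()
    big <- which(truth$size >= min_size)
    for (i in big) {
      for (smp in carriers[[truth$event_id[i]]]) {
        d1 <- sample(2000:8000, 1L); d2 <- sample(2000:8000, 1L)
        out[[length(out) + 1L]] <- data.frame(
          sample = smp, chrom = truth$chrom[i],
          label_start = truth$pos[i] - d1, label_end = truth$pos[i] + d2,
          insert_size = truth$size[i] + stats::rnorm(1L, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(sample = character(0), chrom = character(0),
                 label_start = integer(0), label_end = integer(0),
                 insert_size = numeric(0))
  })
}

#' Simulate an expression count matrix with planted tissue effects
#'
#' Per-gene baseline log2 means are uniform on `base_range`; per-sample
#' log2 expression is Gaussian around the baseline with `sd`, shifted by
#' `effect` for planted (gene, tissue) pairs; counts are
#' `max(0, round(2^x - 1))`, so `log2(count + 1)` recovers the Gaussian
#' model up to integer rounding.
#'
#' @param n_genes Number of genes (default 2000).
#' @param tissues Tissue names.
#' @param n_per_tissue Samples per tissue (default 10).
#' @param n_specific Planted specific genes per tissue (default 0 = null).
#' @param effect Planted log2 shift (default 4).
#' @param sd Per-sample log2 s.d. (default 0.5).
#' @param base_range Baseline log2-mean range (default c(4, 10)).
#' @param seed RNG seed.
#' @return List: `counts` (genes x samples), `tissue` labels, `truth`
#'   (planted gene/tissue pairs).
#' @export
simulate_expression <- function(n_genes = 2000L,
                                tissues = c("brain", "testis", "liver"),
                                n_per_tissue = 10L, n_specific = 0L,
                                effect = 4, sd = 0.5,
                                base_range = c(4, 10), seed) {
  with_seed(seed, {
    n_samp <- length(tissues) * n_per_tissue
    tissue <- rep(tissues, each = n_per_tissue)
    base <- stats::runif(n_genes, base_range[1], base_range[2])
    truth <- list()
    shift <- matrix(0, n_genes, n_samp)
    if (n_specific > 0L) {
      pool <- sample.int(n_genes)
      k <- 0L
      for (ti in tissues) {
        g <- pool[(k + 1L):(k + n_specific)]
        k <- k + n_specific
        shift[g, tissue == ti] <- effect
        truth[[ti]] <- data.frame(gene = sprintf("g%04d", g), tissue = ti,
                                  stringsAsFactors = FALSE)
      }
    }
    x <- matrix(stats::rnorm(n_genes * n_samp, 0, sd), n_genes, n_samp)
    x <- x + base + shift
    counts <- pmax(round(2^x - 1), 0)
    rownames(counts) <- sprintf("g%04d", seq_len(n_genes))
    colnames(counts) <- sprintf("%s_%d", tissue,
                                stats::ave(seq_len(n_samp), tissue,
                                           FUN = seq_along))
    list(counts = counts, tissue = tissue,
         truth = if (length(truth)) do.call(rbind, truth) else NULL)
  })
}

#' Simulate a gap-closure scenario
#'
#' A reference with `n_gaps` N-gaps, one donor scaffold per gap carrying
#' the resolved sequence flanked by the true reference flanks, and the
#' flank-to-scaffold alignments a re-anchoring step would produce.
#' Selected gaps get N runs in their fills (expected `minimized`), others
#' low-mapq flank alignments (expected `open`).
#'
#' @param seed RNG seed.
#' @param n_gaps Number of gaps (default 20).
#' @param flank_len Flank length (default 2000 at desk scale; the
#'   production default of 10 kb only changes the anchor span).
#' @param n_with_n Number of gaps whose fills contain an N run.
#' @param n_low_mapq Number of gaps whose flank alignments get mapq 29.
#' @param n_minus Number of gaps anchored in minus orientation.
#' @return List: `ref`, `gaps` (gap table), `assemblies`, `flank_aln`,
#'   `truth` (planted fill per gap, with expected status).
#' @export
simulate_gap_scenario <- function(seed, n_gaps = 20L, flank_len = 2000L,
                                  n_with_n = 3L, n_low_mapq = 3L,
                                  n_minus = 3L) {
  with_seed(seed, {
    spacing <- 2L * flank_len + 4000L
    L <- n_gaps * spacing + 2L * flank_len + 1000L
    s <- rand_dna(L)
    gaps <- list(); fills <- character(n_gaps)
    kinds <- rep("plain", n_gaps)
    kinds[sample.int(n_gaps, n_with_n)] <- "with_n"
    kinds[sample(setdiff(seq_len(n_gaps), which(kinds == "with_n")),
                 n_low_mapq)] <- "low_mapq"
    minus <- sample(which(kinds != "low_mapq"), n_minus)
    assemblies <- character(0)
    aln <- list()
    for (g in seq_len(n_gaps)) {
      gs <- flank_len + 500L + (g - 1L) * spacing
      glen <- sample(300:900, 1L)
      ge <- gs + glen
      fill <- rand_dna(sample(400:1200, 1L))
      if (kinds[g] == "with_n") {
        mid <- nchar(fill) %/% 2L
        fill <- paste0(substr0(fill, 0L, mid), strrep("N", 30L),
                       substr0(fill, mid, nchar(fill)))
      }
      fills[g] <- fill
      substr(s, gs + 1L, ge) <- strrep("N", glen)
      gaps[[g]] <- data.frame(chrom = "chrG", start = gs, end = ge,
                              gap_type = "contig", stringsAsFactors = FALSE)
      lf <- substr0(s, gs - flank_len, gs)
      rf <- substr0(s, ge, ge + flank_len)
      scaf_fwd <- paste0(lf, fill, rf)
      scaf_name <- sprintf("S%02d|fillscaf_%02d", g %% 5L + 1L, g)
      slen <- nchar(scaf_fwd)
      mq <- if (kinds[g] == "low_mapq") 29L else 60L
      tag <- sprintf("chrG:%d-%d", gs, ge)
      if (g %in% minus) {
        assemblies[scaf_name] <- revcomp(scaf_fwd)
        aln[[length(aln) + 1L]] <- data.frame(
          query_name = paste0(tag, "/L"), query_length = flank_len,
          query_start = 0L, query_end = flank_len, strand = "-",
          ref_name = scaf_name, ref_length = slen,
          ref_start = slen - flank_len, ref_end = slen,
          mapq = mq, is_primary = TRUE,
          cigar = sprintf("%dM", flank_len), stringsAsFactors = FALSE)
        aln[[length(aln) + 1L]] <- data.frame(
          query_name = paste0(tag, "/R"), query_length = flank_len,
          query_start = 0L, query_end = flank_len, strand = "-",
          ref_name = scaf_name, ref_length = slen,
          ref_start = 0L, ref_end = flank_len,
          mapq = mq, is_primary = TRUE,
          cigar = sprintf("%dM", flank_len), stringsAsFactors = FALSE)
      } else {
        assemblies[scaf_name] <- scaf_fwd
        aln[[length(aln) + 1L]] <- data.frame(
          query_name = paste0(tag, "/L"), query_length = flank_len,
          query_start = 0L, query_end = flank_len, strand = "+",
          ref_name = scaf_name, ref_length = slen,
          ref_start = 0L, ref_end = flank_len,
          mapq = mq, is_primary = TRUE,
          cigar = sprintf("%dM", flank_len), stringsAsFactors = FALSE)
        aln[[length(aln) + 1L]] <- data.frame(
          query_name = paste0(tag, "/R"), query_length = flank_len,
          query_start = 0L, query_end = flank_len, strand = "+",
          ref_name = scaf_name, ref_length = slen,
          ref_start = slen - flank_len, ref_end = slen,
          mapq = mq, is_primary = TRUE,
          cigar = sprintf("%dM", flank_len), stringsAsFactors = FALSE)
      }
    }
    gap_df <- do.call(rbind, gaps)
    truth <- data.frame(
      chrom = gap_df$chrom, start = gap_df$start, end = gap_df$end,
      fill = fills,
      expected_status = ifelse(kinds == "low_mapq", "open",
                               ifelse(kinds == "with_n", "minimized",
                                      "closed")),
      stringsAsFactors = FALSE)
    list(ref = c(chrG = s), gaps = gap_df, assemblies = assemblies,
         flank_aln = do.call(rbind, aln), truth = truth)
  })
}
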