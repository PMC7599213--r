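# Per-sample insertion calling from assembly-to-reference alignments.
#
# Two sources of calls, in the style of assembly-based SV callers: insertion
# cigar operations within a single alignment block, and the query-gap /
# reference-gap difference between adjacent blocks of a split alignment.
# Insert size is the query gap size minus the reference gap size.

.empty_calls <- function() {
  data.frame(sample_id = character(0), haplotype_id = character(0),
             chrom = character(0), ref_start = integer(0),
             ref_end = integer(0), query_name = character(0),
             query_start = integer(0), query_end = integer(0),
             strand = character(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

# the query sequence in reference-forward orientation, and the query cursor
# start for a cigar walk along the reference
.oriented_query <- function(block, assembly) {
  if (!block$query_name %in% names(assembly)) {
    stop("assembly lacks query sequence ", block$query_name)
  }
  q <- assembly[[block$query_name]]
  if (block$strand == "-") {
    list(seq = revcomp(q),
         start = block$query_length - block$query_end)
  } else {
    list(seq = q, start = block$query_start)
  }
}

#' Call insertions inside one alignment block
#'
#' Walks the cigar; every insertion run of at least `min_size` bases yields
#' a call with a zero-length reference footprint at the gap point. The
#' emitted sequence is in reference-forward orientation (the query is
#' reverse-complemented for negative-strand blocks).
#'
#' @param block One-row alignment data.frame (see [parse_alignment()]).
#' @param assembly Named character vector with the query sequence.
#' @param sample_id,haplotype_id Provenance labels for the calls.
#' @param min_size Minimum insert size (default 10).
#' @return data.frame of calls (`nui_call` schema).
#' @export
call_within_alignment <- function(block, assembly, sample_id = "sample",
                                  haplotype_id = "1", min_size = 10L) {
  if (!isTRUE(as.logical(block$is_primary))) return(.empty_calls())
  oq <- .oriented_query(block, assembly)
  ops <- .cigar_ops(block$cigar)
  rpos <- block$ref_start
  qpos <- oq$start
  out <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op == "M") {
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op == "D") {
      rpos <- rpos + len
    } else { # I
      if (len >= min_size) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, haplotype_id = haplotype_id,
          chrom = block$ref_name, ref_start = rpos, ref_end = rpos,
          query_name = block$query_name, query_start = qpos,
          query_end = qpos + len, strand = block$strand,
          sequence = substr0(oq$seq, qpos, qpos + len),
          stringsAsFactors = FALSE)
      }
      qpos <- qpos + len
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_calls()
}

#' Call insertions between adjacent alignment blocks
#'
#' Per query, primary blocks passing the mapq and anchor-length thresholds
#' are sorted by query coordinate; for each adjacent pair on the same
#' chromosome and strand the query gap and (strand-aware) reference gap are
#' computed. A call is emitted iff `0 <= r_gap <= max_ref_gap` and
#' `q_gap - r_gap >= min_size`; pairs with a negative gap (anchor overlap)
#' are skipped. The call's sequence is the full query gap in
#' reference-forward orientation, and its footprint is the `r_gap`-long
#' reference interval it replaces.
#'
#' @param blocks data.frame of alignment blocks from one sample.
#' @param assembly Named character vector of that sample's scaffolds.
#' @param sample_id,haplotype_id Provenance labels.
#' @param min_size Minimum insert size (default 10).
#' @param min_anchor_len Minimum query span of both anchors (default 1000).
#' @param max_ref_gap Maximum reference gap bridged (default 10000).
#' @param min_mapq Minimum mapping quality of both anchors (default 20).
#' @return data.frame of calls (`nui_call` schema).
#' @export
call_between_alignments <- function(blocks, assembly,
                                    sample_id = "sample",
                                    haplotype_id = "1",
                                    min_size = 10L,
                                    min_anchor_len = 1000L,
                                    max_ref_gap = 10000L,
                                    min_mapq = 20L) {
  out <- list()
  keep <- blocks$is_primary & blocks$mapq >= min_mapq &
    (blocks$query_end - blocks$query_start) >= min_anchor_len
  blocks <- blocks[keep, , drop = FALSE]
  for (qn in unique(blocks$query_name)) {
    b <- blocks[blocks$query_name == qn, , drop = FALSE]
    b <- b[order(b$query_start), , drop = FALSE]
    if (nrow(b) < 2L) next
    q <- assembly[[qn]]
    if (is.null(q)) stop("assembly lacks query sequence ", qn)
    for (i in seq_len(nrow(b) - 1L)) {
      a <- b[i, ]; d <- b[i + 1L, ]
      if (a$ref_name != d$ref_name || a$strand != d$strand) next
      q_gap <- d$query_start - a$query_end
      if (a$strand == "+") {
        r_gap <- d$ref_start - a$ref_end
        fs <- a$ref_end
      } else {
        r_gap <- a$ref_start - d$ref_end
        fs <- d$ref_end
      }
      if (q_gap < 0L || r_gap < 0L) {
        message(sprintf(
          "call_between_alignments: skipping overlapping anchors on %s (q_gap=%d, r_gap=%d)",
          qn, q_gap, r_gap))
        next
      }
      if (r_gap > max_ref_gap) next
      if (q_gap - r_gap < min_size) next
      gap_seq <- substr0(q, a$query_end, d$query_start)
      if (a$strand == "-") gap_seq <- revcomp(gap_seq)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sample_id, haplotype_id = haplotype_id,
        chrom = a$ref_name, ref_start = fs, ref_end = fs + r_gap,
        query_name = qn, query_start = a$query_end,
        query_end = d$query_start, strand = a$strand,
        sequence = gap_seq, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else .empty_calls()
}

#' Call insertions for one sample from all of its alignments
#'
#' Union of within-alignment (cigar insertion runs) and between-alignment
#' (split anchors) calls.
#'
#' @inheritParams call_between_alignments
#' @return data.frame of calls (`nui_call` schema).
#' @export
call_sample <- function(blocks, assembly, sample_id = "sample",
                        haplotype_id = "1", min_size = 10L,
                        min_anchor_len = 1000L, max_ref_gap = 10000L,
                        min_mapq = 20L) {
  within <- list()
  for (i in seq_len(nrow(blocks))) {
    if (!blocks$is_primary[i] || blocks$mapq[i] < min_mapq) next
    within[[length(within) + 1L]] <-
      call_within_alignment(blocks[i, ], assembly, sample_id,
                            haplotype_id, min_size)
  }
  within <- if (length(within)) do.call(rbind, within) else .empty_calls()
  between <- call_between_alignments(blocks, assembly, sample_id,
                                     haplotype_id, min_size,
                                     min_anchor_len, max_ref_gap, min_mapq)
  calls <- rbind(within, between)
  calls[order(calls$chrom, calls$ref_start), , drop = FALSE]
}

#' Drop calls in excluded regions or off the core chromosomes
#'
#' A call is removed iff its reference footprint (zero-length footprints
#' expanded to 1 bp) intersects a blacklist or segmental-duplication
#' interval, or its chromosome is not in `core_chroms`.
#'
#' @param calls data.frame of calls.
#' @param blacklist,segdups data.frames with `chrom`/`start`/`end`
#'   (0-based half-open); `NULL` or empty means no exclusion.
#' @param core_chroms Character vector of allowed chromosome names; `NULL`
#'   keeps all.
#' @return Filtered data.frame.
#' @export
apply_region_exclusions <- function(calls, blacklist = NULL, segdups = NULL,
                                    core_chroms = NULL) {
  if (nrow(calls) == 0L) return(calls)
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(core_chroms)) keep <- calls$chrom %in% core_chroms
  keep <- keep &
    !overlaps_track(calls$chrom, calls$ref_start, calls$ref_end, blacklist) &
    !overlaps_track(calls$chrom, calls$ref_start, calls$ref_end, segdups)
  calls[keep, , drop = FALSE]
}
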