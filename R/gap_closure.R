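# Closing reference N-gaps from assembly scaffolds: either via insertion
# calls whose footprint spans the whole gap, or by re-anchoring the two
# 10 kb gap flanks onto a scaffold and lifting the sequence between the
# inner anchor ends. A gap is "closed" when the fill has no N, "minimized"
# when residual N runs remain.

.gap_status <- function(fill) {
  if (grepl("N", fill, ignore.case = TRUE)) "minimized" else "closed"
}

#' Load a reference gap track, dropping excluded gap types
#'
#' Short-arm, telomere and heterochromatin gaps are structurally
#' unrecoverable from whole-genome assemblies and are excluded up front.
#'
#' @param gaps data.frame with `chrom`, `start`, `end`, `gap_type`, or a
#'   path to a BED file whose name column is the gap type.
#' @param excluded_types Gap types to drop.
#' @return data.frame (`gap` schema) with `closure_status = "open"`.
#' @export
load_gap_track <- function(gaps,
                           excluded_types = c("short_arm", "telomere",
                                              "heterochromatin")) {
  if (is.character(gaps)) {
    bed <- read_bed(gaps)
    gaps <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                       gap_type = bed$name, stringsAsFactors = FALSE)
  }
  stopifnot_cols(gaps, c("chrom", "start", "end", "gap_type"), "gap track")
  if (any(is.na(gaps$start)) || any(is.na(gaps$end)) ||
      any(gaps$end <= gaps$start)) {
    stop("malformed gap track row(s)")
  }
  gaps <- gaps[!gaps$gap_type %in% excluded_types, , drop = FALSE]
  gaps$closure_status <- rep("open", nrow(gaps))
  gaps$fill_sequence <- rep(".", nrow(gaps))
  gaps$source_scaffold <- rep(".", nrow(gaps))
  rownames(gaps) <- NULL
  gaps
}

#' Close gaps using insertion-call footprints
#'
#' A call whose reference footprint spans the entire gap supplies the
#' candidate fill: the call sequence with the flanking collinear run-in
#' trimmed by the exact distances between footprint and gap boundaries
#' (valid for end-anchored replacement calls, which is how spanning calls
#' arise). Status is set by the fill's N content.
#'
#' @param calls Insertion-call table (`nui_call` schema).
#' @param gaps Gap table from [load_gap_track()].
#' @return Updated gap table.
#' @export
close_gaps_from_calls <- function(calls, gaps) {
  if (nrow(gaps) == 0L || nrow(calls) == 0L) return(gaps)
  for (g in seq_len(nrow(gaps))) {
    if (gaps$closure_status[g] != "open") next
    cand <- calls[calls$chrom == gaps$chrom[g] &
                    calls$ref_start <= gaps$start[g] &
                    calls$ref_end >= gaps$end[g] &
                    calls$ref_end > calls$ref_start, , drop = FALSE]
    if (nrow(cand) == 0L) next
    fills <- vapply(seq_len(nrow(cand)), function(i) {
      lead <- gaps$start[g] - cand$ref_start[i]
      trail <- cand$ref_end[i] - gaps$end[g]
      substr0(cand$sequence[i], lead, nchar(cand$sequence[i]) - trail)
    }, character(1))
    ok <- nzchar(fills)
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]; fills <- fills[ok]
    n_in_fill <- vapply(fills, function(f) {
      sum(strsplit(toupper(f), "")[[1]] == "N")
    }, numeric(1))
    best <- order(n_in_fill, cand$sample_id)[1]
    gaps$fill_sequence[g] <- fills[best]
    gaps$source_scaffold[g] <- cand$query_name[best]
    gaps$closure_status[g] <- .gap_status(fills[best])
  }
  gaps
}

#' Close one gap by flank re-anchoring
#'
#' Expects alignments of the gap's upstream (`/L`) and downstream (`/R`)
#' flanks to sample scaffolds: query names `"<chrom>:<start>-<end>/L"` and
#' `".../R"`, target = scaffold. Both flanks must have primary alignments
#' with mapq >= `min_mapq` to the same scaffold in a consistent
#' orientation, with the inner anchor ends ordered; the fill is the
#' scaffold substring between the inner anchor ends
#' (reverse-complemented for minus-orientation anchoring). When several
#' samples close a gap, the fill with the fewest N wins (ties to the
#' alphabetically first scaffold).
#'
#' @param gap One-row gap table.
#' @param flank_aln data.frame of flank alignment blocks (PAF).
#' @param assemblies Named character vector of scaffolds (across samples;
#'   names must match the alignment target names).
#' @param min_mapq Minimum anchor mapping quality (default 30).
#' @return The gap row, updated in place.
#' @export
close_gap_by_flanks <- function(gap, flank_aln, assemblies, min_mapq = 30L) {
  tag <- sprintf("%s:%d-%d", gap$chrom, gap$start, gap$end)
  lname <- paste0(tag, "/L"); rname <- paste0(tag, "/R")
  al <- flank_aln[flank_aln$query_name == lname & flank_aln$is_primary &
                    flank_aln$mapq >= min_mapq, , drop = FALSE]
  ar <- flank_aln[flank_aln$query_name == rname & flank_aln$is_primary &
                    flank_aln$mapq >= min_mapq, , drop = FALSE]
  if (nrow(al) == 0L || nrow(ar) == 0L) return(gap)
  cands <- list()
  for (i in seq_len(nrow(al))) {
    for (j in seq_len(nrow(ar))) {
      if (al$ref_name[i] != ar$ref_name[j]) next
      if (al$strand[i] != ar$strand[j]) next
      scaf_name <- al$ref_name[i]
      scaf <- assemblies[[scaf_name]]
      if (is.null(scaf)) next
      if (al$strand[i] == "+") {
        inner_l <- al$ref_end[i]; inner_r <- ar$ref_start[j]
        if (inner_l > inner_r) next
        fill <- substr0(scaf, inner_l, inner_r)
      } else {
        # minus orientation: the scaffold holds the region reverse-
        # complemented, so the R flank sits left of the L flank
        inner_l <- al$ref_start[i]; inner_r <- ar$ref_end[j]
        if (inner_r <= inner_l) {
          fill <- revcomp(substr0(scaf, inner_r, inner_l))
        } else next
      }
      if (!nzchar(fill)) next
      cands[[length(cands) + 1L]] <- list(fill = fill, scaf = scaf_name)
    }
  }
  if (!length(cands)) {
    message(sprintf("gap %s: no consistent flank anchoring", tag))
    return(gap)
  }
  n_counts <- vapply(cands, function(c_) {
    sum(strsplit(toupper(c_$fill), "")[[1]] == "N")
  }, numeric(1))
  scafs <- vapply(cands, `[[`, character(1), "scaf")
  best <- order(n_counts, scafs)[1]
  gap$fill_sequence <- cands[[best]]$fill
  gap$source_scaffold <- cands[[best]]$scaf
  gap$closure_status <- .gap_status(cands[[best]]$fill)
  gap
}

#' Extract the two flank queries for every open gap
#'
#' Helper producing the flank FASTA a re-alignment step would consume;
#' names follow the `"<chrom>:<start>-<end>/L|R"` convention used by
#' [close_gap_by_flanks()].
#'
#' @param gaps Gap table.
#' @param ref Named character vector of reference sequences.
#' @param flank_len Flank length in bp (default 10000).
#' @return Named character vector of flank sequences.
#' @export
gap_flanks <- function(gaps, ref, flank_len = 10000L) {
  out <- character(0)
  for (g in seq_len(nrow(gaps))) {
    ch <- ref[[gaps$chrom[g]]]
    tag <- sprintf("%s:%d-%d", gaps$chrom[g], gaps$start[g], gaps$end[g])
    out[paste0(tag, "/L")] <-
      substr0(ch, max(0L, gaps$start[g] - flank_len), gaps$start[g])
    out[paste0(tag, "/R")] <-
      substr0(ch, gaps$end[g], min(nchar(ch), gaps$end[g] + flank_len))
  }
  out
}

#' Run both gap-closure routes over a gap track
#'
#' @param gaps Gap table from [load_gap_track()].
#' @param calls Optional insertion calls (route 1).
#' @param flank_aln Optional flank alignments (route 2).
#' @param assemblies Scaffolds for route 2.
#' @param min_mapq Minimum anchor mapq (default 30).
#' @return Updated gap table.
#' @export
close_gaps <- function(gaps, calls = NULL, flank_aln = NULL,
                       assemblies = NULL, min_mapq = 30L) {
  if (!is.null(calls)) gaps <- close_gaps_from_calls(calls, gaps)
  if (!is.null(flank_aln)) {
    for (g in seq_len(nrow(gaps))) {
      if (gaps$closure_status[g] != "open") next
      gaps[g, ] <- close_gap_by_flanks(gaps[g, , drop = FALSE], flank_aln,
                                       assemblies, min_mapq)
    }
  }
  gaps
}

#' Convert closed/minimized gaps into gap-fill events for the HDR build
#'
#' @param gaps Gap table after closure.
#' @return data.frame (`gapfill` schema); one row per non-open gap.
#' @export
gapfills_from_gaps <- function(gaps) {
  g <- gaps[gaps$closure_status != "open", , drop = FALSE]
  data.frame(
    chrom = g$chrom, ref_start = g$start, ref_end = g$end,
    sequence = g$fill_sequence, source_scaffold = g$source_scaffold,
    closure_status = g$closure_status,
    n_gaps = rep(1L, nrow(g)),
    stringsAsFactors = FALSE
  )
}
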