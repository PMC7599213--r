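# Linear integration of filtered NUIs and gap fills into the reference,
# with a bidirectional coordinate mapping table (a chain-file analogue kept
# as a plain TSV). Zero-footprint events are "inserted" segments; events
# with a positive footprint (and all gap fills) are "replaced" segments
# whose footprint bases are substituted by the event sequence.

#' Remove redundant gap fills
#'
#' One large assembly scaffold can fill several reference gaps, producing
#' overlapping candidate fills. Among fills whose reference intervals
#' overlap (transitively), the one spanning the most gaps is kept; ties go
#' to the longest fill sequence, then the alphabetically first scaffold.
#'
#' @param fills data.frame (`gapfill` schema).
#' @return Deduplicated data.frame.
#' @export
dedupe_gapfills <- function(fills) {
  if (nrow(fills) <= 1L) return(fills)
  keep <- logical(nrow(fills))
  for (ch in unique(fills$chrom)) {
    i <- which(fills$chrom == ch)
    r <- iranges0(fills$ref_start[i], fills$ref_end[i])
    merged <- IRanges::reduce(r, min.gapwidth = 0L)
    grp <- S4Vectors::subjectHits(IRanges::findOverlaps(r, merged))
    for (g in unique(grp)) {
      members <- i[grp == g]
      best <- members[order(-fills$n_gaps[members],
                            -nchar(fills$sequence[members]),
                            fills$source_scaffold[members])][1]
      keep[best] <- TRUE
      dropped <- setdiff(members, best)
      if (length(dropped)) {
        message(sprintf("dedupe_gapfills: dropping %d redundant fill(s) on %s",
                        length(dropped), ch))
      }
    }
  }
  fills[keep, , drop = FALSE]
}

#' Remove NUIs conflicting with retained gap fills
#'
#' A NUI is dropped iff its expanded footprint intersects a retained fill's
#' reference interval (half-open abutment is not a conflict).
#'
#' @param nuis Representative table.
#' @param fills Deduplicated gap fills.
#' @return Filtered representative table.
#' @export
drop_conflicting_nuis <- function(nuis, fills) {
  if (nrow(nuis) == 0L || is.null(fills) || nrow(fills) == 0L) return(nuis)
  track <- data.frame(chrom = fills$chrom, start = fills$ref_start,
                      end = fills$ref_end)
  hit <- overlaps_track(nuis$chrom, nuis$ref_start, nuis$ref_end, track)
  if (any(hit)) {
    message(sprintf("drop_conflicting_nuis: removed %d NUI(s) overlapping gap fills",
                    sum(hit)))
  }
  nuis[!hit, , drop = FALSE]
}

#' Linearly integrate NUIs and gap fills into the reference
#'
#' Events must be pairwise non-overlapping (expanded footprints); any
#' overlap is a hard error listing the offenders. Produces the augmented
#' sequences plus a mapping table that tiles every augmented chromosome
#' with `collinear` / `inserted` / `replaced` segments.
#'
#' @param ref Named character vector of reference sequences.
#' @param nuis Representative table (may be empty).
#' @param fills Deduplicated gap fills (may be `NULL`).
#' @param name_suffix Optional suffix appended to augmented chromosome
#'   names (default `""`, names preserved).
#' @return List of class `hdr_build`: `seq` (augmented sequences), `map`
#'   (mapping table, `mapping` schema), `events` (integrated event table).
#' @export
integrate_events <- function(ref, nuis, fills = NULL, name_suffix = "") {
  ev <- data.frame(
    event_id = character(0), chrom = character(0), ref_start = integer(0),
    ref_end = integer(0), sequence = character(0), stringsAsFactors = FALSE)
  if (!is.null(nuis) && nrow(nuis)) {
    ev <- rbind(ev, data.frame(
      event_id = nuis$nui_id, chrom = nuis$chrom,
      ref_start = nuis$ref_start, ref_end = nuis$ref_end,
      sequence = nuis$sequence, stringsAsFactors = FALSE))
  }
  if (!is.null(fills) && nrow(fills)) {
    ev <- rbind(ev, data.frame(
      event_id = sprintf("FILL_%s_%d", fills$chrom, fills$ref_start),
      chrom = fills$chrom, ref_start = fills$ref_start,
      ref_end = fills$ref_end, sequence = fills$sequence,
      stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$chrom, ev$ref_start, ev$ref_end), , drop = FALSE]
  if (any(!ev$chrom %in% names(ref))) {
    stop("events on unknown chromosome(s): ",
         paste(unique(ev$chrom[!ev$chrom %in% names(ref)]), collapse = ", "))
  }
  # overlap check on expanded footprints
  for (ch in unique(ev$chrom)) {
    i <- which(ev$chrom == ch)
    if (length(i) < 2L) next
    s <- ev$ref_start[i]; e <- pmax(ev$ref_end[i], s + 1L)
    bad <- which(s[-1L] < e[-length(e)])
    if (length(bad)) {
      stop("overlapping events at integration time: ",
           paste(ev$event_id[i][c(bad[1], bad[1] + 1L)], collapse = " / "))
    }
  }
  out_seq <- character(length(ref))
  names(out_seq) <- paste0(names(ref), name_suffix)
  map <- list()
  for (ci in seq_along(ref)) {
    ch <- names(ref)[ci]
    chrom_seq <- ref[[ch]]
    L <- nchar(chrom_seq)
    i <- which(ev$chrom == ch)
    rpos <- 0L; hpos <- 0L
    parts <- character(0)
    add_seg <- function(type, rs, re, hs, he, id) {
      map[[length(map) + 1L]] <<- data.frame(
        chrom = paste0(ch, name_suffix), segment_type = type,
        ref_start = rs, ref_end = re, hdr_start = hs, hdr_end = he,
        event_id = id, stringsAsFactors = FALSE)
    }
    for (k in i) {
      es <- ev$ref_start[k]; ee <- ev$ref_end[k]
      if (es > rpos) {
        seg <- substr0(chrom_seq, rpos, es)
        parts <- c(parts, seg)
        add_seg("collinear", rpos, es, hpos, hpos + (es - rpos), ".")
        hpos <- hpos + (es - rpos)
        rpos <- es
      }
      slen <- nchar(ev$sequence[k])
      parts <- c(parts, ev$sequence[k])
      type <- if (ee == es) "inserted" else "replaced"
      add_seg(type, es, ee, hpos, hpos + slen, ev$event_id[k])
      hpos <- hpos + slen
      rpos <- ee
    }
    if (rpos < L) {
      parts <- c(parts, substr0(chrom_seq, rpos, L))
      add_seg("collinear", rpos, L, hpos, hpos + (L - rpos), ".")
      hpos <- hpos + (L - rpos)
    }
    out_seq[ci] <- paste(parts, collapse = "")
  }
  map <- do.call(rbind, map)
  rownames(map) <- NULL
  structure(list(seq = out_seq, map = map, events = ev,
                 name_suffix = name_suffix),
            class = "hdr_build")
}

#' Lift a position across the mapping table
#'
#' Collinear positions map by offset in either direction. A reference
#' position inside a replaced footprint has no augmented image
#' (`"replaced"`); an augmented position inside inserted or replacement
#' sequence has no reference image (`"non_reference"`).
#'
#' @param map Mapping table (from [integrate_events()] or [read_table()]).
#' @param chrom Chromosome name (in the source genome of `direction`).
#' @param pos 0-based position.
#' @param direction `"ref2hdr"` or `"hdr2ref"`.
#' @return List with `status` (`"mapped"`, `"replaced"`,
#'   `"non_reference"`) and `pos` (mapped position or `NA`).
#' @export
liftover <- function(map, chrom, pos, direction = c("ref2hdr", "hdr2ref")) {
  direction <- match.arg(direction)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown chromosome: ", chrom)
  if (direction == "ref2hdr") {
    hit <- m[m$ref_start <= pos & pos < m$ref_end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      # zero-length footprints (inserted segments) cannot contain a position
      stop(sprintf("position %d outside reference extent of %s", pos, chrom))
    }
    seg <- hit[1, ]
    if (seg$segment_type == "collinear") {
      list(status = "mapped",
           pos = seg$hdr_start + (pos - seg$ref_start))
    } else {
      list(status = "replaced", pos = NA_integer_)
    }
  } else {
    hit <- m[m$hdr_start <= pos & pos < m$hdr_end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      stop(sprintf("position %d outside augmented extent of %s", pos, chrom))
    }
    seg <- hit[1, ]
    if (seg$segment_type == "collinear") {
      list(status = "mapped",
           pos = seg$ref_start + (pos - seg$hdr_start))
    } else {
      list(status = "non_reference", pos = NA_integer_)
    }
  }
}

#' Vectorized liftover
#'
#' @param map Mapping table.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 0-based positions.
#' @param direction `"ref2hdr"` or `"hdr2ref"`.
#' @return data.frame with `status` and `pos` columns, one row per input.
#' @export
liftover_positions <- function(map, chrom, pos,
                               direction = c("ref2hdr", "hdr2ref")) {
  direction <- match.arg(direction)
  m <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop("unknown chromosome: ", chrom)
  if (direction == "ref2hdr") {
    src_s <- m$ref_start; src_e <- m$ref_end
    dst_s <- m$hdr_start
    absent <- "replaced"
  } else {
    src_s <- m$hdr_start; src_e <- m$hdr_end
    dst_s <- m$ref_start
    absent <- "non_reference"
  }
  status <- character(length(pos))
  out <- rep(NA_integer_, length(pos))
  for (k in seq_along(pos)) {
    i <- which(src_s <= pos[k] & pos[k] < src_e)
    if (!length(i)) {
      stop(sprintf("position %d outside %s extent of %s", pos[k],
                   direction, chrom))
    }
    i <- i[1]
    if (m$segment_type[i] == "collinear") {
      status[k] <- "mapped"
      out[k] <- dst_s[i] + (pos[k] - src_s[i])
    } else {
      status[k] <- absent
    }
  }
  data.frame(status = status, pos = out, stringsAsFactors = FALSE)
}

#' Extract every event's sequence from the augmented genome
#'
#' Slices each event's augmented interval out of the built sequences;
#' by construction this returns the event's input sequence bit-exact.
#'
#' @param build An `hdr_build` object.
#' @return Named character vector (names = event ids).
#' @export
extract_event_sequences <- function(build) {
  m <- build$map[build$map$segment_type != "collinear", , drop = FALSE]
  out <- character(nrow(m))
  names(out) <- m$event_id
  for (i in seq_len(nrow(m))) {
    out[i] <- substr0(build$seq[[m$chrom[i]]], m$hdr_start[i], m$hdr_end[i])
  }
  out
}

#' Reconstruct the original reference from an augmented build
#'
#' Deletes inserted segments and restores replaced footprints from the
#' original reference recorded in the mapping table; used as a round-trip
#' integrity check.
#'
#' @param build An `hdr_build` object.
#' @param ref The original reference (needed to restore replaced bases).
#' @return Named character vector of reconstructed reference sequences.
#' @export
reconstruct_reference <- function(build, ref) {
  out <- character(0)
  for (ch_aug in unique(build$map$chrom)) {
    ch <- if (nzchar(build$name_suffix)) {
      sub(paste0(build$name_suffix, "$"), "", ch_aug)
    } else ch_aug
    m <- build$map[build$map$chrom == ch_aug, , drop = FALSE]
    m <- m[order(m$ref_start, m$hdr_start), , drop = FALSE]
    parts <- character(0)
    for (i in seq_len(nrow(m))) {
      parts <- c(parts, switch(m$segment_type[i],
        collinear = substr0(build$seq[[ch_aug]], m$hdr_start[i], m$hdr_end[i]),
        inserted = "",
        replaced = substr0(ref[[ch]], m$ref_start[i], m$ref_end[i])))
    }
    out[ch] <- paste(parts, collapse = "")
  }
  out
}

#' Build the augmented diversity reference end to end
#'
#' Deduplicates gap fills, removes NUIs conflicting with them, and
#' integrates the remainder.
#'
#' @inheritParams integrate
#' @return An `hdr_build` object.
#' @export
build_hdr <- function(ref, nuis, fills = NULL, name_suffix = "") {
  if (!is.null(fills) && nrow(fills)) {
    fills <- dedupe_gapfills(fills)
    nuis <- drop_conflicting_nuis(nuis, fills)
  }
  integrate_events(ref, nuis, fills, name_suffix)
}
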