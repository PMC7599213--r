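# Post-selection filters on representative NUIs: sequence-content rules
# (tandem / low-complexity fraction, undetermined-base rules), local density
# window rules, and a breakpoint-consistency check for small insertions.

#' Annotate the repeat and resolution content of a NUI sequence
#'
#' When no external intervals are supplied, the built-in tandem and
#' low-complexity detectors (see [mask_flags()]) stand in for the external
#' repeat annotation tools. `tandem_masked_frac` is the fraction flagged by
#' the tandem detector; `composite_lc_frac` the fraction flagged by either
#' detector (satellite + simple repeat + low-complexity analogue).
#'
#' @param sequence NUI sequence.
#' @param tandem_intervals,lc_intervals Optional data.frames with
#'   `start`/`end` (0-based half-open, within the sequence) overriding the
#'   detectors.
#' @return List: `tandem_masked_frac`, `composite_lc_frac`, `n_count`,
#'   `resolved_count`, `unmasked_count`, `length`.
#' @export
annotate_repeat_content <- function(sequence, tandem_intervals = NULL,
                                    lc_intervals = NULL) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_n <- toupper(chars) == "N"
  iv_mask <- function(iv) {
    m <- logical(n)
    if (is.null(iv) || nrow(iv) == 0L) return(m)
    if (min(iv$start) < 0 || max(iv$end) > n) {
      stop("annotation intervals outside sequence bounds")
    }
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    }
    m & !is_n
  }
  tandem <- if (is.null(tandem_intervals)) {
    mask_flags(sequence, "tandem")
  } else iv_mask(tandem_intervals)
  lc <- if (is.null(lc_intervals)) {
    mask_flags(sequence, "both")
  } else (iv_mask(lc_intervals) | tandem)
  masked_any <- tandem | lc
  list(
    tandem_masked_frac = sum(tandem) / n,
    composite_lc_frac = sum(lc) / n,
    n_count = sum(is_n),
    resolved_count = n - sum(is_n),
    unmasked_count = sum(!masked_any & !is_n),
    length = n
  )
}

#' Sequence-content filter rules
#'
#' A NUI fails iff any of: (1) tandem-masked fraction > 0.8 and fewer than
#' 100 unmasked bases; (2) composite low-complexity fraction > 0.8 and
#' fewer than 100 unmasked bases; (3) more than 10 undetermined bases and
#' fewer than 50 resolved bases; (4) more than 100 undetermined bases and
#' fewer than 100 resolved bases.
#'
#' @param ann Annotation from [annotate_repeat_content()].
#' @return List with `pass` flag and `failed` rule ids (subset of
#'   `c("trf80", "lc80", "n10", "n100")`).
#' @export
apply_sequence_filters <- function(ann) {
  failed <- character(0)
  if (ann$tandem_masked_frac > 0.8 && ann$unmasked_count < 100) {
    failed <- c(failed, "trf80")
  }
  if (ann$composite_lc_frac > 0.8 && ann$unmasked_count < 100) {
    failed <- c(failed, "lc80")
  }
  if (ann$n_count > 10 && ann$resolved_count < 50) {
    failed <- c(failed, "n10")
  }
  if (ann$n_count > 100 && ann$resolved_count < 100) {
    failed <- c(failed, "n100")
  }
  list(pass = length(failed) == 0L, failed = failed)
}

# maximal runs of sorted start positions fitting in a span of `window` bp
# with more than `max_n` members -> indices flagged
.window_violations <- function(starts, window, max_n) {
  n <- length(starts)
  flagged <- logical(n)
  j <- 1L
  for (i in seq_len(n)) {
    while (j < n && starts[j + 1L] - starts[i] <= window) j <- j + 1L
    if (j - i + 1L > max_n) flagged[i:j] <- TRUE
    if (j == n) break
  }
  flagged
}

#' Local-density window filters
#'
#' Two sliding rules per chromosome over representative footprint starts:
#' any run of more than five representatives within a 200 bp span is
#' removed outright (these regions are dominated by low-complexity
#' artefacts); then, among any remaining run of more than two within a
#' 50 bp span, only the single largest insertion is kept (ties to the
#' alphabetically first sample id).
#'
#' @param reps Representative table (`nui_rep` schema).
#' @return List with `kept`, `removed` (with a `rule` column:
#'   `"window200"` / `"window50"`).
#' @export
apply_window_filters <- function(reps) {
  if (nrow(reps) == 0L) {
    return(list(kept = reps, removed = cbind(reps, rule = character(0))))
  }
  reps <- reps[order(reps$chrom, reps$ref_start), , drop = FALSE]
  removed <- list()
  drop200 <- logical(nrow(reps))
  for (ch in unique(reps$chrom)) {
    i <- which(reps$chrom == ch)
    drop200[i] <- .window_violations(reps$ref_start[i], 200L, 5L)
  }
  if (any(drop200)) {
    removed[[length(removed) + 1L]] <-
      cbind(reps[drop200, , drop = FALSE], rule = "window200")
  }
  reps2 <- reps[!drop200, , drop = FALSE]
  drop50 <- logical(nrow(reps2))
  for (ch in unique(reps2$chrom)) {
    i <- which(reps2$chrom == ch)
    flag <- .window_violations(reps2$ref_start[i], 50L, 2L)
    if (!any(flag)) next
    # within each maximal flagged run keep only the largest insertion
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      run <- i[starts[k]:ends[k]]
      keep <- run[order(-reps2$insert_size[run], reps2$sample_id[run])][1]
      drop50[setdiff(run, keep)] <- TRUE
    }
  }
  if (any(drop50)) {
    removed[[length(removed) + 1L]] <-
      cbind(reps2[drop50, , drop = FALSE], rule = "window50")
  }
  kept <- reps2[!drop50, , drop = FALSE]
  rownames(kept) <- NULL
  removed <- if (length(removed)) do.call(rbind, removed) else
    cbind(reps[0, , drop = FALSE], rule = character(0))
  list(kept = kept, removed = removed)
}

#' Breakpoint-consistency filter for small insertions
#'
#' A representative smaller than 50 bp is retained only if at least two
#' distinct samples in its cluster share its exact reference insertion
#' point (`ref_start` and `ref_end`). Larger representatives are not
#' subject to the rule.
#'
#' @param reps Representative table.
#' @param members Clustered calls with `cluster_id` (from
#'   [select_representatives()]).
#' @return List with `kept` and `removed` (with `rule = "breakpoint"`).
#' @export
breakpoint_consistency_filter <- function(reps, members) {
  if (nrow(reps) == 0L) {
    return(list(kept = reps, removed = cbind(reps, rule = character(0))))
  }
  keep <- rep(TRUE, nrow(reps))
  for (i in seq_len(nrow(reps))) {
    if (reps$insert_size[i] >= 50L) next
    m <- members[members$cluster_id == reps$cluster_id[i], , drop = FALSE]
    same <- m[m$ref_start == reps$ref_start[i] &
                m$ref_end == reps$ref_end[i], , drop = FALSE]
    keep[i] <- length(unique(same$sample_id)) >= 2L
  }
  removed <- if (any(!keep)) {
    cbind(reps[!keep, , drop = FALSE], rule = "breakpoint")
  } else cbind(reps[0, , drop = FALSE], rule = character(0))
  list(kept = reps[keep, , drop = FALSE], removed = removed)
}

#' Classify the repeat type of a NUI
#'
#' The label is the repeat family covering the largest share of the
#' sequence, provided that share is at least 50%; otherwise `"none"`.
#'
#' @param sequence NUI sequence.
#' @param families Optional data.frame with `start`, `end` (0-based
#'   half-open within the sequence) and `family`.
#' @return Character label.
#' @export
classify_repeat_type <- function(sequence, families = NULL) {
  n <- nchar(sequence)
  if (is.null(families) || nrow(families) == 0L) return("none")
  if (min(families$start) < 0 || max(families$end) > n) {
    stop("family intervals outside sequence bounds")
  }
  cov <- tapply(families$end - families$start, families$family, sum)
  top <- sort(names(cov)[cov == max(cov)])[1]
  if (cov[[top]] / n >= 0.5) top else "none"
}

#' Run the full filter cascade on representative NUIs
#'
#' Order: sequence-content rules, then the 200 bp window rule, then the
#' 50 bp window rule, then breakpoint consistency. The cascade is
#' idempotent: re-running it on its own kept output removes nothing.
#'
#' @param reps Representative table.
#' @param members Clustered calls (for the breakpoint rule).
#' @param tandem_intervals,lc_intervals Optional per-NUI named lists of
#'   external annotation intervals (names = `nui_id`).
#' @return List with `kept` and `report` (one row per removed NUI with the
#'   failed rule id).
#' @export
filter_nuis <- function(reps, members, tandem_intervals = NULL,
                        lc_intervals = NULL) {
  report <- list()
  if (nrow(reps)) {
    fail_seq <- character(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      ann <- annotate_repeat_content(
        reps$sequence[i],
        tandem_intervals[[reps$nui_id[i]]],
        lc_intervals[[reps$nui_id[i]]]
      )
      res <- apply_sequence_filters(ann)
      if (!res$pass) fail_seq[i] <- paste(res$failed, collapse = ",")
    }
    if (any(nzchar(fail_seq))) {
      report[[length(report) + 1L]] <-
        cbind(reps[nzchar(fail_seq), , drop = FALSE],
              rule = fail_seq[nzchar(fail_seq)])
    }
    reps <- reps[!nzchar(fail_seq), , drop = FALSE]
  }
  win <- apply_window_filters(reps)
  if (nrow(win$removed)) report[[length(report) + 1L]] <- win$removed
  bp <- breakpoint_consistency_filter(win$kept, members)
  if (nrow(bp$removed)) report[[length(report) + 1L]] <- bp$removed
  kept <- bp$kept
  rownames(kept) <- NULL
  report <- if (length(report)) do.call(rbind, report) else
    cbind(reps[0, , drop = FALSE], rule = character(0))
  rownames(report) <- NULL
  list(kept = kept, report = report)
}
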