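# Cross-sample clustering of insertion calls and representative selection.
#
# Calls whose reference breakpoints overlap by >= 1 bp form a component;
# within a component, padded and soft-masked sequences are multiply aligned
# (center-star), every member gets a consensus-based global score over its
# inserted segment, and members are recursively clustered at 80% pairwise
# identity to the best-scoring founder. The top scorer of each cluster whose
# footprint is not already represented becomes a representative NUI.

.call_insert_size <- function(calls) {
  nchar(calls$sequence) - (calls$ref_end - calls$ref_start)
}

#' Group insertion calls into breakpoint-overlap components
#'
#' Components are the transitive closure of >= 1 bp reference-footprint
#' overlap; zero-length footprints (pure insertion points) are expanded to
#' 1 bp for the overlap test, so two insertions at positions 100 and 101
#' (half-open) do not share a base and fall into different components.
#'
#' @param calls data.frame of insertion calls (`nui_call` schema).
#' @return `calls` with a `component_id` column (deterministic id from the
#'   component's chromosome and minimal start).
#' @export
build_components <- function(calls) {
  stopifnot_cols(calls, c("chrom", "ref_start", "ref_end", "sample_id"),
                 "calls")
  calls$component_id <- rep(NA_character_, nrow(calls))
  if (nrow(calls) == 0L) return(calls)
  for (ch in unique(calls$chrom)) {
    i <- which(calls$chrom == ch)
    r <- iranges0(calls$ref_start[i], calls$ref_end[i])
    merged <- IRanges::reduce(r, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(r, merged, minoverlap = 1L)
    comp <- integer(length(i))
    comp[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
    min_start <- tapply(calls$ref_start[i], comp, min)
    calls$component_id[i] <- sprintf("%s:%d", ch,
                                     as.integer(min_start[as.character(comp)]))
  }
  calls
}

#' Drop single-sample components
#'
#' A component supported by a single sample -- even through both of its
#' haplotypes -- is discarded: recurrence in at least two individuals is
#' required.
#'
#' @param calls data.frame with `component_id` (see [build_components()]).
#' @param min_support Minimum number of distinct samples (default 2).
#' @return Filtered data.frame.
#' @export
drop_singletons <- function(calls, min_support = 2L) {
  if (nrow(calls) == 0L) return(calls)
  n_samp <- tapply(calls$sample_id, calls$component_id,
                   function(x) length(unique(x)))
  keep <- names(n_samp)[n_samp >= min_support]
  calls[calls$component_id %in% keep, , drop = FALSE]
}

#' Pad component members with reference context
#'
#' When at least one member's insert size exceeds 50 bp, each member's text
#' becomes `ref[min_start - 50, ref_start) + sequence + ref[ref_end,
#' max_end + 50)` (clipped at chromosome ends), where min/max are taken over
#' the component; otherwise the raw inserted sequences are used alone.
#' Shorter insertions tend to share exact breakpoints, where padding adds
#' nothing but alignment cost.
#'
#' @param members data.frame of one component's calls.
#' @param ref Named character vector of reference sequences.
#' @return List with one element per member: `text`, `insert_start`,
#'   `insert_end` (0-based half-open span of the inserted segment within
#'   `text`).
#' @export
pad_component <- function(members, ref) {
  sizes <- .call_insert_size(members)
  chrom <- members$chrom[1]
  if (!chrom %in% names(ref)) stop("reference lacks chromosome ", chrom)
  use_pad <- any(sizes > 50L)
  lapply(seq_len(nrow(members)), function(i) {
    seq_i <- members$sequence[i]
    if (!use_pad) {
      return(list(text = seq_i, insert_start = 0L,
                  insert_end = nchar(seq_i)))
    }
    chrom_seq <- ref[[chrom]]
    lo <- max(0L, min(members$ref_start) - 50L)
    hi <- min(nchar(chrom_seq), max(members$ref_end) + 50L)
    left <- substr0(chrom_seq, lo, members$ref_start[i])
    right <- substr0(chrom_seq, members$ref_end[i], hi)
    list(text = paste0(left, seq_i, right),
         insert_start = nchar(left),
         insert_end = nchar(left) + nchar(seq_i))
  })
}

# ---- center-star multiple alignment ----------------------------------------

# split a (center, row) pairwise alignment into per-center-slot pieces
.split_by_center <- function(ac, ar) {
  nc_ <- sum(ac != "-")
  ins <- rep(list(character(0)), nc_ + 1L)
  aligned <- character(nc_)
  ci <- 0L
  for (t in seq_along(ac)) {
    if (ac[t] == "-") {
      ins[[ci + 1L]] <- c(ins[[ci + 1L]], ar[t])
    } else {
      ci <- ci + 1L
      aligned[ci] <- ar[t]
    }
  }
  list(ins = ins, aligned = aligned)
}

.build_row <- function(split, global_ins, nc_) {
  parts <- vector("list", 2L * nc_ + 1L)
  for (i in seq_len(nc_ + 1L)) {
    blk <- split$ins[[i]]
    parts[[2L * i - 1L]] <- c(blk, rep("-", global_ins[i] - length(blk)))
    if (i <= nc_) parts[[2L * i]] <- split$aligned[i]
  }
  unlist(parts)
}

#' Multiple alignment of a component's padded sequences
#'
#' Deterministic center-star progressive alignment: the sequence with the
#' highest summed pairwise score against all others (ties to the earliest
#' input) is the center; every other sequence is globally aligned to it and
#' the pairwise gap patterns are merged ("once a gap, always a gap").
#'
#' @param padded List from [pad_component()] (texts already soft-masked as
#'   desired).
#' @param scheme A [pairwise_scheme()].
#' @return List with `rows` (equal-length gapped strings), `insert_cols`
#'   (per row, the MSA columns of its inserted segment), `ncol`.
#' @export
align_component <- function(padded, scheme = pairwise_scheme()) {
  k <- length(padded)
  if (k == 0L) stop("empty component")
  texts <- vapply(padded, `[[`, character(1), "text")
  spans <- lapply(padded, function(p) c(p$insert_start, p$insert_end))
  if (k == 1L || length(unique(texts)) == 1L) {
    n <- nchar(texts[1])
    return(list(
      rows = texts,
      insert_cols = lapply(spans, function(s) seq.int(s[1] + 1L, s[2])),
      ncol = n
    ))
  }
  # center = max total pairwise score
  sc <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- align_pair(texts[i], texts[j], scheme)$score
      sc[i, j] <- s; sc[j, i] <- s
    }
  }
  center <- which.max(rowSums(sc))
  nc_ <- nchar(texts[center])
  splits <- vector("list", k)
  for (i in seq_len(k)) {
    if (i == center) {
      splits[[i]] <- list(ins = rep(list(character(0)), nc_ + 1L),
                          aligned = strsplit(texts[center], "")[[1]])
    } else {
      al <- align_pair(texts[center], texts[i], scheme, traceback = TRUE)
      splits[[i]] <- .split_by_center(strsplit(al$aligned_a, "")[[1]],
                                      strsplit(al$aligned_b, "")[[1]])
    }
  }
  global_ins <- Reduce(pmax, lapply(splits, function(s) lengths(s$ins)))
  rows_chars <- lapply(splits, .build_row, global_ins = global_ins, nc_ = nc_)
  ncol_msa <- length(rows_chars[[1]])
  insert_cols <- vector("list", k)
  for (i in seq_len(k)) {
    nongap <- which(rows_chars[[i]] != "-")
    s <- spans[[i]]
    insert_cols[[i]] <- if (s[2] > s[1]) nongap[(s[1] + 1L):s[2]] else integer(0)
  }
  list(rows = vapply(rows_chars, paste, character(1), collapse = ""),
       insert_cols = insert_cols, ncol = ncol_msa)
}

#' Consensus-based global score of one MSA row
#'
#' Only the columns of the row's inserted segment contribute. Per column,
#' the consensus is the most frequent non-gap symbol across all rows
#' (case-insensitive; ties to the lexicographically smallest). The row then
#' scores match-unmasked +2 (uppercase) / match-masked +0.2 (lowercase) when
#' it equals the consensus, -0.5 for `N`, -1 for a differing base, 0 for a
#' gap.
#'
#' @param msa Result of [align_component()].
#' @param row Row index.
#' @param scheme A [global_scheme()].
#' @return Numeric score.
#' @export
global_score <- function(msa, row, scheme = global_scheme()) {
  cols <- msa$insert_cols[[row]]
  if (!length(cols)) return(0)
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  up <- toupper(mat)
  row_chars <- mat[row, cols]
  row_up <- up[row, cols]
  score <- 0
  for (idx in seq_along(cols)) {
    j <- cols[idx]
    col <- up[, j]
    col <- col[col != "-"]
    cnt <- table(col)
    consensus <- sort(names(cnt)[cnt == max(cnt)])[1]
    ch <- row_chars[idx]
    chu <- row_up[idx]
    score <- score + if (ch == "-") {
      scheme$gap
    } else if (chu == "N") {
      scheme$undetermined
    } else if (chu == consensus) {
      if (ch %in% c("a", "c", "g", "t")) scheme$match_masked
      else scheme$match_unmasked
    } else {
      scheme$mismatch
    }
  }
  score
}

# score all rows at once (same semantics as global_score, vectorized)
.global_scores_all <- function(msa, scheme = global_scheme()) {
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  up <- toupper(mat)
  consensus <- apply(up, 2L, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return("-")
    cnt <- table(col)
    sort(names(cnt)[cnt == max(cnt)])[1]
  })
  vapply(seq_along(msa$insert_cols), function(r) {
    cols <- msa$insert_cols[[r]]
    if (!length(cols)) return(0)
    ch <- mat[r, cols]
    chu <- up[r, cols]
    cons <- consensus[cols]
    sc <- ifelse(ch == "-", scheme$gap,
          ifelse(chu == "N", scheme$undetermined,
          ifelse(chu == cons,
                 ifelse(ch %in% c("a", "c", "g", "t"),
                        scheme$match_masked, scheme$match_unmasked),
                 scheme$mismatch)))
    sum(sc)
  }, numeric(1))
}

#' Recursive identity clustering within a component
#'
#' Members are sorted by descending global score (ties: sample id, then
#' haplotype id, alphabetical). The highest-scoring unassigned member founds
#' a cluster; every unassigned member with pairwise insert-segment identity
#' >= 0.8 (inclusive) to the founder joins; the process repeats on the
#' remainder until all members are assigned.
#'
#' @param members data.frame of one component's calls.
#' @param scores Numeric vector of global scores, parallel to `members`.
#' @param min_identity Identity threshold (default 0.8, inclusive).
#' @param scheme A [pairwise_scheme()].
#' @return Integer cluster index per member (1 = founded first) plus an
#'   attribute `order` giving the score-sorted member order.
#' @export
cluster_component <- function(members, scores, min_identity = 0.8,
                              scheme = pairwise_scheme()) {
  ord <- order(-scores, members$sample_id, members$haplotype_id)
  cluster <- integer(nrow(members))
  next_id <- 0L
  for (i in ord) {
    if (cluster[i] != 0L) next
    next_id <- next_id + 1L
    cluster[i] <- next_id
    for (j in ord) {
      if (cluster[j] != 0L) next
      ident <- pairwise_identity(members$sequence[i], members$sequence[j],
                                 scheme)
      if (ident >= min_identity) cluster[j] <- next_id
    }
  }
  attr(cluster, "order") <- ord
  cluster
}

#' Choose representative NUIs from a component's clusters
#'
#' Clusters are visited in founding order (descending top score); a
#' cluster's top member becomes a representative iff its expanded footprint
#' overlaps no previously accepted representative of the component. Support
#' is the number of distinct samples in the cluster; clusters below
#' `min_support` are not eligible (recurrence in at least two individuals is
#' part of the NUI definition) and do not reserve footprint space.
#'
#' @param members data.frame of one component's calls.
#' @param cluster Integer vector from [cluster_component()].
#' @param scores Global scores parallel to `members`.
#' @param min_support Minimum distinct samples per cluster (default 2).
#' @return data.frame of representatives with cluster metadata.
#' @export
pick_representatives <- function(members, cluster, scores,
                                 min_support = 2L) {
  ord <- attr(cluster, "order")
  reps <- list()
  for (cl in seq_len(max(cluster))) {
    in_cl <- which(cluster == cl)
    if (length(unique(members$sample_id[in_cl])) < min_support) next
    top <- in_cl[order(match(in_cl, ord))][1]
    fs <- members$ref_start[top]
    fe <- max(members$ref_end[top], fs + 1L)
    clash <- FALSE
    for (r in reps) {
      rs <- r$ref_start
      re <- max(r$ref_end, rs + 1L)
      if (fs < re && rs < fe) { clash <- TRUE; break }
    }
    if (clash) next
    reps[[length(reps) + 1L]] <- data.frame(
      member_idx = top,
      ref_start = members$ref_start[top],
      ref_end = members$ref_end[top],
      cluster = cl,
      support_samples = length(unique(members$sample_id[in_cl])),
      global_score = scores[top],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, reps)
}

#' Select representative NUIs from region-filtered calls
#'
#' Runs the full per-component pipeline: component formation, singleton
#' removal, context padding, soft-masking, center-star multiple alignment,
#' consensus scoring, 80%-identity clustering, and representative selection.
#'
#' @param calls data.frame of insertion calls (`nui_call` schema).
#' @param ref Named character vector of reference sequences.
#' @param min_support Minimum distinct samples per component (default 2).
#' @param min_identity Clustering identity threshold (default 0.8).
#' @param mask_mode Detector selection for [soft_mask()], or `"none"`.
#' @param pair_scheme,cons_scheme Scoring schemes.
#' @return List with `reps` (representative table, `nui_rep` schema) and
#'   `members` (all clustered calls with `component_id`/`cluster_id`).
#' @export
select_representatives <- function(calls, ref, min_support = 2L,
                                   min_identity = 0.8,
                                   mask_mode = "both",
                                   pair_scheme = pairwise_scheme(),
                                   cons_scheme = global_scheme()) {
  calls <- build_components(calls)
  calls <- drop_singletons(calls, min_support)
  if (nrow(calls) == 0L) {
    return(list(reps = .empty_reps(), members = calls))
  }
  calls$cluster_id <- NA_character_
  reps_out <- list()
  for (cid in unique(calls$component_id)) {
    idx <- which(calls$component_id == cid)
    members <- calls[idx, , drop = FALSE]
    padded <- pad_component(members, ref)
    if (!identical(mask_mode, "none")) {
      for (i in seq_along(padded)) {
        padded[[i]]$text <- soft_mask(padded[[i]]$text, mask_mode)
      }
    }
    msa <- align_component(padded, pair_scheme)
    scores <- .global_scores_all(msa, cons_scheme)
    cluster <- cluster_component(members, scores, min_identity, pair_scheme)
    calls$cluster_id[idx] <- sprintf("%s/c%d", cid, cluster)
    picks <- pick_representatives(members, cluster, scores, min_support)
    if (is.null(picks)) next
    for (p in seq_len(nrow(picks))) {
      i <- picks$member_idx[p]
      reps_out[[length(reps_out) + 1L]] <- data.frame(
        nui_id = sprintf("NUI_%s_%d", members$chrom[i],
                         members$ref_start[i]),
        chrom = members$chrom[i],
        ref_start = members$ref_start[i],
        ref_end = members$ref_end[i],
        insert_size = .call_insert_size(members[i, , drop = FALSE]),
        sample_id = members$sample_id[i],
        haplotype_id = members$haplotype_id[i],
        support_samples = picks$support_samples[p],
        global_score = picks$global_score[p],
        component_id = cid,
        cluster_id = sprintf("%s/c%d", cid, picks$cluster[p]),
        sequence = members$sequence[i],
        stringsAsFactors = FALSE
      )
    }
  }
  reps <- if (length(reps_out)) do.call(rbind, reps_out) else .empty_reps()
  if (nrow(reps)) {
    reps <- reps[order(reps$chrom, reps$ref_start), , drop = FALSE]
    rownames(reps) <- NULL
    dup <- duplicated(reps$nui_id)
    if (any(dup)) {
      reps$nui_id[dup] <- paste0(reps$nui_id[dup], "_",
                                 seq_len(sum(dup)))
    }
  }
  list(reps = reps, members = calls)
}

.empty_reps <- function() {
  data.frame(nui_id = character(0), chrom = character(0),
             ref_start = integer(0), ref_end = integer(0),
             insert_size = integer(0), sample_id = character(0),
             haplotype_id = character(0), support_samples = integer(0),
             global_score = numeric(0), component_id = character(0),
             cluster_id = character(0), sequence = character(0),
             stringsAsFactors = FALSE)
}
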