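# Orthogonal validation of representative NUIs against optical-map
# insertion calls, and novelty comparison against external callsets.

#' Optical-map concordance of large NUIs
#'
#' Only NUIs with insert size >= `min_size` (default 1000) and no
#' undetermined bases are evaluated; the rest are `not_evaluated`.
#' Optical calls whose between-label distance exceeds `max_label_dist`
#' (default 500 kb) are discarded first -- inferred sizes in sparsely
#' labeled regions are unreliable. An evaluated NUI is supported if its
#' expanded footprint intersects any remaining call's label interval padded
#' by `pad` (default 5 kb) on both sides; support from any sample counts.
#' A supported NUI is `concordant_size` when some supporting call satisfies
#' `|nui_size - bn_size| <= min(700, 0.2 * bn_size)`, else
#' `concordant_site_only`; unsupported evaluated NUIs are `unsupported`.
#'
#' @param nuis Representative table.
#' @param optical Optical-call table (`optical` schema).
#' @param pad Label-interval padding (default 5000).
#' @param max_label_dist Between-label distance cutoff (default 500000).
#' @param min_size Evaluation size threshold (default 1000).
#' @param size_tol_abs,size_tol_rel The min(700 bp, 20%) size rule.
#' @return data.frame: `nui_id`, `status`, `support_sample`.
#' @export
optical_concordance <- function(nuis, optical, pad = 5000L,
                                max_label_dist = 500000L,
                                min_size = 1000L,
                                size_tol_abs = 700, size_tol_rel = 0.2) {
  if (!is.null(optical) && nrow(optical)) {
    optical <- optical[(optical$label_end - optical$label_start) <=
                         max_label_dist, , drop = FALSE]
  }
  out <- data.frame(nui_id = nuis$nui_id,
                    status = rep("not_evaluated", nrow(nuis)),
                    support_sample = rep(".", nrow(nuis)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(nuis))) {
    if (nuis$insert_size[i] < min_size) next
    if (grepl("N", nuis$sequence[i], ignore.case = TRUE)) next
    fs <- nuis$ref_start[i]
    fe <- max(nuis$ref_end[i], fs + 1L)
    status <- "unsupported"; supp <- "."
    if (!is.null(optical) && nrow(optical)) {
      o <- optical[optical$chrom == nuis$chrom[i], , drop = FALSE]
      for (j in seq_len(nrow(o))) {
        os <- o$label_start[j] - pad
        oe <- o$label_end[j] + pad
        if (!(fs < oe && os < fe)) next
        tol <- min(size_tol_abs, size_tol_rel * o$insert_size[j])
        if (abs(nuis$insert_size[i] - o$insert_size[j]) <= tol) {
          status <- "concordant_size"; supp <- o$sample[j]
          break
        }
        if (status == "unsupported") {
          status <- "concordant_site_only"; supp <- o$sample[j]
        }
      }
    }
    out$status[i] <- status
    out$support_sample[i] <- supp
  }
  out
}

#' Compare NUIs against external variant callsets
#'
#' A NUI is `known` iff at least one external variant overlaps its
#' expanded footprint by >= 1 bp and the size ratio `nui_size / ext_size`
#' lies in \[0.9, 1.1\] for small NUIs (< 50 bp) or \[0.5, 2\] for large
#' NUIs (>= 50 bp), bounds inclusive; otherwise `novel`.
#'
#' @param nuis Representative table.
#' @param externals External variant table (`external` schema).
#' @param small_max Small/large size split (default 50).
#' @return data.frame: `nui_id`, `size_class`, `label`.
#' @export
compare_callsets <- function(nuis, externals, small_max = 50L) {
  out <- data.frame(
    nui_id = nuis$nui_id,
    size_class = ifelse(nuis$insert_size < small_max, "small", "large"),
    label = rep("novel", nrow(nuis)),
    stringsAsFactors = FALSE)
  if (is.null(externals) || nrow(externals) == 0L) return(out)
  for (i in seq_len(nrow(nuis))) {
    fs <- nuis$ref_start[i]; fe <- max(nuis$ref_end[i], fs + 1L)
    bounds <- if (out$size_class[i] == "small") c(0.9, 1.1) else c(0.5, 2)
    e <- externals[externals$chrom == nuis$chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      es <- e$start[j]; ee <- max(e$end[j], es + 1L)
      if (!(fs < ee && es < fe)) next
      ratio <- nuis$insert_size[i] / e$size[j]
      if (ratio >= bounds[1] && ratio <= bounds[2]) {
        out$label[i] <- "known"
        break
      }
    }
  }
  out
}
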