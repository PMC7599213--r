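# Pairwise alignment wrappers around the compiled Gotoh engine, plus the two
# scoring schemes used for representative selection.

#' Pairwise scoring scheme for identity clustering
#'
#' Match +1, mismatch -4, undetermined (N) 0, gap opening -4, gap extension 0
#' by default. A gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param match,mismatch,n_score,gap_open,gap_extend Scheme constants.
#' @return Named list of scheme constants.
#' @export
pairwise_scheme <- function(match = 1, mismatch = -4, n_score = 0,
                            gap_open = -4, gap_extend = 0) {
  list(match = match, mismatch = mismatch, n_score = n_score,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Consensus (global) scoring scheme for representative selection
#'
#' Match of an unmasked base +2, match of a soft-masked (lowercase) base
#' +0.2, mismatch -1, undetermined base (N) -0.5, gap 0.
#'
#' @param match_unmasked,match_masked,mismatch,undetermined,gap Scheme
#'   constants.
#' @return Named list of scheme constants.
#' @export
global_scheme <- function(match_unmasked = 2, match_masked = 0.2,
                          mismatch = -1, undetermined = -0.5, gap = 0) {
  list(match_unmasked = match_unmasked, match_masked = match_masked,
       mismatch = mismatch, undetermined = undetermined, gap = gap)
}

#' Global pairwise alignment (Gotoh, affine gaps)
#'
#' Maximizes alignment score under `scheme`; among score-optimal alignments
#' the matched-column count is itself maximized, so the reported `matches`
#' (and any identity derived from it) does not depend on traceback
#' tie-breaking. Case-insensitive; `N` against anything scores
#' `scheme$n_score` and never counts as a match.
#'
#' @param a,b DNA strings.
#' @param scheme A [pairwise_scheme()].
#' @param traceback If `TRUE`, also return the two gapped aligned strings.
#' @return List with `score`, `matches`, and (with traceback) `aligned_a`,
#'   `aligned_b`.
#' @export
align_pair <- function(a, b, scheme = pairwise_scheme(), traceback = FALSE) {
  .gotoh_align_cpp(a, b, scheme$match, scheme$mismatch, scheme$n_score,
                   scheme$gap_open, scheme$gap_extend, traceback)
}

#' Pairwise sequence identity between two inserted segments
#'
#' Globally aligns the two segments under the pairwise scheme and reports
#' `matched columns / min(nchar(a), nchar(b))`. The shorter-segment
#' denominator makes a sequence fully identical to a sub-fragment of the
#' other score 1.0, which is the intended grouping behaviour for partially
#' resolved copies of one insertion.
#'
#' @param a,b Inserted segments (non-empty DNA strings).
#' @param scheme A [pairwise_scheme()].
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, scheme = pairwise_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("inserted segments must be non-empty")
  if (identical(toupper(a), toupper(b)) && !grepl("N", a, ignore.case = TRUE)) {
    return(1)
  }
  res <- align_pair(a, b, scheme, traceback = FALSE)
  min(1, res$matches / min(nchar(a), nchar(b)))
}
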