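# End-to-end orchestration: per-sample calling -> exclusions -> clustering
# and representative selection -> filters. The unit a downstream HDR build
# consumes.

#' Run the NUI discovery pipeline over a cohort
#'
#' @param cohort List as returned by [simulate_cohort()], or any list with
#'   `ref` and `samples` (per sample: `assembly`, `blocks`).
#' @param blacklist,segdups Optional exclusion tracks
#'   (`chrom`/`start`/`end`).
#' @param core_chroms Allowed chromosomes (default: all reference names).
#' @param min_size Minimum insert size (default 10).
#' @param min_support Minimum distinct samples per component (default 2).
#' @param mask_mode Soft-masking mode for scoring (see [soft_mask()]).
#' @param ... Passed through to [call_sample()].
#' @return List: `calls` (all region-filtered calls), `reps`
#'   (pre-filter representatives), `members`, `kept` (filtered
#'   representative NUIs), `filter_report`.
#' @export
run_discovery <- function(cohort, blacklist = NULL, segdups = NULL,
                          core_chroms = NULL, min_size = 10L,
                          min_support = 2L, mask_mode = "both", ...) {
  if (is.null(core_chroms)) core_chroms <- names(cohort$ref)
  calls <- list()
  for (smp in names(cohort$samples)) {
    s <- cohort$samples[[smp]]
    calls[[smp]] <- call_sample(s$blocks, s$assembly, sample_id = smp,
                                min_size = min_size, ...)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  calls <- apply_region_exclusions(calls, blacklist, segdups, core_chroms)
  sel <- select_representatives(calls, cohort$ref,
                                min_support = min_support,
                                mask_mode = mask_mode)
  filt <- filter_nuis(sel$reps, sel$members)
  list(calls = calls, reps = sel$reps, members = sel$members,
       kept = filt$kept, filter_report = filt$report)
}
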