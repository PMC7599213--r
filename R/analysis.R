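# Discovery-saturation modeling, genic/frame annotation, and the
# tissue-specific expression statistic.

#' Rarefaction (saturation) curve of NUI discovery
#'
#' For each n, the mean over `n_perm` seeded random sample orderings of the
#' number of distinct NUI ids contributed by the first n samples.
#'
#' @param sample_sets Named list: sample id -> character vector of NUI ids.
#' @param n_perm Number of permutations (default 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return data.frame with `n` and `mean_count`; non-decreasing in `n`.
#' @export
rarefaction <- function(sample_sets, n_perm = 100L, seed) {
  if (length(sample_sets) < 2L) stop("need at least 2 samples")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  k <- length(sample_sets)
  acc <- matrix(0, n_perm, k)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      ord <- sample.int(k)
      seen <- character(0)
      for (n in seq_len(k)) {
        seen <- unique(c(seen, sample_sets[[ord[n]]]))
        acc[p, n] <- length(seen)
      }
    }
  })
  data.frame(n = seq_len(k), mean_count = colMeans(acc))
}

#' Project per-sample NUI discovery growth
#'
#' Fits `f(n) = a * n^b` to the last `n_points` rarefaction points by least
#' squares in log-log space and reports the projected yield of one
#' additional sample, `f(N + 1) - f(N)`. When any of the fitted points is
#' <= 0 the fit falls back to a straight line.
#'
#' @param curve data.frame from [rarefaction()].
#' @param n_points Number of trailing points to fit (default 10).
#' @return List: `a`, `b` (NA for the linear fallback), `increment`,
#'   `model` (`"power"` or `"linear"`).
#' @export
project_growth <- function(curve, n_points = 10L) {
  tail_n <- min(n_points, nrow(curve))
  pts <- curve[(nrow(curve) - tail_n + 1L):nrow(curve), , drop = FALSE]
  if (nrow(pts) < 2L) stop("need at least 2 points to fit growth")
  N <- max(curve$n)
  if (any(pts$mean_count <= 0)) {
    fit <- stats::lm(mean_count ~ n, data = pts)
    inc <- unname(stats::coef(fit)[2])
    return(list(a = NA_real_, b = NA_real_, increment = max(0, inc),
                model = "linear"))
  }
  fit <- stats::lm(log(mean_count) ~ log(n), data = pts)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  inc <- a * (N + 1)^b - a * N^b
  list(a = a, b = b, increment = max(0, inc), model = "power")
}

#' Reading-frame classification of NUIs
#'
#' An insertion is in-frame iff its size is a multiple of 3. The summary
#' fraction is computed over NUIs below `size_class_max` (default 50 bp),
#' the size class where the 3 bp periodicity of exonic insertions shows.
#'
#' @param nuis Representative table (or any data.frame with `insert_size`).
#' @param size_class_max Size-class ceiling for the fraction (default 50).
#' @return List: `in_frame` (logical per NUI), `fraction` (in-frame
#'   fraction among NUIs with size < `size_class_max`).
#' @export
frame_classify <- function(nuis, size_class_max = 50L) {
  in_frame <- nuis$insert_size %% 3L == 0L
  small <- nuis$insert_size < size_class_max
  frac <- if (any(small)) mean(in_frame[small]) else NA_real_
  list(in_frame = in_frame, fraction = frac)
}

#' Genic annotation of NUIs with feature-priority resolution
#'
#' Each NUI is labeled with the highest-priority feature class its expanded
#' footprint overlaps, in the order coding exon > 3'UTR > 5'UTR > intron;
#' no overlap is `intergenic`. Regulatory-feature overlap is reported as a
#' separate flag.
#'
#' @param nuis Representative table.
#' @param features data.frame with `chrom`, `start`, `end`, `feature`
#'   (values among `"coding_exon"`, `"utr3"`, `"utr5"`, `"intron"`).
#' @param regulatory Optional data.frame with `chrom`, `start`, `end`.
#' @return data.frame: `nui_id`, `genic_label`, `regulatory`.
#' @export
annotate_genic <- function(nuis, features, regulatory = NULL) {
  priority <- c("coding_exon", "utr3", "utr5", "intron")
  label <- rep("intergenic", nrow(nuis))
  for (i in seq_len(nrow(nuis))) {
    fs <- nuis$ref_start[i]; fe <- max(nuis$ref_end[i], fs + 1L)
    f <- features[features$chrom == nuis$chrom[i] &
                    features$start < fe & fs < pmax(features$end,
                                                    features$start + 1L), ,
                  drop = FALSE]
    if (nrow(f) == 0L) next
    hitp <- priority[priority %in% f$feature]
    if (length(hitp)) label[i] <- hitp[1]
  }
  reg <- overlaps_track(nuis$chrom, nuis$ref_start, nuis$ref_end, regulatory)
  data.frame(nui_id = nuis$nui_id, genic_label = label, regulatory = reg,
             stringsAsFactors = FALSE)
}

#' Tissue-specific gene expression calls
#'
#' Genes with fewer than `min_total` combined raw counts across all samples
#' are excluded, the rest are log2(count + 1)-transformed, and for every
#' tissue each gene is tested with a Welch unequal-variance two-sample
#' t-test of that tissue's samples against all other samples pooled.
#' P-values are Benjamini-Hochberg adjusted within each tissue; a gene is
#' tissue-specific iff the adjusted p-value is < `alpha` and t > `t_min`.
#' Zero-variance degenerate genes are skipped with a message.
#'
#' @param counts Numeric matrix, genes x samples (raw counts).
#' @param tissue Character vector of tissue labels, one per column.
#' @param min_total Minimum combined raw count per gene (default 10).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param t_min t-statistic threshold (default 3).
#' @return data.frame: `gene`, `tissue`, `t`, `p`, `p_adj`, `specific`.
#' @export
tissue_specificity <- function(counts, tissue, min_total = 10,
                               alpha = 0.05, t_min = 3) {
  if (ncol(counts) != length(tissue)) {
    stop("one tissue label per sample column required")
  }
  if (any(table(tissue) < 2L)) stop("need >= 2 samples per tissue")
  keep <- rowSums(counts) >= min_total
  n_drop <- sum(!keep)
  if (n_drop) {
    message(sprintf("tissue_specificity: excluding %d low-count gene(s)",
                    n_drop))
  }
  counts <- counts[keep, , drop = FALSE]
  x <- log2(counts + 1)
  genes <- rownames(x)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(x)))
  out <- list()
  for (ti in unique(tissue)) {
    in_t <- tissue == ti
    tt <- rep(NA_real_, nrow(x)); pp <- rep(NA_real_, nrow(x))
    for (g in seq_len(nrow(x))) {
      a <- x[g, in_t]; b <- x[g, !in_t]
      if (stats::var(a) == 0 && stats::var(b) == 0) next
      ht <- stats::t.test(a, b, var.equal = FALSE)
      tt[g] <- unname(ht$statistic)
      pp[g] <- ht$p.value
    }
    skipped <- is.na(pp)
    if (any(skipped)) {
      message(sprintf(
        "tissue_specificity: %d degenerate gene(s) skipped in %s",
        sum(skipped), ti))
    }
    padj <- rep(NA_real_, nrow(x))
    padj[!skipped] <- stats::p.adjust(pp[!skipped], method = "BH")
    out[[ti]] <- data.frame(
      gene = genes, tissue = ti, t = tt, p = pp, p_adj = padj,
      specific = !is.na(padj) & padj < alpha & tt > t_min,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
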