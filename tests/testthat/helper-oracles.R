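# Independent oracles used to check the package implementation. These are
# deliberately written as straightforward, matrix-based brute force and
# never call the code paths they verify.

# full 3-matrix Gotoh DP over (score, matches) pairs, lexicographic max;
# gap run of length L costs go + L * ge
oracle_gotoh <- function(a, b, match = 1, mismatch = -4, nscore = 0,
                         go = -4, ge = 0) {
  A <- toupper(strsplit(a, "")[[1]])
  B <- toupper(strsplit(b, "")[[1]])
  n <- length(A); m <- length(B)
  NEG <- -1e15
  Ms <- matrix(NEG, n + 1, m + 1); Mm <- matrix(0, n + 1, m + 1)
  Xs <- matrix(NEG, n + 1, m + 1); Xm <- matrix(0, n + 1, m + 1)
  Ys <- matrix(NEG, n + 1, m + 1); Ym <- matrix(0, n + 1, m + 1)
  Ms[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) Xs[i, 1] <- go + ge * (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Ys[1, j] <- go + ge * (j - 1)
  pickmax <- function(ss, mm) {
    best <- 1
    for (k in seq_along(ss)[-1]) {
      if (ss[k] > ss[best] || (ss[k] == ss[best] && mm[k] > mm[best])) {
        best <- k
      }
    }
    c(ss[best], mm[best])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (A[i] == "N" || B[j] == "N") { sub <- nscore; mt <- 0 }
      else if (A[i] == B[j]) { sub <- match; mt <- 1 }
      else { sub <- mismatch; mt <- 0 }
      d <- pickmax(c(Ms[i, j], Xs[i, j], Ys[i, j]),
                   c(Mm[i, j], Xm[i, j], Ym[i, j]))
      Ms[i + 1, j + 1] <- if (d[1] <= NEG) NEG else d[1] + sub
      Mm[i + 1, j + 1] <- d[2] + mt
      x <- pickmax(c(Ms[i, j + 1] + go + ge, Xs[i, j + 1] + ge,
                     Ys[i, j + 1] + go + ge),
                   c(Mm[i, j + 1], Xm[i, j + 1], Ym[i, j + 1]))
      Xs[i + 1, j + 1] <- x[1]; Xm[i + 1, j + 1] <- x[2]
      y <- pickmax(c(Ms[i + 1, j] + go + ge, Xs[i + 1, j] + go + ge,
                     Ys[i + 1, j] + ge),
                   c(Mm[i + 1, j], Xm[i + 1, j], Ym[i + 1, j]))
      Ys[i + 1, j + 1] <- y[1]; Ym[i + 1, j + 1] <- y[2]
    }
  }
  fin <- pickmax(c(Ms[n + 1, m + 1], Xs[n + 1, m + 1], Ys[n + 1, m + 1]),
                 c(Mm[n + 1, m + 1], Xm[n + 1, m + 1], Ym[n + 1, m + 1]))
  list(score = fin[1], matches = fin[2])
}

oracle_identity <- function(a, b) {
  r <- oracle_gotoh(a, b)
  min(1, r$matches / min(nchar(a), nchar(b)))
}

# plain column-walk consensus scorer over an MSA row's insert columns
oracle_global_score <- function(rows, insert_cols_row, row) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  total <- 0
  for (j in insert_cols_row) {
    column <- toupper(mat[, j])
    column <- column[column != "-"]
    counts <- sort(table(column), decreasing = TRUE)
    top <- counts[counts == counts[1]]
    consensus <- sort(names(top))[1]
    ch <- mat[row, j]
    if (ch == "-") next              # gap scores 0
    if (toupper(ch) == "N") { total <- total - 0.5; next }
    if (toupper(ch) == consensus) {
      total <- total + if (ch %in% letters) 0.2 else 2
    } else {
      total <- total - 1
    }
  }
  total
}

# union-find partition of intervals under >=1 bp overlap (0-based
# half-open, zero-length expanded to 1 bp)
oracle_components <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  e <- pmax(end, start + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && chrom[i] == chrom[j] &&
          start[i] < e[j] && start[j] < e[i]) {
        parent[find(j)] <- find(i)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# cut-and-splice string rebuild of an augmented chromosome
oracle_splice <- function(ref_seq, events) {
  ev <- events[order(events$ref_start), , drop = FALSE]
  out <- ""
  pos <- 0L
  for (i in seq_len(nrow(ev))) {
    out <- paste0(out, substr(ref_seq, pos + 1L, ev$ref_start[i]),
                  ev$sequence[i])
    pos <- ev$ref_end[i]
  }
  paste0(out, substr(ref_seq, pos + 1L, nchar(ref_seq)))
}

# brute-force optical size-concordance rule
oracle_size_concordant <- function(nui_size, bn_size) {
  abs(nui_size - bn_size) <= min(700, 0.2 * bn_size)
}

# closed-form Welch t statistic and df
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

rand_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal representative table builder for filter/validation tests
make_reps <- function(chrom, ref_start, ref_end, sequence,
                      sample_id = NULL, cluster_id = NULL) {
  n <- length(ref_start)
  if (n == 0L) {
    return(make_reps("chr0", 0L, 0L, "AAAAAAAAAA")[0, , drop = FALSE])
  }
  data.frame(
    nui_id = sprintf("NUI%03d", seq_len(n)),
    chrom = chrom, ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_end),
    insert_size = nchar(sequence) - (as.integer(ref_end) -
                                       as.integer(ref_start)),
    sample_id = if (is.null(sample_id)) sprintf("S%02d", seq_len(n)) else
      sample_id,
    haplotype_id = "1",
    support_samples = 2L,
    global_score = as.numeric(nchar(sequence)) * 2,
    component_id = sprintf("%s:%d", chrom, as.integer(ref_start)),
    cluster_id = if (is.null(cluster_id)) {
      sprintf("%s:%d/c1", chrom, as.integer(ref_start))
    } else cluster_id,
    sequence = sequence,
    stringsAsFactors = FALSE
  )
}
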