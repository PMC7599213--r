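# Internal helpers shared across modules. All coordinates in this package are
# 0-based half-open, both in memory and on disk (BED-compatible).

#' Reverse complement of a DNA string
#'
#' Case is preserved (lowercase stays lowercase) and `N`/`n` map to
#' themselves, so soft-masking annotations survive the operation.
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}` plus lowercase.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# substr with 0-based half-open coordinates
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# IRanges from 0-based half-open intervals, zero-length intervals expanded to
# 1 bp (the convention used throughout for overlap tests on insertion points)
iranges0 <- function(start, end) {
  end <- pmax(end, start + 1L)
  IRanges::IRanges(start = start + 1L, end = end)
}

# TRUE for rows of (chrom, start, end) whose expanded footprint overlaps any
# interval of `track` (a data.frame with chrom/start/end, 0-based half-open)
overlaps_track <- function(chrom, start, end, track) {
  hit <- logical(length(chrom))
  if (is.null(track) || nrow(track) == 0L) return(hit)
  for (ch in unique(chrom)) {
    qi <- which(chrom == ch)
    ti <- which(track$chrom == ch)
    if (!length(ti)) next
    q <- iranges0(start[qi], end[qi])
    s <- iranges0(track$start[ti], track$end[ti])
    hit[qi] <- IRanges::overlapsAny(q, s)
  }
  hit
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

# deterministic RNG scope: run expr under a seed, restore state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
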