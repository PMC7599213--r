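# Built-in low-complexity and tandem-repeat detectors. These are declared
# stand-ins for the external repeat annotation tools a production run would
# use (window-entropy for low-complexity DNA, a period-scan for tandem
# arrays); externally supplied masked intervals override them everywhere.

# logical mask from a windowed triplet-entropy detector: windows whose 3-mer
# Shannon entropy falls below `min_entropy` bits are flagged wholesale
.mask_entropy <- function(chars, window = 64L, step = 16L,
                          min_entropy = 2.5) {
  n <- length(chars)
  mask <- logical(n)
  if (n < 12L) return(mask)
  window <- min(window, n)
  up <- toupper(chars)
  starts <- unique(c(seq.int(1L, max(1L, n - window + 1L), by = step),
                     n - window + 1L))
  for (s in starts) {
    w <- up[s:(s + window - 1L)]
    if (any(w == "N")) next
    tri <- paste0(w[1:(window - 2L)], w[2:(window - 1L)], w[3:window])
    p <- table(tri) / length(tri)
    h <- -sum(p * log2(p))
    if (h < min_entropy) mask[s:(s + window - 1L)] <- TRUE
  }
  mask
}

# logical mask from a tandem-array detector: period <= max_period,
# adjacent-copy identity >= min_identity, array length >= min_array
.mask_tandem <- function(chars, max_period = 100L, min_identity = 0.8,
                         min_array = 20L) {
  n <- length(chars)
  mask <- logical(n)
  if (n < min_array) return(mask)
  up <- toupper(chars)
  informative <- up != "N"
  for (p in seq_len(min(max_period, n %/% 2L))) {
    e <- (up[1:(n - p)] == up[(p + 1L):n]) &
      informative[1:(n - p)] & informative[(p + 1L):n]
    w <- max(p, 12L)
    if (length(e) < w) next
    cs <- cumsum(c(0L, as.integer(e)))
    frac <- (cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]) / w
    hits <- which(frac >= min_identity)
    if (!length(hits)) next
    flag <- logical(n)
    for (h in hits) flag[h:min(n, h + w + p - 1L)] <- TRUE
    # keep only flagged regions long enough to be an array
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= min_array) {
        mask[starts[k]:ends[k]] <- TRUE
      }
    }
  }
  mask & informative
}

#' Flag low-complexity / tandem-repeat positions of a sequence
#'
#' @param text DNA string.
#' @param mode `"both"` (default), `"entropy"` (low-complexity only) or
#'   `"tandem"` (tandem arrays only).
#' @return Logical vector, one element per base; `N` positions are never
#'   flagged.
#' @export
mask_flags <- function(text, mode = c("both", "entropy", "tandem")) {
  mode <- match.arg(mode)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  m <- logical(length(chars))
  if (mode %in% c("both", "entropy")) m <- m | .mask_entropy(chars)
  if (mode %in% c("both", "tandem")) m <- m | .mask_tandem(chars)
  m[toupper(chars) == "N"] <- FALSE
  m
}

#' Soft-mask a sequence (lowercase flagged positions)
#'
#' Positions flagged by the built-in detectors -- or by externally supplied
#' intervals -- are lowercased; letters are never altered, so the masked
#' sequence degaps/uppercases back to the input.
#'
#' @param text DNA string.
#' @param mode Detector selection, see [mask_flags()].
#' @param intervals Optional data.frame with `start`/`end` (0-based
#'   half-open) of externally masked regions; when given, the detectors are
#'   skipped.
#' @return The soft-masked string.
#' @export
soft_mask <- function(text, mode = "both", intervals = NULL) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  if (!is.null(intervals)) {
    if (nrow(intervals) &&
        (min(intervals$start) < 0 || max(intervals$end) > length(chars))) {
      stop("external mask intervals outside sequence bounds")
    }
    m <- logical(length(chars))
    for (i in seq_len(nrow(intervals))) {
      if (intervals$end[i] > intervals$start[i]) {
        m[(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
      }
    }
    m[toupper(chars) == "N"] <- FALSE
  } else {
    m <- mask_flags(text, mode)
  }
  chars[m] <- tolower(chars[m])
  paste(chars, collapse = "")
}
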