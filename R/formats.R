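# On-disk formats. FASTA is parsed in-package rather than through Biostrings
# because the scoring model depends on lowercase soft-masking, which XString
# containers do not preserve. All tables are tab-separated with a versioned
# comment header recording the coordinate convention.

.FASTA_WRAP <- 60L

#' Read a FASTA file, preserving case
#'
#' Lowercase encodes soft-masked bases and `N` undetermined bases; both are
#' kept verbatim. IUPAC ambiguity letters other than ACGTN are converted to
#' `N` (`n` when lowercase) with a message reporting the count. Any other
#' character is an error, as are duplicate record names and empty files.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path)
  idx <- cumsum(hdr)
  names_full <- sub("^>", "", lines[hdr])
  nm <- vapply(strsplit(names_full, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                 collapse = "")
  # split() drops groups for header-only records; forbid those
  if (length(seqs) != length(nm)) stop("FASTA record with no sequence lines")
  names(seqs) <- nm
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad)) {
    n_conv <- sum(vapply(seqs[bad], function(s) {
      sum(strsplit(s, "")[[1]] %in%
            strsplit("RYSWKMBDHVUryswkmbdhvu", "")[[1]])
    }, numeric(1)))
    converted <- chartr("RYSWKMBDHVUryswkmbdhvu",
                        "NNNNNNNNNNNnnnnnnnnnnn", seqs[bad])
    if (any(grepl("[^ACGTNacgtn]", converted))) {
      stop("non-sequence characters in FASTA: ", path)
    }
    seqs[bad] <- converted
    message(sprintf("read_fasta: converted %d ambiguity base(s) to N", n_conv))
  }
  if (any(nchar(seqs) == 0L)) stop("FASTA record with empty sequence")
  seqs
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = .FASTA_WRAP)
    writeLines(substring(s, starts, pmin(starts + .FASTA_WRAP - 1L, n)), con)
  }
  invisible(path)
}

# ---- alignment interchange (PAF with cg cigar tag) --------------------------

.cigar_ops <- function(cigar) {
  m <- gregexpr("([0-9]+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1L) stop("unparseable cigar: ", cigar)
  toks <- regmatches(cigar, gregexpr("([0-9]+)([MIDNSHP=X])", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) stop("unparseable cigar: ", cigar)
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  op[op %in% c("=", "X")] <- "M"
  if (any(!op %in% c("M", "I", "D"))) {
    stop("unsupported cigar op in: ", cigar)
  }
  data.frame(op = op, len = len)
}

#' Parse one PAF alignment line
#'
#' Requires the 12 mandatory PAF fields plus a `cg:Z:` cigar tag. Consumed
#' lengths implied by the cigar are checked against the query and reference
#' spans; a mismatch is rejected with a diagnostic. Negative-strand records
#' keep forward-strand query coordinates (standard PAF convention).
#'
#' @param line A single tab-separated PAF line.
#' @return One-row data.frame with columns `query_name`, `query_length`,
#'   `query_start`, `query_end`, `strand`, `ref_name`, `ref_length`,
#'   `ref_start`, `ref_end`, `mapq`, `is_primary`, `cigar`.
#' @export
parse_alignment <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 12L) stop("PAF line has fewer than 12 fields")
  tags <- f[-(1:12)]
  cg <- tags[startsWith(tags, "cg:Z:")]
  if (!length(cg)) stop("PAF line lacks cg:Z: cigar tag")
  cigar <- sub("^cg:Z:", "", cg[1])
  tp <- tags[startsWith(tags, "tp:A:")]
  is_primary <- if (length(tp)) sub("^tp:A:", "", tp[1]) == "P" else TRUE
  blk <- data.frame(
    query_name = f[1], query_length = as.integer(f[2]),
    query_start = as.integer(f[3]), query_end = as.integer(f[4]),
    strand = f[5],
    ref_name = f[6], ref_length = as.integer(f[7]),
    ref_start = as.integer(f[8]), ref_end = as.integer(f[9]),
    mapq = as.integer(f[12]), is_primary = is_primary, cigar = cigar,
    stringsAsFactors = FALSE
  )
  ops <- .cigar_ops(cigar)
  q_len <- sum(ops$len[ops$op %in% c("M", "I")])
  r_len <- sum(ops$len[ops$op %in% c("M", "D")])
  if (q_len != blk$query_end - blk$query_start) {
    stop(sprintf("cigar query length %d != span %d (%s)",
                 q_len, blk$query_end - blk$query_start, f[1]))
  }
  if (r_len != blk$ref_end - blk$ref_start) {
    stop(sprintf("cigar reference length %d != span %d (%s)",
                 r_len, blk$ref_end - blk$ref_start, f[1]))
  }
  if (blk$query_start < 0 || blk$query_start >= blk$query_end ||
      blk$query_end > blk$query_length ||
      blk$ref_start < 0 || blk$ref_start >= blk$ref_end ||
      blk$ref_end > blk$ref_length) {
    stop("alignment coordinates out of bounds (", f[1], ")")
  }
  if (!blk$strand %in% c("+", "-")) stop("strand must be + or -")
  blk
}

#' Read a PAF alignment file
#'
#' @param path Path to a PAF file (with `cg:Z:` tags).
#' @return data.frame of alignment blocks (see [parse_alignment()]).
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(parse_alignment("q\t1\t0\t1\t+\tr\t1\t0\t1\t1\t1\t60\tcg:Z:1M")[0, ])
  }
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    out[[i]] <- tryCatch(parse_alignment(lines[i]), error = function(e) {
      stop(sprintf("%s line %d: %s", path, i, conditionMessage(e)),
           call. = FALSE)
    })
  }
  do.call(rbind, out)
}

#' Write alignment blocks as PAF
#'
#' @param blocks data.frame of alignment blocks.
#' @param path Output path.
#' @export
write_paf <- function(blocks, path) {
  if (nrow(blocks) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  lines <- apply(blocks, 1L, function(r) {
    ops <- .cigar_ops(r[["cigar"]])
    nm <- sum(ops$len[ops$op == "M"])
    alen <- sum(ops$len)
    paste(r[["query_name"]], r[["query_length"]], r[["query_start"]],
          r[["query_end"]], r[["strand"]], r[["ref_name"]], r[["ref_length"]],
          r[["ref_start"]], r[["ref_end"]], nm, alen, r[["mapq"]],
          paste0("tp:A:", if (as.logical(r[["is_primary"]])) "P" else "S"),
          paste0("cg:Z:", r[["cigar"]]), sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# ---- versioned TSV tables ---------------------------------------------------

.TSV_VERSION <- "1"

.tsv_schemas <- list(
  nui_call = c(sample_id = "character", haplotype_id = "character",
               chrom = "character", ref_start = "integer",
               ref_end = "integer", query_name = "character",
               query_start = "integer", query_end = "integer",
               strand = "character", sequence = "character"),
  nui_rep = c(nui_id = "character", chrom = "character",
              ref_start = "integer", ref_end = "integer",
              insert_size = "integer", sample_id = "character",
              haplotype_id = "character", support_samples = "integer",
              global_score = "numeric", component_id = "character",
              cluster_id = "character", sequence = "character"),
  mapping = c(chrom = "character", segment_type = "character",
              ref_start = "integer", ref_end = "integer",
              hdr_start = "integer", hdr_end = "integer",
              event_id = "character"),
  optical = c(sample = "character", chrom = "character",
              label_start = "integer", label_end = "integer",
              insert_size = "numeric"),
  gap = c(chrom = "character", start = "integer", end = "integer",
          gap_type = "character", closure_status = "character",
          fill_sequence = "character", source_scaffold = "character"),
  gapfill = c(chrom = "character", ref_start = "integer",
              ref_end = "integer", sequence = "character",
              source_scaffold = "character", closure_status = "character",
              n_gaps = "integer"),
  external = c(chrom = "character", start = "integer", end = "integer",
               size = "numeric", source = "character"),
  truth_event = c(event_id = "character", kind = "character",
                  chrom = "character", pos = "integer", size = "integer",
                  sequence = "character", carriers = "character"),
  generic = NULL
)

#' Write a versioned TSV table
#'
#' The first line is a comment header carrying the format version, the table
#' type, and the coordinate convention (0-based half-open). Numeric columns
#' are serialized with full precision so that `read_table(write_table(x))`
#' is bit-exact.
#'
#' @param records data.frame to write.
#' @param path Output path.
#' @param type Schema name (one of `names(nuiforge:::.tsv_schemas)`), or
#'   `"generic"` for untyped tables.
#' @export
write_table <- function(records, path, type = "generic") {
  if (!type %in% names(.tsv_schemas)) stop("unknown table type: ", type)
  schema <- .tsv_schemas[[type]]
  if (!is.null(schema)) stopifnot_cols(records, names(schema), type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#nuiforge_tsv\tversion=%s\ttype=%s\tcoords=0-based-half-open",
                     .TSV_VERSION, type), con)
  df <- records
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a versioned TSV table
#'
#' @param path Path written by [write_table()].
#' @param type Expected schema name; checked against the file header.
#' @return data.frame with schema-typed columns.
#' @export
read_table <- function(path, type = "generic") {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#nuiforge_tsv")) stop("not a nuiforge TSV: ", path)
  hf <- strsplit(first, "\t", fixed = TRUE)[[1]]
  ver <- sub("^version=", "", hf[startsWith(hf, "version=")])
  ftype <- sub("^type=", "", hf[startsWith(hf, "type=")])
  if (!identical(ver, .TSV_VERSION)) {
    stop(sprintf("unknown table version '%s' in %s", ver, path))
  }
  if (!identical(ftype, type)) {
    stop(sprintf("table type mismatch: file says '%s', expected '%s'",
                 ftype, type))
  }
  schema <- .tsv_schemas[[type]]
  lines <- readLines(path)[-1L]
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  body <- lines[-1L]
  if (!length(body)) {
    df <- stats::setNames(rep(list(character(0)), length(header)), header)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(body, "\t", fixed = TRUE)
    ncols <- lengths(parts)
    bad <- which(ncols != length(header))
    if (length(bad)) {
      stop(sprintf("%s line %d: expected %d columns, found %d",
                   path, bad[1] + 2L, length(header), ncols[bad[1]]))
    }
    mat <- matrix(unlist(parts), ncol = length(header), byrow = TRUE)
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- header
  }
  if (!is.null(schema)) {
    stopifnot_cols(df, names(schema), type)
    for (col in names(schema)) {
      df[[col]] <- switch(schema[[col]],
        integer = as.integer(df[[col]]),
        numeric = as.numeric(df[[col]]),
        logical = as.logical(df[[col]]),
        df[[col]])
    }
  }
  df
}

#' Read a BED-like track (chrom, start, end[, name])
#'
#' @param path Path to a BED file (plain 3+ columns, optional `#` comments).
#' @return data.frame with `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed BED row in ", path)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[`, character(1), 3L)),
    name = vapply(parts, function(p) if (length(p) >= 4L) p[4L] else ".",
                  character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a BED-like track
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  stopifnot_cols(df, cols, "BED")
  out <- df[, c(cols, intersect("name", names(df)))]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
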