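# Readers/writers for the standard formats the pipeline touches. BED6 for
# genes and CGIs; an extended-BED dialect for ERVs (columns 7+: family,
# element_type, ltr5_start, ltr5_end, ltr3_start, ltr3_end, polymorphism,
# with "." for absent LTR fields); bedGraph via rtracklayer.

#' Read genomic features from BED / extended BED
#'
#' Genes and CGIs are read from BED6 (`chrom start end name score strand`;
#' CGIs need only the first three columns). ERVs use an extended-BED dialect
#' with columns 7-13 carrying `family`, `element_type`, the two LTR
#' sub-intervals and the polymorphism state. All coordinates are 0-based
#' half-open. For genes the strand decides which edge is the TSS: `start` on
#' `+`, `end` on `-` (point positions).
#'
#' @param path file path.
#' @param kind one of `"gene"`, `"cgi"`, `"erv"`.
#' @return a [gene_table()], [cgi_table()] or [erv_table()].
#' @export
read_features <- function(path, kind = c("gene", "cgi", "erv")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  ncols <- c(gene = 6L, cgi = 3L, erv = 13L)[[kind]]
  bad <- which(vapply(fields, length, integer(1)) < ncols)
  if (length(bad)) {
    stop(sprintf("malformed %s line %d in %s: expected >= %d fields",
                 kind, lineno[bad[1]], path, ncols))
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncols)))
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) & m[, j] != ".")
    if (length(bad)) stop(sprintf("malformed %s line %d in %s: non-numeric '%s'",
                                  kind, lineno[bad[1]], path, m[bad[1], j]))
    v
  }
  start <- num(2); end <- num(3)
  if (kind == "cgi") return(cgi_table(m[, 1], start, end))
  if (kind == "gene") {
    strand <- m[, 6]
    gene_table(gene_id = m[, 4], chrom = m[, 1], strand = strand,
               tss = ifelse(strand == "+", start, end),
               tts = ifelse(strand == "+", end, start))
  } else {
    erv_table(erv_id = m[, 4], family = m[, 7], element_type = m[, 8],
              chrom = m[, 1], start = start, end = end, strand = m[, 6],
              ltr5_start = num(9), ltr5_end = num(10),
              ltr3_start = num(11), ltr3_end = num(12),
              polymorphism = m[, 13])
  }
}

#' Write genomic features to BED / extended BED
#'
#' Inverse of [read_features()]; `write_features` then `read_features` is the
#' identity on validated tables.
#'
#' @param x a gene, CGI or ERV table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path) {
  fmt <- function(v) ifelse(is.na(v), ".", format(v, scientific = FALSE, trim = TRUE))
  df <- if (inherits(x, "gene_table")) {
    data.frame(x$chrom, fmt(pmin(x$tss, x$tts)), fmt(pmax(x$tss, x$tts)),
               x$gene_id, 0L, x$strand)
  } else if (inherits(x, "cgi_table")) {
    data.frame(x$chrom, fmt(x$start), fmt(x$end))
  } else if (inherits(x, "erv_table")) {
    data.frame(x$chrom, fmt(x$start), fmt(x$end), x$erv_id, 0L, x$strand,
               x$family, x$element_type, fmt(x$ltr5_start), fmt(x$ltr5_end),
               fmt(x$ltr3_start), fmt(x$ltr3_end), x$polymorphism)
  } else stop("unsupported feature table of class ", class(x)[1])
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four-column bedGraph; intervals must be non-overlapping per chromosome
#' (overlap would make the signal ambiguous). Positions not covered read back
#' as 0 on query.
#'
#' @param path bedGraph file.
#' @return a [signal_track()].
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  signal_track(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               S4Vectors::mcols(gr)$score)
}

#' Write a signal track as bedGraph
#'
#' @param x a [signal_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end),
                               score = x$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Query a signal track at single positions
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name (scalar).
#' @param pos numeric vector of 0-based positions.
#' @return signal values; 0 where no interval covers the position.
#' @export
query_track <- function(track, chrom, pos) {
  d <- track[track$chrom == chrom, , drop = FALSE]
  if (!nrow(d)) return(rep(0, length(pos)))
  i <- findInterval(pos, d$start)
  v <- rep(0, length(pos))
  hit <- i >= 1 & ifelse(i >= 1, pos < d$end[pmax(i, 1)], FALSE)
  v[hit] <- d$value[i[hit]]
  v
}

#' Distance between an interval and a point
#'
#' Gap convention on 0-based half-open intervals: 0 when the point falls
#' inside `[start, end)` (and also at `end`, where the gap to the right edge
#' is zero); otherwise `start - point` to the left of the interval and
#' `point - end` to its right. So a point at 2437 sits 437 bp from
#' `[1000, 2000)`, and a point at 999 sits 1 bp left of start 1000.
#'
#' @param start,end interval (vectorized).
#' @param point position (vectorized).
#' @return non-negative distances in bases.
#' @export
distance_between <- function(start, end, point) {
  if (any(start >= end)) stop("interval requires start < end")
  pmax(start - point, point - end, 0)
}
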