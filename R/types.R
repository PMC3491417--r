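# Domain types. Feature tables are plain data.frames with a fixed column
# contract, validated at construction; heavier S4 machinery is reserved for
# the interval work that actually needs it (GenomicRanges / IRanges).

#' Construct a genome model
#'
#' A genome model is the coordinate backdrop for random-insertion simulation:
#' a set of named chromosomes with lengths. Coordinates everywhere in the
#' package are 0-based half-open (BED convention).
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in bases (>= 1).
#' @return A `genome_model` data.frame with columns `chrom`, `length`.
#' @examples
#' genome_model(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_model <- function(chrom, length) {
  if (length(chrom) != length(length)) {
    stop("chrom and length must have equal length")
  }
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  structure(
    data.frame(chrom = as.character(chrom), length = length,
               stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

#' Construct a gene table
#'
#' Genes are anchored by their transcription start site (TSS) and
#' transcription termination site (TTS), both point positions. On the `-`
#' strand the TSS has the larger genomic coordinate.
#'
#' @param gene_id,chrom,strand,tss,tts parallel vectors; `strand` in `+`/`-`.
#' @param promoter_is_cgi optional logical (filled by
#'   [classify_cgi_promoter()]).
#' @return A validated `gene_table` data.frame.
#' @export
gene_table <- function(gene_id, chrom, strand, tss, tts, promoter_is_cgi = NA) {
  df <- data.frame(
    gene_id = as.character(gene_id), chrom = as.character(chrom),
    strand = as.character(strand), tss = as.numeric(tss),
    tts = as.numeric(tts), promoter_is_cgi = promoter_is_cgi,
    stringsAsFactors = FALSE
  )
  validate_genes(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_genes <- function(df) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tts") %in% names(df)))
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(df$tss == df$tts)) stop("gene tss must differ from tts")
  bad_plus <- df$strand == "+" & df$tss > df$tts
  bad_minus <- df$strand == "-" & df$tss < df$tts
  if (any(bad_plus | bad_minus)) {
    stop("strand-inconsistent TSS/TTS for gene(s): ",
         paste(df$gene_id[bad_plus | bad_minus], collapse = ", "))
  }
  invisible(df)
}

#' Construct a CpG island table
#'
#' @param chrom,start,end parallel vectors; intervals 0-based half-open.
#' @return A `cgi_table` data.frame.
#' @export
cgi_table <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("CGI intervals require start < end")
  class(df) <- c("cgi_table", "data.frame")
  df
}

#' Construct an ERV copy table
#'
#' Each row is one ERV copy. Full-length elements carry two long terminal
#' repeats (LTRs) stored as sub-intervals (`ltr5_*`, `ltr3_*`); solo LTRs are
#' a single LTR spanning the whole element (stored in the `ltr5_*` columns
#' with `ltr3_*` set `NA`). On the `+` strand the 5' LTR is the left one.
#'
#' @param erv_id,family,element_type,chrom,start,end,strand parallel vectors;
#'   `family` in `ETn/MusD`/`IAP`, `element_type` in `solo`/`full_length`.
#' @param ltr5_start,ltr5_end,ltr3_start,ltr3_end LTR sub-intervals (bases).
#' @param polymorphism `fixed` or `polymorphic`.
#' @return A validated `erv_table` data.frame.
#' @export
erv_table <- function(erv_id, family, element_type, chrom, start, end, strand,
                      ltr5_start = NA, ltr5_end = NA,
                      ltr3_start = NA, ltr3_end = NA,
                      polymorphism = "fixed") {
  df <- data.frame(
    erv_id = as.character(erv_id), family = as.character(family),
    element_type = as.character(element_type), chrom = as.character(chrom),
    start = as.numeric(start), end = as.numeric(end),
    strand = as.character(strand),
    ltr5_start = as.numeric(ltr5_start), ltr5_end = as.numeric(ltr5_end),
    ltr3_start = as.numeric(ltr3_start), ltr3_end = as.numeric(ltr3_end),
    polymorphism = as.character(polymorphism), stringsAsFactors = FALSE
  )
  validate_ervs(df)
  class(df) <- c("erv_table", "data.frame")
  df
}

validate_ervs <- function(df) {
  need <- c("erv_id", "family", "element_type", "chrom", "start", "end",
            "strand", "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("erv table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (!all(df$family %in% c("ETn/MusD", "IAP"))) {
    stop("family must be 'ETn/MusD' or 'IAP'")
  }
  if (!all(df$element_type %in% c("solo", "full_length"))) {
    stop("element_type must be 'solo' or 'full_length'")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("erv strand must be '+' or '-'")
  if (any(df$start >= df$end)) stop("erv intervals require start < end")
  fl <- df$element_type == "full_length"
  if (any(fl & (is.na(df$ltr5_start) | is.na(df$ltr3_start)))) {
    stop("full_length elements require both LTR sub-intervals")
  }
  in_span <- function(s, e) s >= df$start & e <= df$end & s < e
  if (any(fl & !(in_span(df$ltr5_start, df$ltr5_end) &
                 in_span(df$ltr3_start, df$ltr3_end)))) {
    stop("LTR sub-interval outside element span")
  }
  # LTRs disjoint; 5' LTR on the strand-appropriate side
  overlap <- fl & pmax(df$ltr5_start, df$ltr3_start) <
    pmin(df$ltr5_end, df$ltr3_end)
  if (any(overlap, na.rm = TRUE)) stop("LTR sub-intervals overlap")
  wrong_side <- fl & ifelse(df$strand == "+",
                            df$ltr5_start >= df$ltr3_start,
                            df$ltr5_start <= df$ltr3_start)
  if (any(wrong_side, na.rm = TRUE)) {
    stop("5' LTR on the wrong side for the element strand")
  }
  solo <- df$element_type == "solo"
  solo_bad <- solo & !(df$ltr5_start == df$start & df$ltr5_end == df$end &
                       is.na(df$ltr3_start))
  if (any(solo_bad, na.rm = TRUE) || any(solo & is.na(df$ltr5_start))) {
    stop("solo elements must carry exactly one LTR spanning the element")
  }
  invisible(df)
}

#' Construct a signal track
#'
#' A bedGraph-style per-chromosome step function: disjoint intervals with a
#' finite numeric value; positions not covered by any interval read as 0.
#'
#' @param chrom,start,end,value parallel vectors (0-based half-open).
#' @return A `signal_track` data.frame sorted by (chrom, start).
#' @export
signal_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(df$start >= df$end)) stop("signal intervals require start < end")
  if (any(!is.finite(df$value))) stop("signal values must be finite")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  ov <- unlist(lapply(split(df, df$chrom), function(d) {
    if (nrow(d) > 1) d$start[-1] < d$end[-nrow(d)] else logical(0)
  }), use.names = FALSE)
  if (any(ov)) stop("overlapping intervals in signal track (ambiguous signal)")
  class(df) <- c("signal_track", "data.frame")
  df
}

#' Construct an expression state table
#'
#' Binary on/off expression per (gene, tissue), the oracle used to pick the
#' tissue in which a copy's methylation is interpreted.
#'
#' @param gene_id,tissue,expressed parallel vectors; `expressed` logical.
#' @return An `expression_table` data.frame.
#' @export
expression_table <- function(gene_id, tissue, expressed) {
  df <- data.frame(gene_id = as.character(gene_id),
                   tissue = as.character(tissue),
                   expressed = as.logical(expressed), stringsAsFactors = FALSE)
  if (any(is.na(df$expressed))) stop("expressed must be TRUE/FALSE")
  if (anyDuplicated(df[c("gene_id", "tissue")])) {
    stop("duplicate (gene_id, tissue) entries")
  }
  class(df) <- c("expression_table", "data.frame")
  df
}

#' Query expression state
#'
#' @param tab an [expression_table()].
#' @param gene_id,tissue scalars.
#' @return `TRUE`/`FALSE`; errors if the pair is not declared (the table is a
#'   total function over declared genes x tissues).
#' @export
is_expressed <- function(tab, gene_id, tissue) {
  i <- which(tab$gene_id == gene_id & tab$tissue == tissue)
  if (length(i) != 1) stop("no expression state for (", gene_id, ", ", tissue, ")")
  tab$expressed[i]
}

#' Construct a bisulfite clone set
#'
#' Holds, for one region and tissue, the sequenced clones: per-clone CpG
#' methylation calls plus the positions of unconverted non-CpG cytosines
#' (conversion errors), which drive the quality filters.
#'
#' @param region_id,tissue scalars.
#' @param clones list; each element a list with `cpg` (logical vector, TRUE =
#'   methylated), `nonconv` (integer offsets of unconverted non-CpG Cs) and
#'   `n_noncpg_c` (total non-CpG cytosines assayed).
#' @return A `bisulfite_clone_set` object.
#' @export
bisulfite_clone_set <- function(region_id, tissue, clones) {
  ncpg <- vapply(clones, function(cl) length(cl$cpg), integer(1))
  if (length(clones) && length(unique(ncpg)) != 1) {
    stop("all clones of a region must call the same CpG sites")
  }
  for (cl in clones) {
    if (any(cl$nonconv > cl$n_noncpg_c) || any(cl$nonconv < 1)) {
      stop("nonconversion positions outside the non-CpG cytosine range")
    }
  }
  structure(list(region_id = region_id, tissue = tissue, clones = clones),
            class = "bisulfite_clone_set")
}

#' @export
print.bisulfite_clone_set <- function(x, ...) {
  cat("<bisulfite_clone_set> region", x$region_id, "tissue", x$tissue, "-",
      length(x$clones), "clones\n")
  invisible(x)
}

#' Construct a statistical test result
#'
#' @param statistic numeric test statistic.
#' @param p_value probability in \[0,1\] (or `NA` when degenerate).
#' @param method short description of the test performed.
#' @param degenerate flag set when the input made the p-value undefined.
#' @return An `erv_test` object carrying `statistic`, `p_value`, `method`,
#'   `stars` and `degenerate`.
#' @export
test_result <- function(statistic, p_value, method, degenerate = FALSE) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value outside [0,1]")
  }
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 stars = significance_stars(p_value), degenerate = degenerate),
            class = "erv_test")
}

#' @export
print.erv_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s%s\n", x$method,
              x$statistic, x$p_value, x$stars,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Significance stars
#'
#' Annotation convention used in the figures: `***` for p < 0.001, `**` for
#' p < 0.01, `*` for p < 0.05 (strict inequalities), empty otherwise.
#'
#' @param p probability (vectorized; `NA` gives `""`).
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  out <- ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", ""))))
  as.character(out)
}
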