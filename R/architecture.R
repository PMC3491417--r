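# LTR-gene architecture: CGI-promoter classification, proximal-LTR
# orientation calls, the orientation/CGI association table, differential LTR
# methylation, spreading assessment, and the copy-filtering rules.

#' Classify genes as CGI-promoter genes
#'
#' A promoter is a CGI promoter when any CpG island overlaps the half-open
#' window `[tss - window, tss + window)` (default window 1.5 kb).
#'
#' @param genes a [gene_table()].
#' @param cgis a [cgi_table()].
#' @param window half-width of the promoter window in bases.
#' @return the gene table with `promoter_is_cgi` filled.
#' @export
classify_cgi_promoter <- function(genes, cgis, window = 1500) {
  if (!nrow(cgis)) {
    genes$promoter_is_cgi <- rep(FALSE, nrow(genes))
    return(genes)
  }
  prom <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$tss - window + 1, genes$tss + window))
  cgi <- GenomicRanges::GRanges(cgis$chrom,
                                IRanges::IRanges(cgis$start + 1, cgis$end))
  hits <- GenomicRanges::findOverlaps(prom, cgi)
  genes$promoter_is_cgi <- seq_len(nrow(genes)) %in%
    S4Vectors::queryHits(hits)
  genes
}

#' Proximal LTR of a full-length ERV relative to a gene TSS
#'
#' Returns which LTR (5' or 3') lies closer to the gene's TSS, with the edge
#' distance measured from that LTR's nearest edge. Equidistant LTRs (element
#' centered on the TSS) break the tie to the 5' LTR with a flag.
#'
#' @param erv one-row [erv_table()] slice (full-length).
#' @param gene one-row [gene_table()] slice.
#' @return list of class `ltr_orientation_call`: `erv_id`, `gene_id`,
#'   `proximal_ltr` (`"5prime"`/`"3prime"`), `distance_to_tss`,
#'   `promoter_is_cgi`, `tie`.
#' @export
proximal_ltr <- function(erv, gene) {
  if (erv$element_type != "full_length") {
    stop("proximal_ltr is only defined for full-length elements (",
         erv$erv_id, " is ", erv$element_type, ")")
  }
  if (erv$chrom != gene$chrom) stop("erv and gene on different chromosomes")
  d5 <- distance_between(erv$ltr5_start, erv$ltr5_end, gene$tss)
  d3 <- distance_between(erv$ltr3_start, erv$ltr3_end, gene$tss)
  tie <- d5 == d3
  proximal <- if (d5 <= d3) "5prime" else "3prime"
  structure(list(erv_id = erv$erv_id, gene_id = gene$gene_id,
                 proximal_ltr = proximal,
                 distance_to_tss = min(d5, d3),
                 promoter_is_cgi = isTRUE(gene$promoter_is_cgi), tie = tie),
            class = "ltr_orientation_call")
}

#' Orientation calls for all full-length ERVs near genes
#'
#' Pairs every full-length ERV with the gene whose TSS is nearest (within
#' `max_dist`) and records the proximal LTR.
#'
#' @param ervs an [erv_table()].
#' @param genes a [gene_table()] (run [classify_cgi_promoter()] first to
#'   populate CGI flags).
#' @param max_dist analysis window around the TSS.
#' @return data.frame, one row per call.
#' @export
ltr_orientation_calls <- function(ervs, genes, max_dist = 10000) {
  fl <- ervs[ervs$element_type == "full_length", , drop = FALSE]
  if (!nrow(fl)) return(data.frame())
  anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                        idx = seq_len(nrow(genes)))
  na <- nearest_anchor_interval(fl$chrom, fl$start, fl$end, anchors)
  keep <- which(!is.na(na$distance) & na$distance <= max_dist)
  rows <- lapply(keep, function(i) {
    call <- proximal_ltr(fl[i, ], genes[na$anchor[i], ])
    data.frame(erv_id = call$erv_id, gene_id = call$gene_id,
               family = fl$family[i], proximal_ltr = call$proximal_ltr,
               distance_to_tss = call$distance_to_tss,
               promoter_is_cgi = call$promoter_is_cgi, tie = call$tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Orientation-bias and CGI-association table
#'
#' From a set of proximal-LTR calls, tabulates how many elements face the TSS
#' with their 5' versus 3' LTR and how often each class sits at a CGI
#' promoter. Tests: Yates-corrected one-proportion test of the 5'-proximal
#' fraction against 0.5 (orientation bias), and the Yates-corrected
#' two-proportion test of CGI association between the two classes.
#'
#' @param calls data.frame from [ltr_orientation_calls()] (needs
#'   `proximal_ltr` and `promoter_is_cgi`).
#' @return list with `counts` (data.frame, one row per LTR class) and the two
#'   [test_result()]s (`orientation_test`, `cgi_association_test`).
#' @export
orientation_cgi_table <- function(calls) {
  if (!nrow(calls)) stop("no orientation calls supplied")
  is5 <- calls$proximal_ltr == "5prime"
  n5 <- sum(is5); n3 <- sum(!is5); n <- n5 + n3
  cgi5 <- sum(calls$promoter_is_cgi[is5])
  cgi3 <- sum(calls$promoter_is_cgi[!is5])
  counts <- data.frame(
    ltr = c("5prime", "3prime"), n = c(n5, n3), cgi = c(cgi5, cgi3),
    pct_cgi = 100 * c(cgi5, cgi3) / pmax(c(n5, n3), 1),
    stringsAsFactors = FALSE
  )
  orientation <- one_proportion_test(n5, n, 0.5, continuity = TRUE)
  association <- if (n5 == 0 || n3 == 0) {
    test_result(NA_real_, NA_real_, "two-proportion (degenerate: one class empty)",
                degenerate = TRUE)
  } else {
    two_proportion_test(cgi5, n5, cgi3, n3, continuity = TRUE)
  }
  list(counts = counts, orientation_test = orientation,
       cgi_association_test = association)
}

#' Differential methylation between the two LTRs of an element
#'
#' Mann-Whitney U test on per-clone methylated-CpG fractions of the 5' versus
#' 3' LTR clone sets (post-QC).
#'
#' @param ltr5_clones,ltr3_clones [bisulfite_clone_set()]s.
#' @param method passed to [mann_whitney()].
#' @return a [test_result()].
#' @export
compare_ltr_methylation <- function(ltr5_clones, ltr3_clones,
                                    method = "auto") {
  frac <- function(set) {
    if (!length(set$clones)) stop("empty clone set for region ",
                                  set$region_id)
    vapply(set$clones, function(cl) mean(cl$cpg), numeric(1))
  }
  mann_whitney(frac(ltr5_clones), frac(ltr3_clones), method = method)
}

#' Assess methylation spreading from an ERV into a gene promoter
#'
#' Spreading is called when the ERV is methylated and the promoter's
#' methylated-CpG fraction reaches `threshold` (default 0.10; the
#' spreading-negative promoters in the source material sit at 0-1.4%).
#'
#' @param erv_call a `methylation_call` for the ERV.
#' @param promoter_set a [bisulfite_clone_set()] for the gene promoter (same
#'   tissue).
#' @param distance_to_tss bases between the ERV edge and the TSS.
#' @param cgi is the promoter a CGI promoter?
#' @param threshold promoter-fraction cutoff for the spreading call.
#' @return list of class `spreading_assessment`.
#' @export
assess_spreading <- function(erv_call, promoter_set, distance_to_tss, cgi,
                             threshold = 0.10) {
  if (!identical(erv_call$tissue, promoter_set$tissue)) {
    stop("tissue mismatch: ERV call in ", erv_call$tissue,
         ", promoter clones in ", promoter_set$tissue)
  }
  prom <- methylation_fraction(promoter_set)
  erv_methylated <- erv_call$call == "methylated"
  structure(list(
    erv_id = erv_call$region_id, gene_id = promoter_set$region_id,
    erv_methylation = erv_call$score, promoter_methylation = prom$fraction,
    distance_to_tss = distance_to_tss, cgi = cgi, tissue = erv_call$tissue,
    spreading_call = erv_methylated && prom$fraction >= threshold
  ), class = "spreading_assessment")
}

#' Filter ERV copies by the study-design evidence rules
#'
#' A copy passes when expression/EST evidence exists for the nearby gene, the
#' gene is well annotated, the gene's TSS count does not exceed `max_tss`
#' (default 3 — the "too many TSSs" rule made explicit), and the copy is not
#' inserted inside an upstream gene (exonic or intronic).
#'
#' @param ervs an [erv_table()].
#' @param evidence data.frame keyed by `erv_id` with logical
#'   `est_available`, `expression_available`, `annotation_ok`,
#'   `inside_upstream_gene` and integer `tss_count`.
#' @param max_tss maximum tolerated TSS count.
#' @return data.frame report: `erv_id`, `passed`, `reasons`
#'   (comma-separated), one row per copy.
#' @export
filter_copies <- function(ervs, evidence, max_tss = 3) {
  need <- c("erv_id", "est_available", "expression_available",
            "annotation_ok", "tss_count", "inside_upstream_gene")
  missing <- setdiff(need, names(evidence))
  if (length(missing)) {
    stop("evidence table missing column(s): ", paste(missing, collapse = ", "))
  }
  i <- match(ervs$erv_id, evidence$erv_id)
  if (any(is.na(i))) {
    stop("no evidence row for copy(ies): ",
         paste(ervs$erv_id[is.na(i)], collapse = ", "))
  }
  ev <- evidence[i, , drop = FALSE]
  reasons <- mapply(function(est, expr, ok, tssn, inup) {
    r <- character(0)
    if (!est || !expr) r <- c(r, "no_est_or_expression_data")
    if (!ok) r <- c(r, "gene_misannotated")
    if (tssn > max_tss) r <- c(r, "too_many_tss")
    if (inup) r <- c(r, "inside_upstream_gene")
    paste(r, collapse = ",")
  }, ev$est_available, ev$expression_available, ev$annotation_ok,
     ev$tss_count, ev$inside_upstream_gene)
  data.frame(erv_id = ervs$erv_id, passed = reasons == "",
             reasons = unname(reasons), stringsAsFactors = FALSE)
}
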