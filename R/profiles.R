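# Chromatin profiles over ERV-gene intervening regions: region extraction,
# exact overlap-weighted resampling of bedGraph signal onto a common axis
# with fixed flanks, orientation normalization (TE left, TSS right) and
# cross-region averaging; plus the ChIP-qPCR enrichment formula.

#' Intervening region between an ERV and a gene
#'
#' The sequence between the gene-proximal edge of the ERV span and the gene
#' TSS. Orientation records which side the TE is on in genomic coordinates
#' (`te_left`: TE edge < TSS). An ERV overlapping the TSS yields a
#' zero-length region with a flag.
#'
#' @param erv one-row [erv_table()] slice.
#' @param gene one-row [gene_table()] slice.
#' @return list of class `intervening_region`: `erv_id`, `gene_id`, `chrom`,
#'   `te_edge`, `tss`, `length`, `orientation`, `flag`.
#' @export
intervening_region <- function(erv, gene) {
  if (erv$chrom != gene$chrom) stop("erv and gene on different chromosomes")
  tss <- gene$tss
  if (tss >= erv$start && tss <= erv$end) {
    te_edge <- tss
    orientation <- "te_left"
    flag <- "erv_overlaps_tss"
  } else if (tss > erv$end) {
    te_edge <- erv$end
    orientation <- "te_left"
    flag <- NA_character_
  } else {
    te_edge <- erv$start
    orientation <- "te_right"
    flag <- NA_character_
  }
  structure(list(erv_id = erv$erv_id, gene_id = gene$gene_id,
                 chrom = erv$chrom, te_edge = te_edge, tss = tss,
                 length = abs(tss - te_edge), orientation = orientation,
                 flag = flag),
            class = "intervening_region")
}

# cumulative signal integral of a per-chromosome track slice at positions x
# (gaps contribute 0); d must be sorted by start with disjoint intervals
track_integral <- function(d, x) {
  if (!nrow(d)) return(rep(0, length(x)))
  seg <- d$value * (d$end - d$start)
  cum <- cumsum(seg)
  i <- findInterval(x, d$start)
  out <- rep(0, length(x))
  pos <- i >= 1
  out[pos] <- cum[i[pos]] -
    d$value[i[pos]] * pmax(0, d$end[i[pos]] - x[pos])
  out
}

#' Extract a signal profile row for one intervening region
#'
#' Metagene-style resampling onto a common axis: the fixed-length flanks get
#' a fixed share of the points (`flank_points` per side, default a quarter of
#' `n_points` each) and the variable-length body (TE edge to TSS) is scaled
#' into the remaining points, so one column means the same thing across
#' regions with different TE-TSS distances. Each point is the
#' overlap-weighted mean of the covering bedGraph intervals within its window
#' (gaps read 0), so a constant track yields an exactly constant row. The row
#' is returned in genomic left-to-right order with the region's orientation
#' attached; [orient_and_average()] performs the TE-left normalization. A
#' flank running past the chromosome start is truncated with a flag; a
#' zero-length body contributes point samples at the shared edge.
#'
#' @param region an [intervening_region()].
#' @param track a [signal_track()].
#' @param flank flank length in bases (default 400; the 200 bp fallback for
#'   short regions is chosen via [common_flank()]); 0 drops the flanks.
#' @param n_points total number of points.
#' @param flank_points points allocated to each flank.
#' @return numeric row with attributes `orientation`, `lo`, `hi`, `flag`.
#' @export
extract_profile <- function(region, track, flank = 400, n_points = 100,
                            flank_points = if (flank > 0)
                              max(1L, round(n_points / 4)) else 0L) {
  body_lo <- min(region$te_edge, region$tss)
  body_hi <- max(region$te_edge, region$tss)
  n_body <- n_points - 2L * flank_points
  if (n_body < 1) stop("n_points too small for the flank allocation")
  lo <- body_lo - flank
  flag <- NA_character_
  if (lo < 0) {
    lo <- 0
    flag <- "flank_truncated"
  }
  d <- track[track$chrom == region$chrom, , drop = FALSE]
  win_means <- function(a, b, k) {
    if (k < 1) return(numeric(0))
    if (b <= a) {
      # degenerate segment: per-base value at the point
      v <- track_integral(d, a + 1) - track_integral(d, a)
      return(rep(v, k))
    }
    breaks <- seq(a, b, length.out = k + 1)
    diff(track_integral(d, breaks)) / diff(breaks)
  }
  row <- c(win_means(lo, body_lo, flank_points),
           win_means(body_lo, body_hi, n_body),
           win_means(body_hi, body_hi + flank, flank_points))
  attributes(row) <- list(orientation = region$orientation, lo = lo,
                          hi = body_hi + flank, flag = flag)
  row
}

#' Pick the largest common flank for a region set
#'
#' Returns the first candidate flank (default 400 then 200 bp) that fits all
#' regions inside their chromosome bounds; falls back to the largest flank
#' that fits everywhere.
#'
#' @param regions list of [intervening_region()]s.
#' @param genome a [genome_model()].
#' @param candidates flank lengths to try, largest first.
#' @return flank length in bases.
#' @export
common_flank <- function(regions, genome, candidates = c(400, 200)) {
  avail <- vapply(regions, function(r) {
    L <- genome$length[genome$chrom == r$chrom]
    min(min(r$te_edge, r$tss), L - max(r$te_edge, r$tss))
  }, numeric(1))
  fit <- candidates[candidates <= min(avail)]
  if (length(fit)) fit[1] else max(0, floor(min(avail)))
}

#' Orientation-normalize and average profile rows
#'
#' Rows whose region had orientation `te_right` are reversed so the TE end is
#' always the left end of the axis; the pointwise mean and standard deviation
#' across regions are computed. Flipping is an involution: a row plus its
#' mirrored duplicate (opposite orientation) average back to the original
#' row exactly.
#'
#' @param rows list of rows from [extract_profile()] (or a plain list of
#'   numeric vectors with `orientations` supplied).
#' @param orientations optional character vector overriding row attributes.
#' @param mark track label carried into the result.
#' @return list of class `profile_matrix`: `mat` (regions x points, TE side
#'   left), `mean`, `sd`, `mark`, `n`.
#' @export
orient_and_average <- function(rows, orientations = NULL, mark = "signal") {
  if (!length(rows)) stop("no profile rows supplied")
  if (is.null(orientations)) {
    orientations <- vapply(rows, function(r) {
      o <- attr(r, "orientation")
      if (is.null(o)) "te_left" else o
    }, character(1))
  }
  len <- unique(vapply(rows, length, integer(1)))
  if (length(len) != 1) stop("profile rows have differing lengths")
  mat <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- as.numeric(rows[[i]])
    if (orientations[i] == "te_right") rev(r) else r
  }))
  structure(list(mat = mat, mean = colMeans(mat),
                 sd = apply(mat, 2, stats::sd), mark = mark, n = nrow(mat)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s: %d regions x %d points (TE left, TSS right)\n",
              x$mark, nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Average profiles over a set of ERV-gene pairs
#'
#' Convenience driver: builds intervening regions, extracts one row per
#' region from each track and returns oriented profile matrices, reported
#' raw and (when an input track is given) as mark - input difference.
#'
#' @param pairs data.frame with columns `erv_id`, `gene_id`.
#' @param ervs,genes feature tables.
#' @param tracks named list of [signal_track()]s.
#' @param genome a [genome_model()] (for flank fitting).
#' @param flank flank length, or `NULL` to use [common_flank()].
#' @param n_points resolution.
#' @param input_track name of the input track for the difference profiles
#'   (`NULL` to skip).
#' @return named list of `profile_matrix` objects (`<mark>` and
#'   `<mark>_minus_input`).
#' @export
average_profiles <- function(pairs, ervs, genes, tracks, genome,
                             flank = NULL, n_points = 100,
                             input_track = "Input") {
  regions <- lapply(seq_len(nrow(pairs)), function(i) {
    intervening_region(ervs[ervs$erv_id == pairs$erv_id[i], ],
                       genes[genes$gene_id == pairs$gene_id[i], ])
  })
  if (is.null(flank)) flank <- common_flank(regions, genome)
  out <- list()
  rows_by_mark <- lapply(tracks, function(tr) {
    lapply(regions, extract_profile, track = tr, flank = flank,
           n_points = n_points)
  })
  for (mark in names(tracks)) {
    out[[mark]] <- orient_and_average(rows_by_mark[[mark]], mark = mark)
  }
  if (!is.null(input_track) && input_track %in% names(tracks)) {
    for (mark in setdiff(names(tracks), input_track)) {
      diff_mat <- out[[mark]]$mat - out[[input_track]]$mat
      out[[paste0(mark, "_minus_input")]] <- structure(
        list(mat = diff_mat, mean = colMeans(diff_mat),
             sd = apply(diff_mat, 2, stats::sd),
             mark = paste0(mark, "_minus_input"), n = nrow(diff_mat)),
        class = "profile_matrix")
    }
  }
  attr(out, "flank") <- flank
  out
}

#' ChIP-qPCR enrichment
#'
#' `efficiency ^ (Ct_input - Ct_IP)`, with no spike normalization (unlike
#' MeDIP scores).
#'
#' @param ct_input,ct_ip cycle thresholds.
#' @param efficiency primer amplification factor (> 1; typically 1.9-2).
#' @return enrichment ratio (vectorized).
#' @export
chip_enrichment <- function(ct_input, ct_ip, efficiency = 2) {
  if (any(!is.finite(c(ct_input, ct_ip)))) stop("non-finite Ct value")
  if (any(efficiency <= 1)) stop("efficiency must exceed 1")
  efficiency^(ct_input - ct_ip)
}
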