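# Distance-distribution machinery: random-insertion expected distribution,
# observed edge distances, per-bin proportion tests, and detection of the
# depletion threshold as the lower bound of the first non-significant bin.

#' Simulate the expected distance distribution under random insertion
#'
#' Draws `n` uniform insertion points per replicate (chromosome chosen
#' proportional to length), computes the distance of each point to the
#' nearest anchor (TSS or TTS), bins the distances and averages counts over
#' replicates. The study-scale defaults are one million insertions averaged
#' over three replicates.
#'
#' @param genome a [genome_model()].
#' @param genes a [gene_table()].
#' @param anchor `"tss"` or `"tts"`.
#' @param n insertions per replicate.
#' @param reps replicates averaged.
#' @param seed RNG seed.
#' @param bin_width,max_dist binning (defaults 500 bp up to 10 kb).
#' @return list with `counts` (average per-bin counts), `breaks`, `n_total`
#'   (insertions per replicate; denominator for proportions).
#' @export
simulate_expected <- function(genome, genes, anchor = c("tss", "tts"),
                              n = 1e6, reps = 3, seed = 1,
                              bin_width = 500, max_dist = 10000) {
  anchor <- match.arg(anchor)
  stopifnot(n >= 1, reps >= 1)
  if (!nrow(genes)) stop("empty gene set")
  anchors <- data.frame(chrom = genes$chrom,
                        pos = if (anchor == "tss") genes$tss else genes$tts)
  breaks <- seq(0, max_dist, by = bin_width)
  withr::with_seed(seed, {
    counts <- matrix(0, nrow = reps, ncol = length(breaks) - 1)
    for (r in seq_len(reps)) {
      ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
      pos <- floor(runif(n) * genome$length[ci])
      d <- nearest_anchor_point(genome$chrom[ci], pos, anchors)
      d <- d[!is.na(d)]
      counts[r, ] <- tabulate(findInterval(d[d < max_dist], breaks),
                              nbins = length(breaks) - 1)
    }
    list(counts = colMeans(counts), breaks = breaks, n_total = n)
  })
}

#' Distances of random insertion points to the nearest anchor
#'
#' Draws `n` uniform insertion points (chromosome proportional to length) and
#' returns their distances to the nearest anchor — the raw material of the
#' random-insertion null, also useful for calibration experiments where an
#' "observed" sample under no selection is needed.
#'
#' @inheritParams simulate_expected
#' @return numeric vector of distances (length `n`).
#' @export
sample_null_distances <- function(genome, genes, anchor = c("tss", "tts"),
                                  n = 1e4, seed = 1) {
  anchor <- match.arg(anchor)
  if (!nrow(genes)) stop("empty gene set")
  anchors <- data.frame(chrom = genes$chrom,
                        pos = if (anchor == "tss") genes$tss else genes$tts)
  withr::with_seed(seed, {
    ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
    pos <- floor(runif(n) * genome$length[ci])
    nearest_anchor_point(genome$chrom[ci], pos, anchors)
  })
}

#' Observed ERV distances to the nearest gene anchor
#'
#' Unsigned edge distance from each ERV span to the nearest TSS (or TTS) over
#' all genes, with a position class from the ERV midpoint relative to the
#' nearest-anchor gene: `inside` the gene body, otherwise `upstream` or
#' `downstream` of it in the gene's reading direction. Equidistant anchors
#' break the tie to the lower genomic coordinate. ERVs on chromosomes with no
#' genes are excluded with a warning.
#'
#' @param ervs an [erv_table()].
#' @param genes a [gene_table()].
#' @param anchor `"tss"` or `"tts"`.
#' @return data.frame `erv_id`, `family`, `gene_id`, `distance`,
#'   `position_class`.
#' @export
observed_distances <- function(ervs, genes, anchor = c("tss", "tts")) {
  anchor <- match.arg(anchor)
  anchors <- data.frame(chrom = genes$chrom,
                        pos = if (anchor == "tss") genes$tss else genes$tts,
                        idx = seq_len(nrow(genes)))
  na <- nearest_anchor_interval(ervs$chrom, ervs$start, ervs$end, anchors)
  drop <- is.na(na$distance)
  if (any(drop)) {
    warning(sum(drop), " ERV(s) on chromosomes without genes excluded")
  }
  keep <- which(!drop)
  g <- genes[na$anchor[keep], , drop = FALSE]
  mid <- (ervs$start[keep] + ervs$end[keep]) / 2
  body_lo <- pmin(g$tss, g$tts)
  body_hi <- pmax(g$tss, g$tts)
  pos_class <- ifelse(mid >= body_lo & mid < body_hi, "inside",
               ifelse(xor(mid < body_lo, g$strand == "-"),
                      "upstream", "downstream"))
  data.frame(erv_id = ervs$erv_id[keep], family = ervs$family[keep],
             gene_id = g$gene_id, distance = na$distance[keep],
             position_class = pos_class, stringsAsFactors = FALSE)
}

#' Per-bin observed-vs-expected proportion tests
#'
#' Bins observed distances with the expected distribution's binning and runs
#' the Yates-corrected two-proportion test per bin: observed count out of all
#' observed copies against the rounded average expected count out of the
#' expected total. Copies beyond the binning window stay in the denominators.
#'
#' @param observed data.frame from [observed_distances()] (or any frame with
#'   a `distance` column).
#' @param expected list from [simulate_expected()].
#' @param anchor,family labels carried into the result.
#' @param bh also report Benjamini-Hochberg adjusted p-values? (the original
#'   analysis applied none; default off)
#' @return a `distance_distribution` object; its `bins` element holds one row
#'   per bin (`lo`, `hi`, `observed`, `expected`, `chi2`, `p`, `stars`).
#' @export
per_bin_tests <- function(observed, expected, anchor = "tss", family = "all",
                          bh = FALSE) {
  breaks <- expected$breaks
  n_obs <- nrow(observed)
  obs_counts <- tabulate(findInterval(
    observed$distance[observed$distance < max(breaks)], breaks),
    nbins = length(breaks) - 1)
  exp_counts <- round(expected$counts)
  tests <- lapply(seq_along(obs_counts), function(i) {
    two_proportion_test(obs_counts[i], n_obs, exp_counts[i],
                        round(expected$n_total), continuity = TRUE)
  })
  bins <- data.frame(
    lo = breaks[-length(breaks)], hi = breaks[-1],
    observed = obs_counts, expected = expected$counts,
    chi2 = vapply(tests, function(t) t$statistic, numeric(1)),
    p = vapply(tests, function(t) t$p_value, numeric(1)),
    stars = vapply(tests, function(t) t$stars, character(1)),
    degenerate = vapply(tests, function(t) isTRUE(t$degenerate), logical(1)),
    stringsAsFactors = FALSE
  )
  if (bh) bins$p_bh <- stats::p.adjust(bins$p, method = "BH")
  dist <- list(anchor = anchor, family = family,
               bin_width = breaks[2] - breaks[1], bins = bins,
               n_observed = n_obs, n_expected_total = expected$n_total,
               threshold = NA_real_, threshold_flag = NA_character_)
  class(dist) <- "distance_distribution"
  dist$threshold <- detect_threshold(dist)
  dist$threshold_flag <- attr(dist$threshold, "flag")
  dist
}

#' Detect the depletion threshold
#'
#' The selection-zone boundary is read off as the lower bound of the first
#' (smallest-distance) bin whose observed-vs-expected test is not significant
#' at `alpha`. If the very first bin is already non-significant the threshold
#' is 0 and flagged `no_depletion`; if every bin is significant the threshold
#' is the window maximum, flagged `all_significant`. A non-monotone
#' significance pattern (significant bins beyond the threshold) is flagged
#' `non_monotone`.
#'
#' @param dist a `distance_distribution` from [per_bin_tests()].
#' @param alpha significance level (default 0.05, the lowest star level).
#' @return threshold in bases, with a `flag` attribute.
#' @export
detect_threshold <- function(dist, alpha = 0.05) {
  bins <- dist$bins
  sig <- !is.na(bins$p) & bins$p < alpha
  first_ns <- which(!sig)[1]
  if (is.na(first_ns)) {
    return(structure(max(bins$hi), flag = "all_significant"))
  }
  flag <- if (first_ns == 1) "no_depletion"
          else if (any(sig[first_ns:length(sig)])) "non_monotone"
          else NA_character_
  structure(bins$lo[first_ns], flag = flag)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %s / %s: %d bins of %g bp, n_obs = %d, threshold = %g%s\n",
              x$family, x$anchor, nrow(x$bins), x$bin_width, x$n_observed,
              x$threshold,
              if (!is.na(x$threshold_flag)) paste0(" [", x$threshold_flag, "]")
              else ""))
  invisible(x)
}

#' Serialize a distance distribution to TSV
#'
#' One bin per row (`lo`, `hi`, `observed`, `expected`, `chi2`, `p`, `stars`)
#' plus a trailing comment line carrying the detected threshold.
#'
#' @param dist a `distance_distribution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  write.table(dist$bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("# threshold\t%g\t%s\n", dist$threshold,
              ifelse(is.na(dist$threshold_flag), "", dist$threshold_flag)),
      file = path, append = TRUE)
  invisible(path)
}
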