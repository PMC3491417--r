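# Methylation quantification: MeDIP-qPCR enrichment scores with spike-in
# normalization and the 0.2 unmethylated threshold; bisulfite clone QC
# (conversion-rate filter, PCR-duplicate removal) and methylated-CpG
# fractions; cross-method concordance.

#' MeDIP-qPCR methylation score for one region
#'
#' Raw enrichment is `efficiency ^ (Ct_input - Ct_IP)`; the score divides the
#' region's raw enrichment by the spike-in's (in-vitro methylated positive
#' control from the same batch). Scores below `threshold` (default 0.2) are
#' called unmethylated.
#'
#' @param m one measurement: list/row with `region_id`, `tissue`, `ct_input`,
#'   `ct_ip`, `efficiency`, `batch_id`.
#' @param spike the batch's spike-in measurement(s); several spikes are
#'   combined by averaging their raw enrichments (`spike_combine = "mean"`)
#'   or the first is used (`"first"`).
#' @param threshold unmethylated cutoff on the normalized score.
#' @param spike_combine how to combine multiple spike fragments.
#' @return list of class `methylation_call`: `region_id`, `tissue`, `score`,
#'   `call` (`"methylated"`/`"unmethylated"`), `method = "medip"`.
#' @export
medip_score <- function(m, spike, threshold = 0.2,
                        spike_combine = c("mean", "first")) {
  spike_combine <- match.arg(spike_combine)
  spike <- if (is.data.frame(spike)) split(spike, seq_len(nrow(spike)))
           else if (!is.null(spike$ct_input)) list(spike)
           else as.list(spike)
  if (!length(spike)) stop("missing spike-in measurement for batch ", m$batch_id)
  check_ct <- function(x) {
    if (any(!is.finite(c(x$ct_input, x$ct_ip))) ||
        any(c(x$ct_input, x$ct_ip) < 0)) {
      stop("invalid Ct value for region ", x$region_id)
    }
    if (x$efficiency <= 1) stop("primer efficiency must exceed 1")
  }
  check_ct(m)
  lapply(spike, check_ct)
  bad_batch <- vapply(spike, function(s) !identical(s$batch_id, m$batch_id),
                      logical(1))
  if (any(bad_batch)) stop("spike-in from a different batch than region ",
                           m$region_id)
  raw <- m$efficiency^(m$ct_input - m$ct_ip)
  raw_spike <- vapply(spike, function(s) s$efficiency^(s$ct_input - s$ct_ip),
                      numeric(1))
  raw_spike <- if (spike_combine == "mean") mean(raw_spike)
               else unname(raw_spike[1])
  score <- raw / raw_spike
  structure(list(region_id = m$region_id, tissue = m$tissue, score = score,
                 fraction = NA_real_,
                 call = if (score < threshold) "unmethylated" else "methylated",
                 method = "medip"),
            class = "methylation_call")
}

#' Score a full MeDIP Ct table
#'
#' Applies [medip_score()] to every non-spike row, resolving each row's
#' spike-in within its batch.
#'
#' @param ct data.frame as produced by [simulate_ct_table()] (columns
#'   `region_id`, `tissue`, `ct_input`, `ct_ip`, `efficiency`, `batch_id`,
#'   `is_spike`).
#' @inheritParams medip_score
#' @return data.frame of calls: `region_id`, `tissue`, `method`, `score`,
#'   `call`.
#' @export
medip_call_table <- function(ct, threshold = 0.2,
                             spike_combine = c("mean", "first")) {
  spike_combine <- match.arg(spike_combine)
  calls <- lapply(which(!ct$is_spike), function(i) {
    spikes <- ct[ct$is_spike & ct$batch_id == ct$batch_id[i], , drop = FALSE]
    medip_score(ct[i, ], spikes, threshold, spike_combine)
  })
  data.frame(
    region_id = vapply(calls, `[[`, character(1), "region_id"),
    tissue = vapply(calls, `[[`, character(1), "tissue"),
    method = "medip",
    score = vapply(calls, `[[`, numeric(1), "score"),
    call = vapply(calls, `[[`, character(1), "call"),
    stringsAsFactors = FALSE
  )
}

#' Bisulfite conversion rate of a clone
#'
#' Fraction of non-CpG cytosines that converted (read T). A clone passes QC
#' only with a rate strictly greater than `min_rate` (default 0.95; a clone
#' at exactly 95% fails). Clones with no assayable non-CpG cytosine are
#' flagged indeterminate, never silently passed.
#'
#' @param clone one clone (list with `nonconv`, `n_noncpg_c`).
#' @return conversion rate in `[0,1]`, or `NA` when indeterminate.
#' @export
conversion_rate <- function(clone) {
  if (is.null(clone$n_noncpg_c) || clone$n_noncpg_c < 1) return(NA_real_)
  1 - length(clone$nonconv) / clone$n_noncpg_c
}

#' @rdname conversion_rate
#' @param min_rate strict lower bound on the conversion rate.
#' @return `passes_conversion`: `TRUE`/`FALSE`, `NA` when indeterminate.
#' @export
passes_conversion <- function(clone, min_rate = 0.95) {
  r <- conversion_rate(clone)
  if (is.na(r)) NA else r > min_rate
}

#' Apply the conversion-rate filter to a clone set
#'
#' Removes clones failing [passes_conversion()]; indeterminate clones (no
#' non-CpG cytosines) are removed and reported via the `indeterminate`
#' attribute.
#'
#' @param set a [bisulfite_clone_set()].
#' @param min_rate strict conversion-rate bound.
#' @return filtered [bisulfite_clone_set()].
#' @export
filter_conversion <- function(set, min_rate = 0.95) {
  pass <- vapply(set$clones, passes_conversion, logical(1), min_rate = min_rate)
  out <- bisulfite_clone_set(set$region_id, set$tissue,
                             set$clones[which(pass %in% TRUE)])
  attr(out, "indeterminate") <- sum(is.na(pass))
  out
}

#' Remove PCR-duplicate clones
#'
#' A clone is retained if its CpG methylation pattern is unique among the
#' set, or its set of conversion-error positions is unique (a clone unique in
#' either respect cannot be a PCR copy of another template). Clones identical
#' in both respects collapse to one representative, the first in input order.
#'
#' @param set a [bisulfite_clone_set()] (conversion filter already applied).
#' @return deduplicated [bisulfite_clone_set()].
#' @export
dedup_clones <- function(set) {
  if (!length(set$clones)) return(set)
  pat <- vapply(set$clones, function(cl) paste(as.integer(cl$cpg),
                                               collapse = ""), character(1))
  err <- vapply(set$clones, function(cl) paste(sort(cl$nonconv),
                                               collapse = ","), character(1))
  pat_unique <- !(pat %in% pat[duplicated(pat)])
  err_unique <- !(err %in% err[duplicated(err)])
  both <- paste(pat, err, sep = "|")
  first_of_kind <- !duplicated(both)
  keep <- pat_unique | err_unique | first_of_kind
  bisulfite_clone_set(set$region_id, set$tissue, set$clones[keep])
}

#' Methylated-CpG fraction of a clone set
#'
#' Fraction of methylated CpG calls over all retained clones; called
#' methylated/unmethylated against the same 0.2 threshold used for MeDIP
#' scores (a reconstruction — the threshold is configurable).
#'
#' @param set a [bisulfite_clone_set()] with at least one clone.
#' @param threshold unmethylated cutoff on the fraction.
#' @return a `methylation_call` with `fraction` set and
#'   `method = "bisulfite"`.
#' @export
methylation_fraction <- function(set, threshold = 0.2) {
  if (!length(set$clones)) stop("no clones in region ", set$region_id)
  calls <- unlist(lapply(set$clones, `[[`, "cpg"))
  frac <- mean(calls)
  structure(list(region_id = set$region_id, tissue = set$tissue,
                 score = frac, fraction = frac,
                 call = if (frac < threshold) "unmethylated" else "methylated",
                 method = "bisulfite", n_clones = length(set$clones)),
            class = "methylation_call")
}

#' @export
print.methylation_call <- function(x, ...) {
  cat(sprintf("<methylation_call> %s/%s [%s]: %.3f -> %s\n", x$region_id,
              x$tissue, x$method, x$score, x$call))
  invisible(x)
}

#' MeDIP vs bisulfite concordance
#'
#' Spearman correlation between MeDIP scores and bisulfite methylated-CpG
#' fractions over shared (region, tissue) pairs.
#'
#' @param calls_medip,calls_bisulfite data.frames with `region_id`, `tissue`
#'   and `score` (MeDIP) / `fraction` or `score` (bisulfite).
#' @return a [test_result()] (statistic = Spearman r).
#' @export
medip_bisulfite_concordance <- function(calls_medip, calls_bisulfite) {
  bs_val <- if ("fraction" %in% names(calls_bisulfite))
    calls_bisulfite$fraction else calls_bisulfite$score
  key_m <- paste(calls_medip$region_id, calls_medip$tissue)
  key_b <- paste(calls_bisulfite$region_id, calls_bisulfite$tissue)
  shared <- intersect(key_m, key_b)
  if (length(shared) < 3) stop("need at least 3 shared (region, tissue) pairs")
  spearman_test(calls_medip$score[match(shared, key_m)],
                bs_val[match(shared, key_b)])
}

#' Derive bisulfite clone calls from reads against a reference
#'
#' Reads must align ungapped (same length as the reference). Reference CpG
#' cytosines read `C` are methylated, `T` unmethylated; non-CpG cytosines
#' read `C` are conversion failures, `T` converted. Other bases at scored
#' positions are skipped with a warning.
#'
#' @param reference reference sequence (character scalar).
#' @param reads character vector of clone reads (names become clone ids).
#' @param region_id,tissue labels for the resulting set.
#' @return a [bisulfite_clone_set()].
#' @export
bisulfite_from_reads <- function(reference, reads, region_id = "region",
                                 tissue = "unknown") {
  ref_chars <- strsplit(toupper(reference), "")[[1]]
  cpg_pos <- gregexpr("CG", toupper(reference))[[1]]
  if (identical(as.integer(cpg_pos), -1L)) cpg_pos <- integer(0)
  noncpg_pos <- setdiff(which(ref_chars == "C"), cpg_pos)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("%s_clone%02d", region_id, seq_along(reads))
  clones <- lapply(seq_along(reads), function(i) {
    rc <- strsplit(toupper(reads[[i]]), "")[[1]]
    if (length(rc) != length(ref_chars)) {
      stop("read ", ids[i], " length differs from reference")
    }
    cpg_base <- rc[cpg_pos]
    bad <- !(cpg_base %in% c("C", "T"))
    if (any(bad)) {
      warning("ambiguous base at ", sum(bad), " CpG position(s) in ", ids[i],
              "; skipped")
    }
    nc_base <- rc[noncpg_pos]
    bad_nc <- !(nc_base %in% c("C", "T"))
    if (any(bad_nc)) {
      warning("ambiguous base at ", sum(bad_nc),
              " non-CpG C position(s) in ", ids[i], "; skipped")
    }
    list(clone_id = ids[i],
         cpg = (cpg_base == "C")[!bad],
         nonconv = which((nc_base == "C")[!bad_nc]),
         n_noncpg_c = sum(!bad_nc))
  })
  bisulfite_clone_set(region_id, tissue, clones)
}

#' Read a bisulfite FASTA (reference + clone reads)
#'
#' Convenience wrapper: the first record is the reference, the rest are clone
#' reads; dispatches to [bisulfite_from_reads()].
#'
#' @param path FASTA file.
#' @param region_id,tissue labels.
#' @return a [bisulfite_clone_set()].
#' @export
read_bisulfite_fasta <- function(path, region_id = "region",
                                 tissue = "unknown") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) < 2) stop("FASTA must hold a reference plus >= 1 read")
  reads <- as.character(seqs[-1])
  names(reads) <- names(seqs)[-1]
  bisulfite_from_reads(as.character(seqs[[1]]), reads, region_id, tissue)
}

#' Full bisulfite QC + quantification for one region
#'
#' Conversion filter, PCR-duplicate removal, then the methylated fraction.
#'
#' @param set a [bisulfite_clone_set()].
#' @param min_rate strict conversion bound.
#' @param threshold unmethylated cutoff.
#' @return a `methylation_call` with QC counts attached
#'   (`attr(, "qc")`: clones in, failing conversion, duplicates removed).
#' @export
bisulfite_qc <- function(set, min_rate = 0.95, threshold = 0.2) {
  n_in <- length(set$clones)
  conv <- filter_conversion(set, min_rate)
  dedup <- dedup_clones(conv)
  call <- methylation_fraction(dedup, threshold)
  attr(call, "qc") <- c(clones_in = n_in,
                        failed_conversion = n_in - length(conv$clones),
                        duplicates_removed = length(conv$clones) -
                          length(dedup$clones),
                        clones_retained = length(dedup$clones))
  call
}
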