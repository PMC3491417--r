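# End-to-end orchestration on synthetic inputs: simulate -> write -> read
# back (exercising the readers) -> distance distributions and thresholds ->
# methylation calls -> LTR/CGI association -> spreading -> profiles, with
# TSV report tables and a JSON run log carrying the config hash.

#' Pipeline run configuration
#'
#' Bundles the simulation world with every analysis threshold. All stage
#' thresholds live here; stage code contains no literals.
#'
#' @param sim a [sim_config()].
#' @param unmethylated score/fraction below which a region is unmethylated.
#' @param spreading promoter fraction at/above which spreading is called.
#' @param significance per-bin significance level for threshold detection.
#' @param conversion strict bisulfite conversion-rate bound.
#' @param cgi_window promoter half-window for CGI classification (bases).
#' @param bin_width,max_dist distance-distribution binning.
#' @param flanks candidate profile flanks, largest first.
#' @param expected_n,expected_reps random-insertion null size.
#' @param n_bisulfite_regions,n_spreading_cases,n_profile_pairs stage sizes.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), unmethylated = 0.2,
                       spreading = 0.10, significance = 0.05,
                       conversion = 0.95, cgi_window = 1500,
                       bin_width = 500, max_dist = 10000,
                       flanks = c(400, 200),
                       expected_n = 1e5, expected_reps = 3,
                       n_bisulfite_regions = 10, n_spreading_cases = 5,
                       n_profile_pairs = 8) {
  stopifnot(unmethylated > 0, unmethylated < 1, spreading > 0, spreading < 1,
            significance > 0, significance < 1, conversion > 0,
            conversion < 1, cgi_window > 0, bin_width > 0,
            max_dist > bin_width)
  structure(list(sim = sim, unmethylated = unmethylated,
                 spreading = spreading, significance = significance,
                 conversion = conversion, cgi_window = cgi_window,
                 bin_width = bin_width, max_dist = max_dist, flanks = flanks,
                 expected_n = expected_n, expected_reps = expected_reps,
                 n_bisulfite_regions = n_bisulfite_regions,
                 n_spreading_cases = n_spreading_cases,
                 n_profile_pairs = n_profile_pairs),
            class = "run_config")
}

#' Small demonstration configuration
#'
#' A scaled-down world (2 chromosomes x 200 kb, 30 genes, 150 copies per
#' family under hard exclusion within 1.5 kb of TSSs) that runs the full
#' pipeline in seconds.
#'
#' @param seed RNG seed.
#' @return a `run_config`.
#' @export
demo_config <- function(seed = 1) {
  run_config(
    sim = sim_config(
      seed = seed,
      genome = list(n_chromosomes = 2L, chrom_length = 2e5),
      genes = list(n_genes = 30L, length_range = c(1000, 3000)),
      ervs = list(n_per_family = c("ETn/MusD" = 150L, "IAP" = 150L),
                  ltr_length = 200, full_length_size = 2000,
                  full_length_fraction = 0.3),
      selection = list(type = "hard_exclusion", d_sel = 1500)
    ),
    expected_n = 2e4, expected_reps = 3
  )
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Group methylation calls by family and distance class
#'
#' Splits calls into near/far classes per family using the detected
#' depletion thresholds (near means distance strictly below the family's
#' threshold) and reports the methylated fraction per group.
#'
#' @param calls data.frame with `region_id`, `family`, `distance`, `call`.
#' @param thresholds named numeric vector of per-family distance thresholds.
#' @return data.frame: `family`, `class`, `n`, `n_methylated`,
#'   `fraction_methylated` (NA for empty groups).
#' @export
summarize_calls <- function(calls, thresholds) {
  rows <- list()
  for (fam in names(thresholds)) {
    sub <- calls[calls$family == fam, , drop = FALSE]
    near <- sub$distance < thresholds[[fam]]
    for (cls in c("near", "far")) {
      grp <- sub[if (cls == "near") near else !near, , drop = FALSE]
      nm <- sum(grp$call == "methylated")
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, class = cls, n = nrow(grp), n_methylated = nm,
        fraction_methylated = if (nrow(grp)) nm / nrow(grp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline on synthetic inputs
#'
#' Deterministic under the config seed. Writes, under `outdir`:
#' `inputs/` (every simulated input file), `distribution_<family>.tsv` with
#' detected thresholds, `methylation_calls.tsv`, `call_summary.tsv`,
#' `ltr_orientation.tsv` + `orientation_tests.tsv`, `spreading.tsv`,
#' `profile_<mark>.tsv` mean profiles, and `run_log.json` with the config
#' hash and per-stage counts.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("ervtools")),
              counts = list())
  tsv <- function(x, f) write.table(x, file.path(outdir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)

  # -- synthesize and read back through the standard formats
  sim <- stage("simulate", write_simulation(config$sim,
                                            file.path(outdir, "inputs")))
  inp <- file.path(outdir, "inputs")
  genes <- stage("read", read_features(file.path(inp, "genes.bed"), "gene"))
  cgis <- read_features(file.path(inp, "cgis.bed"), "cgi")
  ervs <- read_features(file.path(inp, "ervs.bed"), "erv")
  tracks <- list(H3K4me3 = read_bedgraph(file.path(inp, "h3k4me3.bedGraph")),
                 CTCF = read_bedgraph(file.path(inp, "ctcf.bedGraph")),
                 Input = read_bedgraph(file.path(inp, "input.bedGraph")))
  genome <- sim$world$genome
  genes <- classify_cgi_promoter(genes, cgis, window = config$cgi_window)
  log$counts$genes <- nrow(genes)
  log$counts$ervs <- nrow(ervs)

  # -- distance distributions and depletion thresholds per family
  thresholds <- c()
  dists <- list()
  distributions <- list()
  for (fam in unique(ervs$family)) {
    fam_ervs <- ervs[ervs$family == fam, , drop = FALSE]
    obs <- stage("distances", observed_distances(fam_ervs, genes, "tss"))
    expd <- stage("expected", simulate_expected(
      genome, genes, "tss", n = config$expected_n,
      reps = config$expected_reps, seed = config$sim$seed + 101,
      bin_width = config$bin_width, max_dist = config$max_dist))
    dd <- per_bin_tests(obs, expd, anchor = "tss", family = fam)
    dd$threshold <- detect_threshold(dd, alpha = config$significance)
    dd$threshold_flag <- attr(dd$threshold, "flag")
    write_distribution(dd, file.path(outdir, paste0(
      "distribution_", gsub("/", "", fam), ".tsv")))
    thresholds[fam] <- as.numeric(dd$threshold)
    dists[[fam]] <- obs
    distributions[[fam]] <- dd
  }

  # -- MeDIP methylation calls, joined to distances
  medip <- stage("medip", medip_call_table(sim$ct,
                                           threshold = config$unmethylated))
  all_d <- do.call(rbind, dists)
  medip$family <- ervs$family[match(medip$region_id, ervs$erv_id)]
  medip$distance <- all_d$distance[match(medip$region_id, all_d$erv_id)]
  tsv(medip, "methylation_calls.tsv")
  summary <- summarize_calls(
    medip[!is.na(medip$distance), c("region_id", "family", "distance", "call")],
    thresholds)
  tsv(summary, "call_summary.tsv")
  log$counts$medip_calls <- nrow(medip)

  # -- bisulfite confirmation on the copies nearest genes + concordance
  near_order <- order(medip$distance)
  pick <- medip[near_order, ][seq_len(min(config$n_bisulfite_regions,
                                          nrow(medip))), ]
  truth <- sim$truth
  bis_calls <- lapply(pick$region_id, function(id) {
    set <- simulate_bisulfite_clones(
      config$sim, id, truth$true_level[truth$erv_id == id],
      tissue = pick$tissue[pick$region_id == id][1])
    bisulfite_qc(set, min_rate = config$conversion,
                 threshold = config$unmethylated)
  })
  bis <- data.frame(
    region_id = vapply(bis_calls, `[[`, character(1), "region_id"),
    tissue = vapply(bis_calls, `[[`, character(1), "tissue"),
    method = "bisulfite",
    fraction = vapply(bis_calls, `[[`, numeric(1), "fraction"),
    call = vapply(bis_calls, `[[`, character(1), "call"),
    n_clones = vapply(bis_calls, `[[`, numeric(1), "n_clones"),
    stringsAsFactors = FALSE)
  tsv(bis, "bisulfite_calls.tsv")
  concord <- stage("concordance", medip_bisulfite_concordance(
    medip[medip$region_id %in% bis$region_id, ], bis))

  # -- LTR orientation and CGI association
  calls <- stage("orientation", ltr_orientation_calls(ervs, genes,
                                                      max_dist = config$max_dist))
  if (!is.null(calls) && nrow(calls)) {
    tab <- orientation_cgi_table(calls)
    tsv(calls, "ltr_orientation.tsv")
    tsv(cbind(tests_to_table(orientation_bias = tab$orientation_test,
                             cgi_association = tab$cgi_association_test)),
        "orientation_tests.tsv")
    log$counts$orientation_calls <- nrow(calls)
  } else {
    tab <- NULL
  }

  # -- spreading assessment for methylated near-gene copies
  meth_near <- medip[medip$call == "methylated" & !is.na(medip$distance) &
                     medip$distance > 0 & medip$distance <= config$max_dist, ]
  meth_near <- utils::head(meth_near[order(meth_near$distance), ],
                           config$n_spreading_cases)
  spread_rows <- lapply(seq_len(nrow(meth_near)), function(i) {
    id <- meth_near$region_id[i]
    gene_id <- all_d$gene_id[all_d$erv_id == id][1]
    prom_set <- simulate_bisulfite_clones(config$sim,
                                          paste0(gene_id, "_prom"), 0.02,
                                          tissue = meth_near$tissue[i])
    prom_set$region_id <- gene_id
    call <- medip_score_from_row(meth_near[i, ])
    a <- assess_spreading(call, prom_set, meth_near$distance[i],
                          isTRUE(genes$promoter_is_cgi[genes$gene_id == gene_id]),
                          threshold = config$spreading)
    data.frame(erv_id = a$erv_id, gene_id = a$gene_id,
               erv_methylation = a$erv_methylation,
               promoter_methylation = a$promoter_methylation,
               distance_to_tss = a$distance_to_tss, cgi = a$cgi,
               tissue = a$tissue, spreading = a$spreading_call,
               stringsAsFactors = FALSE)
  })
  spread <- if (length(spread_rows)) do.call(rbind, spread_rows) else
    data.frame()
  tsv(spread, "spreading.tsv")

  # -- chromatin profiles over intervening regions
  prof_src <- medip[!is.na(medip$distance) & medip$distance > 0 &
                    medip$distance <= config$max_dist, ]
  prof_src <- utils::head(prof_src[order(prof_src$distance), ],
                          config$n_profile_pairs)
  profiles <- NULL
  if (nrow(prof_src) > 0) {
    pairs <- data.frame(erv_id = prof_src$region_id,
                        gene_id = all_d$gene_id[match(prof_src$region_id,
                                                      all_d$erv_id)])
    profiles <- stage("profiles", average_profiles(
      pairs, ervs, genes, tracks, genome, flank = NULL, n_points = 100))
    for (mark in names(profiles)) {
      tsv(data.frame(point = seq_along(profiles[[mark]]$mean),
                     mean = profiles[[mark]]$mean, sd = profiles[[mark]]$sd),
          paste0("profile_", mark, ".tsv"))
    }
    log$counts$profile_regions <- nrow(pairs)
  }

  log$thresholds <- as.list(thresholds)
  log$concordance <- list(spearman_r = concord$statistic,
                          p_value = concord$p_value)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(list(genome = genome, genes = genes, ervs = ervs,
                 distributions = distributions, thresholds = thresholds,
                 medip = medip, bisulfite = bis, concordance = concord,
                 orientation = tab, spreading = spread, profiles = profiles,
                 log = log))
}

# rebuild a methylation_call from a call-table row (pipeline internal)
medip_score_from_row <- function(row) {
  structure(list(region_id = row$region_id, tissue = row$tissue,
                 score = row$score, fraction = NA_real_, call = row$call,
                 method = "medip"),
            class = "methylation_call")
}
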