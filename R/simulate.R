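# Synthetic-data generators. These emulate the structure the analysis
# assumes: a multi-chromosome genome with non-overlapping genes and CGI
# promoters, ERV insertions thinned by a distance-to-TSS selection function,
# family-dependent methylation coupled to proximity, bisulfite clones with
# conversion failures and PCR duplicates, MeDIP Ct tables with log-scale
# noise, and TSS-anchored signal tracks. Every generator is deterministic
# under the config seed (each uses its own fixed offset of the seed so the
# streams are independent) and writes formats the readers in io.R consume.

#' Simulation configuration
#'
#' Returns the default simulated world, with any component overridden by
#' name (nested lists are merged). Defaults: 5 chromosomes of 2 Mb, 200
#' genes, 60% CGI promoters, 150 ERV copies per family (IAP and ETn/MusD)
#' with realistic element lengths (solo LTR 330 bp, full-length ~7 kb, 15%
#' full-length), IAP baseline methylation 0.9 and ETn/MusD 0.85 with the
#' near-TSS hypomethylation rule for ETn/MusD (probability 4/7 of being
#' unmethylated within 1.5 kb of a TSS, the proportion observed among
#' near-TSS copies), 10 bisulfite clones x 20 CpGs per region with a 2%
#' conversion-failure rate and 10% PCR-duplicate rate, qPCR efficiency 2.0
#' with noise_sd 0.3 cycles, and H3K4me3 peaks of height 10 decaying over
#' 500 bp at expressed TSSs.
#'
#' @param ... named overrides, e.g. `selection = list(type = "hard_exclusion",
#'   d_sel = 1500)` or `seed = 7`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(n_chromosomes = 5L, chrom_length = 2e6),
    genes = list(n_genes = 200L, length_range = c(2000, 10000),
                 cgi_promoter_fraction = 0.6, cgi_width_range = c(500, 1500),
                 tissues = c("liver", "spleen", "kidney", "pancreas", "testis"),
                 expressed_prob = 0.5),
    ervs = list(n_per_family = c("ETn/MusD" = 150L, "IAP" = 150L),
                full_length_fraction = 0.15, ltr_length = 330,
                full_length_size = 7000, polymorphic_fraction = 0.2),
    selection = list(type = "none", d_sel = 1500, d50 = 1500, slope = 300),
    methylation = list(baseline = c("ETn/MusD" = 0.85, "IAP" = 0.90),
                       near_tss_distance = 1500, near_unmeth_prob = 4 / 7,
                       near_unmeth_level = 0.05, level_sd = 0.05),
    bisulfite = list(clones_per_region = 10L, cpgs_per_region = 20L,
                     n_noncpg_c = 40L, conversion_failure_rate = 0.02,
                     duplicate_rate = 0.1),
    ct_model = list(base_ct = 25, efficiency = 2.0, noise_sd = 0.3,
                    capture_scale = 1, floor = 0.01),
    signal = list(tss_peak_height = 10, decay_length = 500,
                  ctcf_boundary_fraction = 0.5, ctcf_peak_height = 8,
                  ctcf_peak_width = 50, background_sd = 0.1,
                  input_level = 1, bin = 20)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  stopifnot(cfg$genes$cgi_promoter_fraction >= 0,
            cfg$genes$cgi_promoter_fraction <= 1,
            cfg$selection$d_sel < cfg$genome$chrom_length)
  structure(cfg, class = "sim_config")
}

# stable small integer derived from a string, for per-region seed offsets
string_seed <- function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100000L

#' Generate a genome with genes, CGI promoters and expression states
#'
#' Genes are laid out on a jittered grid (one gene per equal-width slot) so
#' they never overlap; each gets a random strand, and the configured fraction
#' of promoters receives a CpG island overlapping the TSS. Expression is an
#' independent coin per (gene, tissue).
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `genes`, `cgis`, `expression`.
#' @export
make_genome_and_genes <- function(config) {
  withr::with_seed(config$seed + 11L, {
    gcfg <- config$genome
    genome <- genome_model(paste0("chr", seq_len(gcfg$n_chromosomes)),
                           rep(gcfg$chrom_length, gcfg$n_chromosomes))
    ncfg <- config$genes
    chrom_of <- rep(genome$chrom, length.out = ncfg$n_genes)
    per_chrom <- table(chrom_of)
    rows <- lapply(names(per_chrom), function(ch) {
      k <- per_chrom[[ch]]
      L <- genome$length[genome$chrom == ch]
      slot <- floor(L / k)
      max_len <- ncfg$length_range[2]
      if (slot <= max_len + 2) {
        stop("capacity error: cannot place ", k, " non-overlapping genes of up to ",
             max_len, " bp on a ", L, " bp chromosome")
      }
      len <- floor(runif(k, ncfg$length_range[1], ncfg$length_range[2]))
      offset <- floor(runif(k, 0, slot - len))
      start <- (seq_len(k) - 1) * slot + offset
      data.frame(chrom = ch, start = start, end = start + len,
                 strand = sample(c("+", "-"), k, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    pos <- do.call(rbind, rows)
    genes <- gene_table(
      gene_id = sprintf("gene%03d", seq_len(nrow(pos))),
      chrom = pos$chrom, strand = pos$strand,
      tss = ifelse(pos$strand == "+", pos$start, pos$end),
      tts = ifelse(pos$strand == "+", pos$end, pos$start)
    )
    has_cgi <- runif(nrow(genes)) < ncfg$cgi_promoter_fraction
    if (any(has_cgi)) {
      w <- floor(runif(sum(has_cgi), ncfg$cgi_width_range[1],
                       ncfg$cgi_width_range[2]))
      off <- floor(runif(sum(has_cgi), -300, 300))
      tss <- genes$tss[has_cgi]
      L <- config$genome$chrom_length
      cstart <- pmax(0, pmin(tss - floor(w / 2) + off, L - w))
      cgis <- cgi_table(genes$chrom[has_cgi], cstart, cstart + w)
    } else {
      cgis <- cgi_table(character(0), numeric(0), numeric(0))
    }
    grid <- expand.grid(gene_id = genes$gene_id, tissue = ncfg$tissues,
                        stringsAsFactors = FALSE)
    expr <- expression_table(grid$gene_id, grid$tissue,
                             runif(nrow(grid)) < ncfg$expressed_prob)
    list(genome = genome, genes = genes, cgis = cgis, expression = expr)
  })
}

# nearest anchor (point set) distance for intervals [start, end); returns
# distance and index of the chosen anchor (ties broken to the lower
# coordinate). anchors: data.frame(chrom, pos, idx)
nearest_anchor_interval <- function(chrom, start, end, anchors) {
  d <- rep(NA_real_, length(start))
  which_anchor <- rep(NA_integer_, length(start))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    a <- anchors[anchors$chrom == ch, , drop = FALSE]
    if (!nrow(a)) next
    o <- order(a$pos)
    ap <- a$pos[o]; ai <- a$idx[o]
    i1 <- findInterval(start[sel], ap)              # anchors <= start
    i2 <- findInterval(end[sel], ap)                # anchors <= end
    inside <- i2 > i1                               # an anchor in (start, end]
    dl <- ifelse(i1 >= 1, start[sel] - ap[pmax(i1, 1)], Inf)
    dr <- ifelse(i2 < length(ap), ap[pmin(i2 + 1, length(ap))] - end[sel], Inf)
    di <- ifelse(inside, 0, pmin(dl, dr))
    pick_left <- inside | (dl <= dr)                # tie -> lower coordinate
    idx_left <- ifelse(inside, i1 + 1L, pmax(i1, 1L))
    wa <- ifelse(pick_left, ai[idx_left], ai[pmin(i2 + 1L, length(ap))])
    d[sel] <- di
    which_anchor[sel] <- wa
  }
  list(distance = d, anchor = which_anchor)
}

# nearest anchor distance for point positions
nearest_anchor_point <- function(chrom, pos, anchors) {
  d <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ap <- sort(anchors$pos[anchors$chrom == ch])
    if (!length(ap)) next
    i <- findInterval(pos[sel], ap)
    dl <- ifelse(i >= 1, pos[sel] - ap[pmax(i, 1)], Inf)
    dr <- ifelse(i < length(ap), ap[pmin(i + 1, length(ap))] - pos[sel], Inf)
    d[sel] <- pmin(dl, dr)
  }
  d
}

selection_prob <- function(selection, d) {
  switch(selection$type,
    none = rep(1, length(d)),
    hard_exclusion = as.numeric(d >= selection$d_sel),
    logistic = 1 / (1 + exp(-(d - selection$d50) / selection$slope)),
    stop("unknown selection type: ", selection$type)
  )
}

#' Sample ERV insertions under a selection function
#'
#' Candidate insertion points are uniform over the genome (chromosome chosen
#' proportional to length); each candidate is dressed with an element span
#' (solo LTR or full-length, per the configured mix) and retained with the
#' probability given by the selection function evaluated at the element's
#' nearest-edge distance to the nearest TSS. Sampling continues until
#' `n_per_family` copies are retained per family.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_model()].
#' @param genes a [gene_table()].
#' @return an [erv_table()] with the selection settings attached as
#'   `attr(, "selection")` (ground-truth sidecar).
#' @export
sample_insertions <- function(config, genome, genes) {
  ecfg <- config$ervs
  anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                        idx = seq_len(nrow(genes)))
  withr::with_seed(config$seed + 23L, {
    out <- lapply(names(ecfg$n_per_family), function(fam) {
      target <- ecfg$n_per_family[[fam]]
      got <- list(); n_got <- 0L; batch <- 0L
      while (n_got < target) {
        batch <- batch + 1L
        if (batch > 200L) stop("selection too strict: cannot retain ", target,
                               " copies")
        nb <- max(4L * target, 5000L)
        ci <- sample.int(nrow(genome), nb, replace = TRUE,
                         prob = genome$length)
        full <- runif(nb) < ecfg$full_length_fraction
        len <- ifelse(full, ecfg$full_length_size, ecfg$ltr_length)
        pos <- floor(runif(nb) * (genome$length[ci] - len))
        d <- nearest_anchor_interval(genome$chrom[ci], pos, pos + len,
                                     anchors)$distance
        ok <- !is.na(d) & runif(nb) < selection_prob(config$selection, d)
        if (any(ok)) {
          got[[length(got) + 1L]] <- data.frame(
            chrom = genome$chrom[ci][ok], start = pos[ok],
            end = pos[ok] + len[ok], full = full[ok],
            stringsAsFactors = FALSE)
          n_got <- n_got + sum(ok)
        }
      }
      df <- utils::head(do.call(rbind, got), target)
      df$family <- fam
      df
    })
    df <- do.call(rbind, out)
    n <- nrow(df)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    lt <- ecfg$ltr_length
    left_ltr_is5 <- strand == "+"
    ltr5_start <- ifelse(df$full, ifelse(left_ltr_is5, df$start, df$end - lt),
                         df$start)
    ltr5_end <- ifelse(df$full, ltr5_start + lt, df$end)
    ltr3_start <- ifelse(df$full, ifelse(left_ltr_is5, df$end - lt, df$start),
                         NA)
    ltr3_end <- ifelse(df$full, ltr3_start + lt, NA)
    ervs <- erv_table(
      erv_id = sprintf("%s_%04d", sub("/", "", df$family), seq_len(n)),
      family = df$family,
      element_type = ifelse(df$full, "full_length", "solo"),
      chrom = df$chrom, start = df$start, end = df$end, strand = strand,
      ltr5_start = ltr5_start, ltr5_end = ltr5_end,
      ltr3_start = ltr3_start, ltr3_end = ltr3_end,
      polymorphism = ifelse(runif(n) < ecfg$polymorphic_fraction,
                            "polymorphic", "fixed")
    )
    attr(ervs, "selection") <- config$selection
    ervs
  })
}

#' Assign ground-truth methylation levels to ERV copies
#'
#' Family baselines (IAP heavily methylated, ETn/MusD slightly lower) with
#' Gaussian jitter, clipped to (0.01, 0.99); ETn/MusD copies within the
#' near-TSS window are set to the unmethylated level with the configured
#' probability, emulating the observation that near-TSS ETn/MusD copies are
#' often unmethylated while IAPs stay methylated.
#'
#' @param config a [sim_config()].
#' @param ervs an [erv_table()].
#' @param genes a [gene_table()].
#' @return data.frame `erv_id`, `family`, `distance_to_tss`, `true_level`
#'   (ground-truth sidecar).
#' @export
assign_true_methylation <- function(config, ervs, genes) {
  mcfg <- config$methylation
  anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                        idx = seq_len(nrow(genes)))
  d <- nearest_anchor_interval(ervs$chrom, ervs$start, ervs$end,
                               anchors)$distance
  withr::with_seed(config$seed + 31L, {
    lvl <- mcfg$baseline[ervs$family] +
      rnorm(nrow(ervs), 0, mcfg$level_sd)
    near <- !is.na(d) & d < mcfg$near_tss_distance
    flip <- near & ervs$family == "ETn/MusD" &
      runif(nrow(ervs)) < mcfg$near_unmeth_prob
    lvl[flip] <- mcfg$near_unmeth_level
    data.frame(erv_id = ervs$erv_id, family = ervs$family,
               distance_to_tss = d,
               true_level = pmin(0.99, pmax(0.01, lvl)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate bisulfite clones for one region
#'
#' Each clone calls `cpgs_per_region` CpGs, methylated independently with
#' probability `true_level`; each of `n_noncpg_c` non-CpG cytosines fails
#' conversion with `conversion_failure_rate`. With probability
#' `duplicate_rate` a clone is an exact PCR duplicate of an earlier clone
#' (same CpG pattern and same conversion-error positions). Ground-truth
#' duplicate links are attached as `attr(, "truth")`.
#'
#' @param config a [sim_config()].
#' @param region_id region label (also seeds the region's RNG stream).
#' @param true_level ground-truth methylation probability.
#' @param tissue tissue label.
#' @return a [bisulfite_clone_set()].
#' @export
simulate_bisulfite_clones <- function(config, region_id, true_level,
                                      tissue = "liver") {
  bcfg <- config$bisulfite
  withr::with_seed(config$seed + 47L + string_seed(region_id), {
    clones <- list()
    truth <- data.frame(clone_id = character(0), duplicate_of = character(0),
                        stringsAsFactors = FALSE)
    for (i in seq_len(bcfg$clones_per_region)) {
      id <- sprintf("%s_clone%02d", region_id, i)
      if (i > 1 && runif(1) < bcfg$duplicate_rate) {
        src <- sample.int(i - 1L, 1L)
        cl <- clones[[src]]
        cl$clone_id <- id
        clones[[i]] <- cl
        truth <- rbind(truth, data.frame(clone_id = id,
                                         duplicate_of = clones[[src]]$clone_id))
      } else {
        clones[[i]] <- list(
          clone_id = id,
          cpg = runif(bcfg$cpgs_per_region) < true_level,
          nonconv = which(runif(bcfg$n_noncpg_c) < bcfg$conversion_failure_rate),
          n_noncpg_c = bcfg$n_noncpg_c
        )
        truth <- rbind(truth, data.frame(clone_id = id,
                                         duplicate_of = NA_character_))
      }
    }
    set <- bisulfite_clone_set(region_id, tissue, clones)
    attr(set, "truth") <- truth
    set
  })
}

#' Simulate a MeDIP-qPCR Ct table
#'
#' For each region, `Ct_IP = Ct_input - log_E(level * capture + floor) +
#' N(0, noise_sd)` where `E` is the primer efficiency; one spike-in row with
#' true level 1 is added per batch (the in-vitro methylated positive
#' control). With `noise_sd = 0`, `capture = 1`, `floor = 0` the normalized
#' score recovers `true_level` exactly.
#'
#' @param config a [sim_config()].
#' @param regions data.frame with `region_id`, `tissue`, `true_level`.
#' @param batch_id batch label shared by all rows (one spike per batch).
#' @return data.frame of measurements (columns `region_id`, `tissue`,
#'   `ct_input`, `ct_ip`, `efficiency`, `batch_id`, `is_spike`).
#' @export
simulate_ct_table <- function(config, regions, batch_id = "batch1") {
  ccfg <- config$ct_model
  withr::with_seed(config$seed + 59L, {
    rows <- rbind(
      data.frame(region_id = regions$region_id, tissue = regions$tissue,
                 true_level = regions$true_level, is_spike = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(region_id = "spikein", tissue = "control", true_level = 1,
                 is_spike = TRUE, stringsAsFactors = FALSE)
    )
    captured <- rows$true_level * ccfg$capture_scale + ccfg$floor
    ct_input <- rep(ccfg$base_ct, nrow(rows))
    ct_ip <- ct_input - log(captured) / log(ccfg$efficiency) +
      rnorm(nrow(rows), 0, ccfg$noise_sd)
    data.frame(region_id = rows$region_id, tissue = rows$tissue,
               ct_input = ct_input, ct_ip = ct_ip,
               efficiency = ccfg$efficiency, batch_id = batch_id,
               is_spike = rows$is_spike, stringsAsFactors = FALSE)
  })
}

#' Simulate chromatin signal tracks
#'
#' Emits binned bedGraph-style tracks: H3K4me3 peaks of configured height at
#' expressed TSSs decaying exponentially with `decay_length` into the flanks;
#' CTCF point peaks (Gaussian bumps) midway between an ERV edge and the
#' nearest TSS for the configured fraction of ERV-gene pairs within 10 kb; a
#' flat Input track. Gaussian background noise is added everywhere and values
#' are clipped at 0.
#'
#' @param config a [sim_config()].
#' @param genome,genes as generated by [make_genome_and_genes()].
#' @param expression an [expression_table()].
#' @param tissue tissue whose expression states drive the peaks.
#' @param ervs optional [erv_table()] enabling CTCF boundary peaks.
#' @return named list of [signal_track()]s: `H3K4me3`, `CTCF`, `Input`.
#' @export
simulate_signal_tracks <- function(config, genome, genes, expression,
                                   tissue = "liver", ervs = NULL) {
  scfg <- config$signal
  withr::with_seed(config$seed + 71L, {
    expr_on <- expression$gene_id[expression$tissue == tissue &
                                  expression$expressed]
    make_grid <- function(ch) {
      L <- genome$length[genome$chrom == ch]
      starts <- seq(0, L - scfg$bin, by = scfg$bin)
      list(starts = starts, mid = starts + scfg$bin / 2)
    }
    tracks <- list(H3K4me3 = NULL, CTCF = NULL, Input = NULL)
    ctcf_peaks <- NULL
    if (!is.null(ervs) && nrow(ervs)) {
      anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                            idx = seq_len(nrow(genes)))
      na <- nearest_anchor_interval(ervs$chrom, ervs$start, ervs$end, anchors)
      ok <- !is.na(na$distance) & na$distance > 0 & na$distance <= 10000 &
        runif(nrow(ervs)) < scfg$ctcf_boundary_fraction
      if (any(ok)) {
        tss <- genes$tss[na$anchor[ok]]
        edge <- ifelse(tss >= ervs$end[ok], ervs$end[ok], ervs$start[ok])
        ctcf_peaks <- data.frame(chrom = ervs$chrom[ok],
                                 pos = (edge + tss) / 2)
      }
    }
    per_chrom <- lapply(genome$chrom, function(ch) {
      g <- make_grid(ch)
      nbin <- length(g$starts)
      noise <- function() pmax(0, rnorm(nbin, 0, scfg$background_sd))
      h3 <- noise()
      tss_here <- genes$tss[genes$chrom == ch & genes$gene_id %in% expr_on]
      for (tss in tss_here) {
        w <- which(abs(g$mid - tss) < 10 * scfg$decay_length)
        h3[w] <- h3[w] + scfg$tss_peak_height *
          exp(-abs(g$mid[w] - tss) / scfg$decay_length)
      }
      ctcf <- noise()
      if (!is.null(ctcf_peaks)) {
        for (p in ctcf_peaks$pos[ctcf_peaks$chrom == ch]) {
          w <- which(abs(g$mid - p) < 6 * scfg$ctcf_peak_width)
          ctcf[w] <- ctcf[w] + scfg$ctcf_peak_height *
            exp(-(g$mid[w] - p)^2 / (2 * scfg$ctcf_peak_width^2))
        }
      }
      inp <- pmax(0, scfg$input_level + rnorm(nbin, 0, scfg$background_sd))
      data.frame(chrom = ch, start = g$starts, end = g$starts + scfg$bin,
                 h3 = round(h3, 4), ctcf = round(ctcf, 4),
                 inp = round(inp, 4), stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, per_chrom)
    list(H3K4me3 = signal_track(all$chrom, all$start, all$end, all$h3),
         CTCF = signal_track(all$chrom, all$start, all$end, all$ctcf),
         Input = signal_track(all$chrom, all$start, all$end, all$inp))
  })
}

#' Build a synthetic bisulfite reference sequence
#'
#' Deterministic reference with exactly `n_cpg` CpG dinucleotides (one per
#' `ACGT` unit) followed by `n_noncpg_c` non-CpG cytosines (one per `TCTT`
#' unit), so CpG and conversion positions are known by construction.
#'
#' @param n_cpg,n_noncpg_c counts.
#' @return a character scalar DNA sequence.
#' @export
make_bisulfite_reference <- function(n_cpg, n_noncpg_c) {
  paste0(strrep("ACGT", n_cpg), strrep("TCTT", n_noncpg_c))
}

#' Render bisulfite clone calls as converted reads
#'
#' Inverse of [bisulfite_from_reads()]: methylated CpG cytosines stay `C`,
#' unmethylated ones read `T`; non-CpG cytosines read `T` unless the clone
#' carries a conversion failure at that position (then `C`).
#'
#' @param reference sequence from [make_bisulfite_reference()].
#' @param set a [bisulfite_clone_set()].
#' @return named character vector of reads (one per clone).
#' @export
clones_to_reads <- function(reference, set) {
  chars <- strsplit(reference, "")[[1]]
  cpg_pos <- gregexpr("CG", reference)[[1]]
  noncpg_pos <- setdiff(which(chars == "C"), cpg_pos)
  reads <- vapply(set$clones, function(cl) {
    if (length(cl$cpg) != length(cpg_pos)) {
      stop("clone CpG count does not match reference")
    }
    r <- chars
    r[cpg_pos] <- ifelse(cl$cpg, "C", "T")
    conv <- rep(TRUE, length(noncpg_pos))
    conv[cl$nonconv] <- FALSE
    r[noncpg_pos] <- ifelse(conv, "T", "C")
    paste(r, collapse = "")
  }, character(1))
  names(reads) <- vapply(set$clones, function(cl) {
    if (is.null(cl$clone_id)) "clone" else cl$clone_id
  }, character(1))
  reads
}

#' Write a full synthetic input bundle to disk
#'
#' Emits every file the pipeline consumes, in the formats the readers in this
#' package accept: `genome.tsv`, `genes.bed`, `cgis.bed`, `ervs.bed` (extended
#' BED), `expression.tsv`, `ct_table.tsv`, the three bedGraph tracks, plus
#' ground-truth sidecars (`truth_methylation.tsv`, `selection.tsv`).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param tissue tissue used for the signal tracks.
#' @return invisibly, a list of the in-memory objects written.
#' @export
write_simulation <- function(config, dir, tissue = "liver") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- make_genome_and_genes(config)
  ervs <- sample_insertions(config, world$genome, world$genes)
  truth <- assign_true_methylation(config, ervs, world$genes)
  ct <- simulate_ct_table(config, data.frame(region_id = truth$erv_id,
                                             tissue = tissue,
                                             true_level = truth$true_level))
  tracks <- simulate_signal_tracks(config, world$genome, world$genes,
                                   world$expression, tissue, ervs)
  p <- function(f) file.path(dir, f)
  write.table(world$genome, p("genome.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_features(world$genes, p("genes.bed"))
  write_features(world$cgis, p("cgis.bed"))
  write_features(ervs, p("ervs.bed"))
  write.table(world$expression, p("expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ct, p("ct_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth, p("truth_methylation.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(as.data.frame(config$selection), p("selection.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(tracks$H3K4me3, p("h3k4me3.bedGraph"))
  write_bedgraph(tracks$CTCF, p("ctcf.bedGraph"))
  write_bedgraph(tracks$Input, p("input.bedGraph"))
  invisible(list(world = world, ervs = ervs, truth = truth, ct = ct,
                 tracks = tracks))
}
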