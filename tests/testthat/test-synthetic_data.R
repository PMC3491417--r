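test_that("generators are deterministic under the config seed", {
  cfg <- sim_config(seed = 12)
  w1 <- make_genome_and_genes(cfg)
  w2 <- make_genome_and_genes(cfg)
  expect_identical(w1, w2)
  e1 <- sample_insertions(cfg, w1$genome, w1$genes)
  e2 <- sample_insertions(cfg, w1$genome, w1$genes)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  s1 <- simulate_bisulfite_clones(cfg, "rX", 0.7)
  s2 <- simulate_bisulfite_clones(cfg, "rX", 0.7)
  expect_identical(s1$clones, s2$clones)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg_small <- sim_config(seed = 12,
                          genome = list(n_chromosomes = 2L, chrom_length = 1e5),
                          genes = list(n_genes = 10L,
                                       length_range = c(1000, 3000)),
                          ervs = list(n_per_family = c("IAP" = 20L)))
  write_simulation(cfg_small, d1)
  write_simulation(cfg_small, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("gene/CGI generation respects density and the CGI fraction", {
  cfg <- sim_config(seed = 4, genes = list(cgi_promoter_fraction = 0.6))
  w <- make_genome_and_genes(cfg)
  # genes never overlap within a chromosome
  for (ch in unique(w$genes$chrom)) {
    g <- w$genes[w$genes$chrom == ch, ]
    lo <- pmin(g$tss, g$tts); hi <- pmax(g$tss, g$tts)
    o <- order(lo)
    expect_true(all(lo[o][-1] >= hi[o][-length(o)]))
  }
  # CGI count within 3 sigma of binomial expectation
  n <- nrow(w$genes)
  expect_lt(abs(nrow(w$cgis) - 0.6 * n), 3 * sqrt(n * 0.6 * 0.4) + 1)
  # classify_cgi_promoter recovers the planted islands
  g2 <- classify_cgi_promoter(w$genes, w$cgis)
  expect_equal(sum(g2$promoter_is_cgi), nrow(w$cgis))
  # zero fraction -> no CGI
  w0 <- make_genome_and_genes(sim_config(seed = 4,
                                         genes = list(cgi_promoter_fraction = 0)))
  expect_equal(nrow(w0$cgis), 0)
  # impossible density errors out
  expect_error(make_genome_and_genes(
    sim_config(genome = list(n_chromosomes = 1L, chrom_length = 1e4),
               genes = list(n_genes = 10L, length_range = c(2000, 9000)))),
    "capacity")
})

test_that("hard-exclusion selection leaves no copy inside the zone", {
  cfg <- sim_config(seed = 8,
                    selection = list(type = "hard_exclusion", d_sel = 1500))
  w <- make_genome_and_genes(cfg)
  ervs <- sample_insertions(cfg, w$genome, w$genes)
  obs <- observed_distances(ervs, w$genes, "tss")
  expect_true(all(obs$distance >= 1500))
})

test_that("unselected insertions match uniform coverage per bin", {
  # analytic expectation: fraction of genome within [lo, hi) of an anchor
  cfg <- sim_config(seed = 15, selection = list(type = "none"),
                    ervs = list(n_per_family = c("IAP" = 4000L),
                                full_length_fraction = 0, ltr_length = 2))
  w <- make_genome_and_genes(cfg)
  ervs <- sample_insertions(cfg, w$genome, w$genes)
  obs <- observed_distances(ervs, w$genes, "tss")
  L <- sum(w$genome$length)
  n_anchor <- nrow(w$genes)
  n <- nrow(ervs)
  for (bin in list(c(0, 2000), c(2000, 4000), c(4000, 6000))) {
    p_exp <- n_anchor * 2 * (bin[2] - bin[1]) / L  # both sides, sparse anchors
    got <- mean(obs$distance >= bin[1] & obs$distance < bin[2])
    expect_lt(abs(got - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n) + 0.005)
  }
})

test_that("bisulfite clone simulation recovers the true level after QC", {
  cfg <- sim_config(seed = 21,
                    bisulfite = list(clones_per_region = 50L,
                                     cpgs_per_region = 20L,
                                     duplicate_rate = 0))
  set <- simulate_bisulfite_clones(cfg, "recov", 0.8)
  frac <- methylation_fraction(dedup_clones(filter_conversion(set)))$fraction
  n_calls <- 50 * 20
  expect_lt(abs(frac - 0.8), 3 * sqrt(0.8 * 0.2 / n_calls) + 0.02)
  # degenerate extremes
  cfg1 <- sim_config(seed = 21,
                     bisulfite = list(conversion_failure_rate = 0,
                                      duplicate_rate = 0))
  s1 <- simulate_bisulfite_clones(cfg1, "all", 1.0)
  expect_true(all(unlist(lapply(s1$clones, `[[`, "cpg"))))
  expect_true(all(vapply(s1$clones, conversion_rate, numeric(1)) == 1))
})

test_that("duplicate injection is recorded and removed exactly", {
  cfg <- sim_config(seed = 33,
                    bisulfite = list(clones_per_region = 20L,
                                     duplicate_rate = 0.5))
  set <- simulate_bisulfite_clones(cfg, "dup", 0.5)
  truth <- attr(set, "truth")
  expect_gt(sum(!is.na(truth$duplicate_of)), 0)
  dedup <- dedup_clones(set)
  kept <- vapply(dedup$clones, `[[`, character(1), "clone_id")
  # every originally-generated (non-duplicate) clone pattern survives
  originals <- truth$clone_id[is.na(truth$duplicate_of)]
  expect_setequal(kept, intersect(kept, truth$clone_id))
  expect_true(all(originals %in% kept))
  # and no two retained clones share both pattern and error set
  pat <- vapply(dedup$clones, function(cl) paste(as.integer(cl$cpg),
                                                 collapse = ""), character(1))
  err <- vapply(dedup$clones, function(cl) paste(cl$nonconv, collapse = ","),
                character(1))
  expect_false(any(duplicated(paste(pat, err))))
})

test_that("noiseless Ct tables invert to the true level exactly", {
  cfg <- sim_config(seed = 2, ct_model = list(noise_sd = 0, floor = 0))
  ct <- simulate_ct_table(cfg, data.frame(region_id = c("a", "b"),
                                          tissue = "liver",
                                          true_level = c(1, 0.1)))
  calls <- medip_call_table(ct)
  expect_equal(calls$score, c(1, 0.1), tolerance = 1e-12)
  expect_equal(calls$call, c("methylated", "unmethylated"))
})

test_that("signal tracks peak at expressed TSSs and decay as configured", {
  cfg <- sim_config(seed = 5,
                    genome = list(n_chromosomes = 1L, chrom_length = 1e5),
                    genes = list(n_genes = 2L, length_range = c(1000, 2000),
                                 tissues = "liver"),
                    signal = list(background_sd = 0, bin = 10,
                                  tss_peak_height = 10, decay_length = 500))
  w <- make_genome_and_genes(cfg)
  expr <- expression_table(w$genes$gene_id, "liver", c(TRUE, FALSE))
  tr <- simulate_signal_tracks(cfg, w$genome, w$genes, expr, "liver")
  tss_on <- w$genes$tss[1]
  tss_off <- w$genes$tss[2]
  at <- function(pos) query_track(tr$H3K4me3, "chr1", pos)
  # peak at the expressed TSS, e-fold decay at one decay length
  expect_gt(at(tss_on), 9)
  expect_equal(at(tss_on + 500) / at(tss_on), exp(-1), tolerance = 0.05)
  # silent gene: background only (zero here)
  expect_lt(at(tss_off), 0.01)
  expect_equal(query_track(tr$Input, "chr1", 500), 1)
})

test_that("bisulfite reference/read rendering round-trips clone calls", {
  ref <- make_bisulfite_reference(5, 8)
  expect_equal(length(gregexpr("CG", ref)[[1]]), 5)
  cfg <- sim_config(seed = 9, bisulfite = list(clones_per_region = 6L,
                                               cpgs_per_region = 5L,
                                               n_noncpg_c = 8L,
                                               duplicate_rate = 0))
  set <- simulate_bisulfite_clones(cfg, "rt", 0.6)
  reads <- clones_to_reads(ref, set)
  back <- bisulfite_from_reads(ref, reads, "rt", "liver")
  for (i in seq_along(set$clones)) {
    expect_equal(back$clones[[i]]$cpg, set$clones[[i]]$cpg)
    expect_equal(back$clones[[i]]$nonconv, set$clones[[i]]$nonconv)
  }
})
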