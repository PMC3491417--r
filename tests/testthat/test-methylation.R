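spike1 <- list(region_id = "spikein", tissue = "control", ct_input = 20,
               ct_ip = 20, efficiency = 2, batch_id = "b1")

test_that("medip_score implements the enrichment formula with spike division", {
  m <- list(region_id = "r", tissue = "liver", ct_input = 20, ct_ip = 20,
            efficiency = 2, batch_id = "b1")
  c1 <- medip_score(m, spike1)
  expect_equal(c1$score, 1)
  expect_equal(c1$call, "methylated")
  # efficiency 2, Ct_input 20, Ct_IP 23 -> 2^-3 = 0.125 -> unmethylated
  m$ct_ip <- 23
  c2 <- medip_score(m, spike1)
  expect_equal(c2$score, 0.125)
  expect_equal(c2$call, "unmethylated")
  # raw 0.4 over spike raw 0.5 -> 0.8
  m3 <- list(region_id = "r", tissue = "liver", ct_input = 20,
             ct_ip = 20 - log2(0.4), efficiency = 2, batch_id = "b1")
  s3 <- list(region_id = "s", tissue = "c", ct_input = 20,
             ct_ip = 20 - log2(0.5), efficiency = 2, batch_id = "b1")
  expect_equal(medip_score(m3, s3)$score, 0.8, tolerance = 1e-12)
  expect_equal(medip_score(m3, s3)$call, "methylated")
})

test_that("medip_score validates input and batch linkage", {
  m <- list(region_id = "r", tissue = "l", ct_input = NaN, ct_ip = 20,
            efficiency = 2, batch_id = "b1")
  expect_error(medip_score(m, spike1), "invalid Ct")
  m$ct_input <- 20
  bad_spike <- spike1; bad_spike$batch_id <- "b2"
  expect_error(medip_score(m, bad_spike), "different batch")
  expect_error(medip_score(m, list()[0]), "missing spike")
})

test_that("medip_score monotonicity and spike scale invariance", {
  mk <- function(ct_ip, shift = 0) {
    # shift raises both the region's and the spike's raw enrichment 2^shift-fold
    m <- list(region_id = "r", tissue = "l", ct_input = 20,
              ct_ip = ct_ip + shift, efficiency = 2, batch_id = "b1")
    s <- spike1; s$ct_ip <- s$ct_ip + shift
    medip_score(m, s)$score
  }
  # strictly decreasing in ct_ip
  scores <- vapply(seq(18, 26, by = 2), mk, numeric(1))
  expect_true(all(diff(scores) < 0))
  # scaling region and spike raw enrichment together leaves the score unchanged
  expect_equal(mk(21, shift = -3), mk(21, shift = 0))
  # mean-of-spikes combination
  m <- list(region_id = "r", tissue = "l", ct_input = 20, ct_ip = 20,
            efficiency = 2, batch_id = "b1")
  spikes <- data.frame(region_id = "s", tissue = "c", ct_input = 20,
                       ct_ip = c(19, 21), efficiency = 2, batch_id = "b1")
  expect_equal(medip_score(m, spikes)$score, 1 / mean(c(2, 0.5)))
  expect_equal(medip_score(m, spikes, spike_combine = "first")$score, 0.5)
})

test_that("conversion rate filter is strict at 95%", {
  expect_equal(conversion_rate(make_clone(rep(TRUE, 5), nonconv = 1,
                                          n_noncpg_c = 40)), 0.975)
  expect_true(passes_conversion(make_clone(rep(TRUE, 5), nonconv = 1,
                                           n_noncpg_c = 40)))
  # exactly 95% fails the strict filter
  expect_false(passes_conversion(make_clone(rep(TRUE, 5), nonconv = 1,
                                            n_noncpg_c = 20)))
  expect_true(passes_conversion(make_clone(rep(TRUE, 5), n_noncpg_c = 20)))
  # no assayable non-CpG C -> indeterminate, flagged not passed
  ind <- make_clone(rep(TRUE, 5), n_noncpg_c = 0)
  expect_true(is.na(passes_conversion(ind)))
  fset <- filter_conversion(make_set(list(ind)))
  expect_equal(length(fset$clones), 0)
  expect_equal(attr(fset, "indeterminate"), 1)
})

test_that("dedup keeps clones unique in pattern OR error set", {
  p <- c(TRUE, FALSE, TRUE)
  # identical in both respects -> collapse to first
  s1 <- make_set(list(make_clone(p, c(1, 3), id = "a"),
                      make_clone(p, c(1, 3), id = "b"),
                      make_clone(p, c(1, 3), id = "c")))
  expect_equal(vapply(dedup_clones(s1)$clones, `[[`, character(1),
                      "clone_id"), "a")
  # same pattern, different error sets -> both retained (the OR clause)
  s2 <- make_set(list(make_clone(p, c(1, 3), id = "a"),
                      make_clone(p, c(2), id = "b")))
  expect_equal(length(dedup_clones(s2)$clones), 2)
  # empty set passes through
  expect_equal(length(dedup_clones(make_set(list()))$clones), 0)
  # idempotence and non-growth on simulated sets
  cfg <- sim_config(seed = 13, bisulfite = list(duplicate_rate = 0.4,
                                                clones_per_region = 15L))
  set <- simulate_bisulfite_clones(cfg, "idem", 0.5)
  once <- dedup_clones(set)
  expect_identical(dedup_clones(once)$clones, once$clones)
  expect_lte(length(once$clones), length(set$clones))
})

test_that("methylation_fraction counts calls and is order-invariant", {
  clones <- list(make_clone(c(TRUE, TRUE, TRUE, TRUE, FALSE), id = "a"),
                 make_clone(c(TRUE, TRUE, TRUE, TRUE, FALSE), c(2), id = "b"),
                 make_clone(c(TRUE, TRUE, TRUE, TRUE, TRUE), id = "c"),
                 make_clone(c(TRUE, TRUE, FALSE, FALSE, TRUE), id = "d"))
  # 16 methylated of 20 calls
  expect_equal(methylation_fraction(make_set(clones))$fraction, 0.8)
  expect_equal(methylation_fraction(make_set(rev(clones)))$fraction, 0.8)
  expect_equal(methylation_fraction(make_set(clones))$call, "methylated")
  expect_error(methylation_fraction(make_set(list())), "no clones")
  all1 <- replicate(10, make_clone(rep(TRUE, 10)), simplify = FALSE)
  expect_equal(methylation_fraction(make_set(all1))$fraction, 1)
})

test_that("concordance is Spearman over shared pairs", {
  m <- data.frame(region_id = letters[1:5], tissue = "l",
                  score = c(0.1, 0.3, 0.5, 0.7, 0.9))
  b <- data.frame(region_id = letters[1:5], tissue = "l",
                  fraction = c(0.05, 0.2, 0.6, 0.8, 0.95))
  expect_equal(medip_bisulfite_concordance(m, b)$statistic, 1)
  b$fraction <- rev(b$fraction)
  expect_equal(medip_bisulfite_concordance(m, b)$statistic, -1)
  expect_error(medip_bisulfite_concordance(m[1:2, ], b[1:2, ]), "at least 3")
})

test_that("bisulfite_from_reads handles degenerate controls", {
  ref <- make_bisulfite_reference(4, 10)
  # read identical to the reference: all CpGs methylated, nothing converted
  same <- bisulfite_from_reads(ref, c(cl1 = ref))
  expect_true(all(same$clones[[1]]$cpg))
  expect_equal(conversion_rate(same$clones[[1]]), 0)
  expect_false(passes_conversion(same$clones[[1]]))
  # fully converted read: fraction 0, conversion 100%
  conv <- chartr("C", "T", ref)
  full <- bisulfite_from_reads(ref, c(cl1 = conv))
  expect_false(any(full$clones[[1]]$cpg))
  expect_equal(conversion_rate(full$clones[[1]]), 1)
  expect_error(bisulfite_from_reads(ref, "ACGT"), "length differs")
  # ambiguous base at a CpG position is skipped with a warning
  amb <- conv
  substr(amb, 2, 2) <- "N"  # position 2 is the first reference CpG cytosine
  expect_warning(r <- bisulfite_from_reads(ref, c(cl1 = amb)), "ambiguous")
  expect_equal(length(r$clones[[1]]$cpg), 3)
})

test_that("bisulfite FASTA I/O feeds the QC pipeline", {
  ref <- make_bisulfite_reference(6, 12)
  cfg <- sim_config(seed = 6, bisulfite = list(clones_per_region = 8L,
                                               cpgs_per_region = 6L,
                                               n_noncpg_c = 12L))
  set <- simulate_bisulfite_clones(cfg, "fa", 0.7)
  reads <- clones_to_reads(ref, set)
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">reference", ref,
               unlist(lapply(names(reads), function(n) {
                 c(paste0(">", n), reads[[n]])
               }))), f)
  back <- read_bisulfite_fasta(f, "fa", "liver")
  expect_equal(methylation_fraction(back)$fraction,
               methylation_fraction(set)$fraction)
  qc <- bisulfite_qc(back)
  expect_true(!is.null(attr(qc, "qc")))
})
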