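test_that("classify_cgi_promoter uses the half-open 1.5 kb window", {
  g <- gene_table("g1", "chr1", "+", 10000, 12000)
  over <- function(cgi) classify_cgi_promoter(g, cgi)$promoter_is_cgi
  expect_true(over(cgi_table("chr1", 9900, 10100)))        # covers the TSS
  expect_false(over(cgi_table("chr1", 11501, 11600)))      # starts past +1500
  expect_false(over(cgi_table("chr1", 8000, 8500)))        # ends at -1500
  expect_true(over(cgi_table("chr1", 8000, 8501)))         # one base inside
  expect_true(over(cgi_table("chr1", 11499, 11600)))       # last inside base
  expect_false(classify_cgi_promoter(
    g, cgi_table(character(0), numeric(0), numeric(0)))$promoter_is_cgi)
})

test_that("proximal_ltr picks the TSS-nearer LTR with a flagged tie rule", {
  gene <- gene_table("g1", "chr1", "+", 30000, 35000)
  # + strand ERV left of the + gene: the right (3') LTR is nearer the TSS
  call <- proximal_ltr(one_full_length(20000, 27000, "+"), gene)
  expect_equal(call$proximal_ltr, "3prime")
  expect_equal(call$distance_to_tss, 30000 - 27000)
  # - strand ERV left of the gene: right LTR is the 5' one
  call2 <- proximal_ltr(one_full_length(20000, 27000, "-"), gene)
  expect_equal(call2$proximal_ltr, "5prime")
  # element centered on the TSS: equidistant -> 5' wins, flagged
  gene0 <- gene_table("g0", "chr1", "+", 23500, 29000)
  call3 <- proximal_ltr(one_full_length(20000, 27000, "+"), gene0)
  expect_true(call3$tie)
  expect_equal(call3$proximal_ltr, "5prime")
  solo <- erv_table("s", "IAP", "solo", "chr1", 100, 430, "+",
                    ltr5_start = 100, ltr5_end = 430)
  expect_error(proximal_ltr(solo, gene), "full-length")
})

test_that("proximal_ltr is invariant under genome mirroring plus strand flip", {
  M <- 1e6
  set.seed(2)
  for (i in 1:20) {
    s <- sample(5e5, 1); len <- 7000
    strand <- sample(c("+", "-"), 1)
    erv <- one_full_length(s, s + len, strand)
    tss <- s + sample(c(-5000, -1000, 3000, 9000), 1)
    gene <- gene_table("g", "chr1", "+", tss, tss + 2000)
    a <- proximal_ltr(erv, gene)
    mirrored <- erv_table(
      "erv1", "IAP", "full_length", "chr1", M - (s + len), M - s,
      ifelse(strand == "+", "-", "+"),
      ltr5_start = M - erv$ltr5_end, ltr5_end = M - erv$ltr5_start,
      ltr3_start = M - erv$ltr3_end, ltr3_end = M - erv$ltr3_start)
    gene_m <- gene_table("g", "chr1", "-", M - tss, M - tss - 2000)
    b <- proximal_ltr(mirrored, gene_m)
    expect_equal(b$proximal_ltr, a$proximal_ltr)
    expect_equal(b$distance_to_tss, a$distance_to_tss)
  }
})

table1_world <- function() {
  # 56 full-length IAPs, each with a gene TSS 1 kb right of the element;
  # the right-hand LTR faces the TSS, so strand "-" makes the 5' LTR
  # proximal. 25 elements 5'-proximal (20 CGI promoters), 31 3'-proximal
  # (15 CGI promoters) - the reference genome-wide screen counts.
  n <- 56
  strands <- c(rep("-", 25), rep("+", 31))
  cgi_flags <- c(rep(TRUE, 20), rep(FALSE, 5), rep(TRUE, 15), rep(FALSE, 16))
  chroms <- paste0("chr", seq_len(n))
  ervs <- do.call(rbind, lapply(seq_len(n), function(i) {
    one_full_length(10000, 17000, strands[i], chrom = chroms[i],
                    id = paste0("erv", i))
  }))
  class(ervs) <- c("erv_table", "data.frame")
  genes <- gene_table(paste0("g", seq_len(n)), chroms, "+",
                      tss = rep(18000, n), tts = rep(20000, n))
  cgis <- cgi_table(chroms[cgi_flags], 17800, 18200)
  genes <- classify_cgi_promoter(genes, cgis)
  list(ervs = ervs, genes = genes)
}

test_that("orientation/CGI table reproduces the reference screen values", {
  w <- table1_world()
  calls <- ltr_orientation_calls(w$ervs, w$genes)
  expect_equal(nrow(calls), 56)
  tab <- orientation_cgi_table(calls)
  expect_equal(tab$counts$n, c(25, 31))
  expect_equal(tab$counts$cgi, c(20, 15))
  expect_equal(tab$counts$pct_cgi[1], 80)
  expect_equal(round(tab$cgi_association_test$p_value, 4), 0.0314)
  expect_equal(round(tab$orientation_test$p_value, 1), 0.5)
})

test_that("orientation table flags degenerate classes and symmetric input", {
  all5 <- data.frame(proximal_ltr = rep("5prime", 8),
                     promoter_is_cgi = rep(TRUE, 8))
  tab <- orientation_cgi_table(all5)
  expect_true(tab$cgi_association_test$degenerate)
  # same CGI fraction in both classes -> association p = 1
  sym <- data.frame(proximal_ltr = rep(c("5prime", "3prime"), each = 20),
                    promoter_is_cgi = rep(c(TRUE, FALSE), 20))
  expect_equal(orientation_cgi_table(sym)$cgi_association_test$p_value, 1)
  expect_error(orientation_cgi_table(sym[0, ]), "no orientation calls")
})

test_that("compare_ltr_methylation runs Mann-Whitney on per-clone fractions", {
  hi <- make_set(replicate(8, make_clone(rep(TRUE, 10)), simplify = FALSE))
  lo <- make_set(replicate(8, make_clone(rep(FALSE, 10)), simplify = FALSE))
  r <- suppressWarnings(compare_ltr_methylation(hi, lo))
  expect_lt(r$p_value, 0.001)
  expect_equal(r$stars, "***")
  same <- suppressWarnings(compare_ltr_methylation(hi, hi))
  expect_gt(same$p_value, 0.9)
  expect_error(compare_ltr_methylation(make_set(list()), lo), "empty")
})

test_that("equal-level LTR pairs reject at about the nominal rate", {
  set.seed(31)
  rej <- vapply(1:100, function(i) {
    f5 <- replicate(8, make_clone(runif(10) < 0.5), simplify = FALSE)
    f3 <- replicate(8, make_clone(runif(10) < 0.5), simplify = FALSE)
    suppressWarnings(
      compare_ltr_methylation(make_set(f5), make_set(f3))$p_value) < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.10)  # at or below nominal (approx test with ties)
})

test_that("assess_spreading applies the methylated-ERV AND threshold rule", {
  mk_call <- function(score, tissue = "liver") {
    structure(list(region_id = "erv1", tissue = tissue, score = score,
                   fraction = NA_real_,
                   call = ifelse(score < 0.2, "unmethylated", "methylated"),
                   method = "medip"), class = "methylation_call")
  }
  prom <- function(frac, tissue = "liver") {
    n <- 100
    calls <- rep(c(TRUE, FALSE), c(round(frac * n), n - round(frac * n)))
    make_set(list(make_clone(calls)), region_id = "gene1", tissue = tissue)
  }
  # methylated ERV, promoter at 1% -> no spreading
  expect_false(assess_spreading(mk_call(0.95), prom(0.01), 973, TRUE)$spreading_call)
  # methylated ERV, promoter at 30% -> spreading
  expect_true(assess_spreading(mk_call(0.84), prom(0.30), 368, TRUE)$spreading_call)
  # boundary: exactly at the threshold counts as spreading (>=)
  expect_true(assess_spreading(mk_call(0.84), prom(0.10), 368, TRUE)$spreading_call)
  # unmethylated ERV never spreads, whatever the promoter shows
  expect_false(assess_spreading(mk_call(0.05), prom(0.90), 500, TRUE)$spreading_call)
  # monotone in the promoter fraction
  fr <- seq(0, 0.5, by = 0.05)
  calls <- vapply(fr, function(f) {
    assess_spreading(mk_call(0.9), prom(f), 500, FALSE)$spreading_call
  }, logical(1))
  expect_true(all(diff(as.integer(calls)) >= 0))
  expect_error(assess_spreading(mk_call(0.9, "liver"), prom(0.5, "brain"),
                                500, TRUE), "tissue mismatch")
})

test_that("filter_copies reports reasons and is stable on the passed subset", {
  ervs <- do.call(rbind, lapply(1:5, function(i) {
    one_full_length(10000, 17000, "+", id = paste0("e", i))
  }))
  class(ervs) <- c("erv_table", "data.frame")
  ev <- data.frame(
    erv_id = paste0("e", 1:5),
    est_available = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    expression_available = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    annotation_ok = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    tss_count = c(1, 2, 1, 5, 1),
    inside_upstream_gene = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  rep <- filter_copies(ervs, ev)
  expect_equal(rep$passed, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(rep$reasons[2], "no_est_or_expression_data")
  expect_equal(rep$reasons[3], "gene_misannotated")
  expect_equal(rep$reasons[4], "too_many_tss")
  expect_equal(rep$reasons[5],
               "no_est_or_expression_data,gene_misannotated,inside_upstream_gene")
  # configurable TSS rule
  expect_true(filter_copies(ervs[4, ], ev, max_tss = 5)$passed)
  # rerunning on the passed subset excludes nothing
  passed <- ervs[rep$passed, , drop = FALSE]
  expect_true(all(filter_copies(passed, ev)$passed))
  expect_error(filter_copies(ervs, ev[, -2]), "est_available")
})
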