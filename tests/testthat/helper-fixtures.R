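# Fixture builders shared across the suite. Everything is constructed in
# code; no stored data files.

tiny_genome <- function() genome_model(c("chr1", "chr2"), c(1e5, 8e4))

tiny_genes <- function() {
  gene_table(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000, 60000, 30000),
    tts = c(15000, 50000, 36000)
  )
}

make_clone <- function(cpg, nonconv = integer(0), n_noncpg_c = 40,
                       id = "clone") {
  list(clone_id = id, cpg = as.logical(cpg), nonconv = as.integer(nonconv),
       n_noncpg_c = n_noncpg_c)
}

make_set <- function(clones, region_id = "r1", tissue = "liver") {
  bisulfite_clone_set(region_id, tissue, clones)
}

constant_track <- function(value = 2.5, chrom = "chr1", len = 1e5) {
  signal_track(chrom, 0, len, value)
}

# brute-force two-sided permutation p-value for the Mann-Whitney U statistic:
# counts label assignments at least as extreme (|U - mn/2|) as observed
mw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  nt <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_of(seq_len(n))
  center <- n * length(b) / 2
  combos <- utils::combn(nt, n)
  us <- apply(combos, 2, u_of)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# one full-length IAP straddling nothing, for architecture tests
one_full_length <- function(start = 20000, end = 27000, strand = "+",
                            chrom = "chr1", id = "erv1", ltr = 330) {
  erv_table(
    erv_id = id, family = "IAP", element_type = "full_length",
    chrom = chrom, start = start, end = end, strand = strand,
    ltr5_start = if (strand == "+") start else end - ltr,
    ltr5_end = if (strand == "+") start + ltr else end,
    ltr3_start = if (strand == "+") end - ltr else start,
    ltr3_end = if (strand == "+") end else start + ltr
  )
}
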