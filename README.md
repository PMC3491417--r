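# ervtools

Analysis toolkit for the epigenetic interplay between endogenous retrovirus
(ERV) insertions and nearby genes in a mammalian genome. Mouse IAP and
ETn/MusD retrotransposons carry strong regulatory sequences in their long
terminal repeats (LTRs) and are usually silenced by dense DNA methylation;
what happens when such a copy lands next to a gene promoter is a question
about selection (where are copies tolerated?), about methylation control
(is a near-promoter copy still methylated, and does its methylation spread
into the promoter?), and about chromatin boundaries (what sits in the
intervening sequence between copy and gene?).

The package implements that full analysis as reusable, tested components:

- **Depletion zones** (`simulate_expected`, `observed_distances`,
  `per_bin_tests`, `detect_threshold`): the expected distribution of
  ERV-to-TSS/TTS distances under random insertion is simulated (default
  10^6 points averaged over 3 replicates), binned (default 500 bp bins over
  0-10 kb), and compared bin-by-bin with the observed copy distribution
  using a Yates-corrected two-proportion test. The selection-zone boundary
  is the lower edge of the first non-significant bin.
- **Methylation quantification** (`medip_score`, `medip_call_table`,
  `bisulfite_qc`): MeDIP-qPCR enrichment `efficiency^(Ct_input - Ct_IP)`
  normalized by an in-vitro methylated spike-in, with scores `< 0.2` called
  unmethylated; bisulfite clone sets pass a strict `> 95%` conversion-rate
  filter and PCR-duplicate removal (a clone is kept if its CpG pattern *or*
  its conversion-error set is unique) before the methylated-CpG fraction is
  computed.
- **LTR architecture** (`proximal_ltr`, `orientation_cgi_table`,
  `compare_ltr_methylation`, `assess_spreading`, `filter_copies`): which
  LTR of a full-length element faces the gene TSS, whether 5'-proximal
  elements preferentially sit at CpG-island (CGI) promoters
  (two-proportion test), differential 5' vs 3' LTR methylation
  (Mann-Whitney U on per-clone fractions), and whether ERV methylation
  spreads into the promoter.
- **Chromatin profiles** (`intervening_region`, `extract_profile`,
  `orient_and_average`, `average_profiles`): orientation-normalized
  metagene averages of bedGraph signal (H3K4me3/CTCF/Input style) over the
  region between the copy and the TSS, with fixed ±400 bp (or ±200 bp)
  flanks, the TE always drawn on the left.
- **Synthetic data** (`sim_config`, `make_genome_and_genes`,
  `sample_insertions`, `simulate_bisulfite_clones`, `simulate_ct_table`,
  `simulate_signal_tracks`, `write_simulation`): generates every input the
  pipeline consumes, with ground-truth sidecars, so the whole analysis runs
  and is tested without any genome or track downloads.
- **Pipeline** (`run_config`, `run_pipeline`): config-driven end-to-end run
  with TSV report tables and a JSON run log carrying a config hash;
  deterministic under the seed.

## Statistics

The proportion-equality machinery is the Yates-corrected chi-square on the
contingency table (the construction that reproduces the reference values,
see below); the uncorrected variants are pooled z-tests. Mann-Whitney U is
exact (null distribution of U) for small tie-free samples with a
tie-corrected normal approximation otherwise; Spearman correlation uses
midranks with a t-approximation p-value. Stars follow the usual convention:
`***` p<0.001, `**` p<0.01, `*` p<0.05.

## Worked example

```r
library(ervtools)

# the two reference association statistics, from their reported counts:
# 20/25 5'-proximal IAPs at CGI promoters vs 15/31 3'-proximal
two_proportion_test(20, 25, 15, 31, continuity = TRUE)
#> two-proportion chi-square, Yates-corrected: statistic = 4.629, p = 0.03143 *
# 25 of 56 full-length IAPs with the 5' LTR nearest the TSS, against 0.5
one_proportion_test(25, 56, 0.5, continuity = TRUE)
#> one-proportion chi-square, Yates-corrected: statistic = 0.4464, p = 0.504

# end-to-end on a synthetic world: 2 chromosomes x 200 kb, 30 genes,
# 150 copies per family inserted under a hard 1.5 kb exclusion around TSSs
res <- run_pipeline(demo_config(seed = 1), "demo_out")
res$thresholds
#> ETn/MusD      IAP
#>     2000     1500
```

The detected depletion thresholds recover the simulated 1.5 kb exclusion
zone within one 500 bp bin. `demo_out/` then contains the report tables:
per-bin distribution tests (`distribution_*.tsv`), methylation calls and
their near/far summary (`methylation_calls.tsv`, `call_summary.tsv`),
bisulfite confirmations, the LTR orientation/CGI table
(`ltr_orientation.tsv`, `orientation_tests.tsv`), the spreading assessment
(`spreading.tsv`), mean chromatin profiles (`profile_*.tsv`, 100 points,
TE left) and `run_log.json`.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ervtools-cli.R", package="ervtools"))') \
    run-all --seed 1 --out demo_out --small
```

Subcommands: `simulate`, `erv-dist`, `meth-call`, `bisulfite-qc`,
`cgi-assoc`, `profile`, `run-all`.

## File formats

Genes and CGIs are BED6 / BED3 (0-based half-open; the strand decides which
edge of a gene is the TSS). ERVs use an extended-BED dialect, columns 1-6 as
BED6 plus:

| column | content |
|---|---|
| 7 | family (`ETn/MusD` or `IAP`) |
| 8 | element type (`solo` or `full_length`) |
| 9-10 | 5' LTR start, end (solo: the element span) |
| 11-12 | 3' LTR start, end (`.` for solo) |
| 13 | `fixed` or `polymorphic` |

Signal tracks are 4-column bedGraph (read/written via rtracklayer);
uncovered positions read as 0. MeDIP tables, expression states and all
reports are TSV.

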