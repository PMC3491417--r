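---
title: "Methods: ERV-gene epigenetic interplay analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERV-gene epigenetic interplay analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices behind
ervtools: what each stage assumes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open and a choice had to be made.

## Coordinates and distances

All coordinates are 0-based half-open (BED convention). TSS and TTS are
point positions at the strand-appropriate gene edge: on `+` the TSS is the
left edge, on `-` the right one. The distance between an interval and a
point is a gap: 0 when the point falls in `[start, end)` (and at `end`,
where the right gap is zero), otherwise `start - point` on the left and
`point - end` on the right. ERV-to-anchor distances use the nearest edge of
the whole element span — intervening-region lengths in the hundreds of base
pairs read naturally as edge-to-TSS gaps — and are unsigned;
upstream/inside/downstream is carried as a separate label derived from the
ERV midpoint relative to the gene body and strand. When two anchors are
equidistant the lower genomic coordinate wins, deterministically.

## The random-insertion null and depletion zones

The null model is positional: insertion points are uniform over the genome
(chromosome drawn proportional to length), distances to the nearest anchor
binned, and counts averaged over replicates (defaults: 10^6 points, 3
replicates). Observed copies are binned identically and each bin is tested
with the Yates-corrected two-proportion test: observed-in-bin out of all
observed copies versus `round(mean expected count)` out of the per-replicate
total. Rounding is negligible at null sizes of 10^5 and up. Two open
points were resolved as follows:

* *Denominators.* Proportions use **all** copies, including those beyond
  the binning window (default 500 bp bins over 0–10 kb; the bin width is
  the one implied by a half-kilobase-resolution readout and both are
  configurable). Using only in-window copies would couple the bins.
* *Threshold rule.* The depletion boundary is the lower edge of the
  literal first non-significant bin at α = 0.05 (the lowest star level). A
  first bin already non-significant yields threshold 0 with a
  `no_depletion` flag; all-significant yields the window maximum with an
  `all_significant` flag; significant bins beyond the threshold raise a
  `non_monotone` flag rather than changing the answer.

No multiple-testing correction is applied across bins by default, matching
the original single-test-per-bin readout; `per_bin_tests(bh = TRUE)` adds
Benjamini–Hochberg adjusted p-values for modern use.

## The statistics kernel

"Proportion equality test" is implemented as the chi-square test on the
contingency table with Yates continuity correction (the correction capped
so the corrected deviation stays non-negative, hence an exact match gives
p = 1). This reconstruction is validated, not assumed: it uniquely
reproduces both reference values — p = 0.03143 for 20/25 vs 15/31 CGI
association and p = 0.5 (to one decimal) for 25/56 vs 0.5 orientation —
which the acceptance suite asserts. All p-values are two-sided; the reference
values force that choice. The uncorrected variants are pooled z-tests.

Mann-Whitney U uses the exact null distribution of U when the pooled sample
is tie-free and `min(n, m) <= 12`; with ties an exact request falls back to
the tie-corrected normal approximation (0.5 continuity correction) with a
warning. The exact path is verified against brute-force permutation
enumeration in the tests. For LTR comparisons the unit of observation is
the per-clone methylated-CpG fraction. Spearman correlation uses midranks
and a t-approximation for its p-value; perfectly monotone input reports
p = 0 and constant input is flagged degenerate rather than guessed.

## Methylation quantification

MeDIP scores are `efficiency^(Ct_input − Ct_IP)` divided by the spike-in's
raw enrichment from the same batch. Where several spike fragments exist the
default combines them by averaging raw enrichments (`spike_combine =
"mean"`), with `"first"` available — the original normalization's exact
arithmetic over its two control fragments is not recorded. Scores below 0.2
are unmethylated. Bisulfite clones pass a **strict** `> 95%` conversion
filter (a clone at exactly 95.0% fails; clones with no assayable non-CpG
cytosine are flagged indeterminate and dropped, never silently passed).
Deduplication keeps a clone whose CpG pattern is unique *or* whose
conversion-error position set is unique; clones identical in both collapse
to the first seen. Identity is exact equality — no fuzzy matching. The
bisulfite methylated fraction reuses the 0.2 threshold for a
methylated/unmethylated call, a documented reconstruction for symmetry (the
original bisulfite calls were qualitative); the threshold is configurable.
Confirmation across methods is represented by reporting MeDIP and bisulfite
calls side by side plus their Spearman concordance, not as an algorithm.

## LTR architecture choices

* A CGI promoter is any CpG island overlapping the half-open window
  `[tss − 1500, tss + 1500)`.
* `proximal_ltr` measures each LTR's nearest-edge distance to the TSS;
  equidistant LTRs (element centered on the TSS) break the tie to the 5'
  LTR and carry a `tie` flag, since the original screen does not state
  whether ties occurred.
* Orientation-table distances are from the proximal LTR's edge, while the
  distribution stage uses whole-element edges; both conventions are
  deliberate and documented at their call sites.
* The "too many TSSs" exclusion is an explicit parameter (`max_tss`,
  default 3); no cutoff was stated, so the filter never hides its rule.
* Spreading is called when the ERV is methylated *and* the promoter's
  methylated-CpG fraction is ≥ 0.10. The negative cases in the source
  material sit at 0–1.4% promoter methylation and the one positive case is
  qualitative, so 0.10 is a reconstruction chosen to separate those regimes;
  it is configurable and the call is monotone in the promoter fraction with
  the boundary counted as spreading.

## Chromatin profiles

Rows are resampled metagene-style: the fixed-length flanks (default 400 bp,
with 200 bp as the fallback common minimum chosen by `common_flank` when a
region set cannot support 400) each receive a fixed quarter of the points
and the variable-length body is scaled into the rest, so a column means the
same thing across regions with different TE-TSS distances. Window values
are exact overlap-weighted means of the covering bedGraph intervals via a
cumulative integral (gaps read 0), so a constant track gives an exactly
constant row and refining the windows converges to per-base signal.
Orientation normalization reverses rows whose TE lies right of the TSS —
an involution, so a row and its mirrored duplicate average back to the row
exactly. Because whether averages were computed on raw or input-corrected
signal is unstated, both are emitted (`<mark>` and `<mark>_minus_input`).
ChIP-qPCR enrichment is `efficiency^(Ct_input − Ct_IP)` with no spike
normalization.

## The synthetic world

The generator emulates the statistical structure the analysis assumes, with
defaults chosen once as a realistic stated world:

| parameter | default | rationale |
|---|---|---|
| genome | 5 chromosomes × 2 Mb | large enough for ~50 kb gene spacing |
| genes | 200, 2–10 kb, strands random | non-overlapping jittered grid |
| CGI promoters | 60% of genes | mammalian promoter ballpark |
| tissues | liver, spleen, kidney, pancreas, testis | the panel used for expression-matched assays |
| copies | 150 per family; 15% full-length (~7 kb), solo LTR 330 bp | genome-like solo:full ratio and element sizes |
| selection | none / hard exclusion / logistic on TSS distance | emulates negative selection near genes |
| methylation | IAP 0.90, ETn/MusD 0.85 (±0.05); near-TSS ETn/MusD unmethylated (0.05) with probability 4/7 within 1.5 kb | heavy baseline methylation; the observed near-TSS hypomethylation rate among ETn/MusD |
| bisulfite | 10 clones × 20 CpGs, 40 non-CpG Cs, 2% conversion failure, 10% PCR duplicates | typical clone-sequencing depth and error regime |
| qPCR | efficiency 2.0, base Ct 25, noise 0.3 cycles, capture 1, floor 0.01 | efficiencies were 1.9–2.1; floor models nonspecific capture |
| signal | TSS peak 10 decaying over 500 bp at expressed genes; CTCF bumps midway in half the intervening regions; flat input 1 | promoter-mark and boundary-factor geometry |

One deliberate deviation: candidate insertions are points (the null is
positional), but the generator's *selection* step evaluates the retention
probability on the dressed element's nearest-edge distance — the quantity
the observed pipeline measures. Thinning the raw point and then dressing it
with a multi-kilobase element would leak element edges into the stated
exclusion zone, so a hard-exclusion world would not actually have an empty
zone. The null simulation itself remains point-based.

What the generator does **not** emulate: realistic sequence composition
(bisulfite references are deterministic `ACGT`/`TCTT` unit strings with
known CpG and non-CpG C positions), read-level alignment artifacts,
insertion-site sequence preference, element-length occupancy effects in the
null, and nucleosome-scale chromatin structure. A green end-to-end test
therefore establishes that the machinery recovers parameters from data with
the assumed structure — not that real ERV data meet those assumptions.

Determinism: every generator derives its stream from the config seed plus a
fixed per-generator offset (plus a string-derived offset per bisulfite
region), so the same config always reproduces byte-identical files while
different generators stay decorrelated.

## Calibration and verification design

The type-I calibration of the per-bin machinery compares an independent
point sample (no selection) against the point null, isolating the test
statistic: comparing interval-edge distances of length-dressed elements to
a point null carries a small structural enrichment that is a property of
the method itself, not of the statistic being calibrated. The H0
rejection-rate check for the uncorrected two-proportion test uses 4,000
replicates (scaled from 10,000 for runtime) with a tolerance computed for
the n actually used. Oracles stay independent of the paths they check:
exact Mann-Whitney is validated against `combn` enumeration, the proportion
tests against `stats::prop.test`, Spearman against `stats::cor.test`, and
generator recoveries against analytic binomial/uniform-coverage
expectations at 3σ.

## Known limitations

Solo elements carry their single LTR in the 5' slot by convention, so
5'/3' semantics apply only to full-length copies. The exact-U path refuses
ties rather than enumerating them (the fallback handles ties); genuinely
tiny tied samples get approximate p-values. The Spearman p-value is a
t-approximation, adequate at the n ≥ 25 used here but not exact for n < 10.
Expression states are binary per (gene, tissue); graded expression is out
of scope, as are GFF ingestion, liftover, RepeatMasker parsing, COBRA
quantification and allele-specific analysis beyond labels.
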