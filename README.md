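# isomirdisp

Concurrent profiling of canonical and non-canonical miRNA isoforms
(isomiRs) with race-stratified differential analysis and prognostic
signature discovery, for transcriptomics researchers studying how
end-shifted, non-templated-addition (NTA) and edited miRNA molecules
behave across patient groups — for example White (W) versus Black or
African American (B/AA) lung adenocarcinoma cohorts, where tumor/normal
expression trends and survival associations can differ by ancestry.

## What it computes

**isomiR calling.** Each small-RNA read is placed on a hairpin reference
by ungapped search (≤ 2 internal mismatches, ≤ 3 unmatched 3′-terminal
bases) and annotated relative to its mature miRNA: 5′/3′ end offsets,
templated-ness of 3′ extensions, NTA sequence, and SNVs on the canonical
mature coordinate system. SNVs are labeled EDITING only when they match a
catalogued A-to-I site (A→G, inosine reads as G), DNA_VARIANT for
catalogued SNPs/somatic mutations, UNKNOWN otherwise; calls with an
unannotated SNV in the first or last two aligned nucleotides are
discarded as ligation/sequencing artifacts. Calls are classified into 16
categories — shift class {no shift, 5′, 3′, both} × variant label {none,
DNA variant, editing, unknown} — and named deterministically:
`<mature>|5p<off5>|3p<off3>|nta:<seq|->|snv:<pos><ref>><alt>:<class>|-`.

**Quantification.** Features are kept when ⌊geometric-mean RPM⌋ > 1 (a
zero annihilates the geometric mean); normalization factors come from a
from-scratch implementation of the trimmed mean of M-values (TMM):
reference column by 75th-percentile closeness, doubly trimmed M/A (30% /
5%), inverse-variance-weighted mean of M, factors rescaled to geometric
mean 1. Downstream statistics use CPM on effective library sizes.

**Four-group differential analysis.** Kruskal–Wallis (mid-ranks, tie
correction, χ²₍₃₎ tail) across W(N), W(T), B/AA(N), B/AA(T), with
Benjamini–Hochberg FDR, and a six-trend classification of significant
features from the 4-tuple of group geometric means: monotonic
increasing/decreasing, up/down in both races, or opposite directions.

**Stratified gene-level DE.** Tumor samples are split at the first/third
quartiles of one isomiR's expression (e.g. an edited miR-151a-3p-like
molecule); genes pass ⌊geometric-mean FPKM⌋ > 1 and are tested Q1 vs Q3
with a negative-binomial exact test (conditional on the pooled sum;
dispersion 0 degenerates to the exact binomial test); significance is
p < 0.01 and |linear fold change| > 1.5, with hypergeometric
over-representation of gene sets in place of commercial pathway tools.

**Prognostic signatures.** Two-stage search per endpoint (OS/RFS) and
group: eligibility (≥ 10 patients per event type); a sweep of correlation
thresholds 0.60–0.80 (step 0.01) with greedy pruning; univariate Cox
(Efron ties, Newton–Raphson) keeping FDR < 0.05; multivariate Cox keeping
p < 0.05; recursive feature elimination under an L2 logistic estimator;
risk score = Σᵢ expᵢ·βᵢ with the univariate coefficients; median split
into high/low risk; Kaplan–Meier, log-rank, and ROC-AUC of the score
against the event flag. The signature maximizing AUC wins and can be
cross-applied to the other group (NOT_TESTABLE when a feature is absent
there).

**Synthetic data.** Every input can be generated with planted ground
truth: hairpin references with registered seed editing sites, reads with
known shifts/NTA/edits, four-group NB count matrices with known trends
and effect sizes, and proportional-hazards survival cohorts with known
prognostic features — the basis of the package's property-based tests.

## Worked example

```r
library(isomirdisp)

cfg   <- sim_config(seed = 17, n_hairpins = 10, read_depth = 5000)
ref   <- make_reference(cfg)                 # 10 hairpins, 22 variant sites
sim   <- simulate_reads(ref, cfg)
calls <- call_isomirs(sim$reads$read, ref)
kept  <- filter_terminal_unannotated(calls)$kept
isomir_category_table(kept, weights = kept$count)
#>          NONE DNA_VARIANT EDITING UNKNOWN
#> NO_SHIFT 1732           0     542       0
#> SHIFT5    494           0       0       0
#> SHIFT3   1728           0       0       0
#> SHIFT53   504           0       0       0
```

5,000 reads collapse to 322 distinct isomiRs; the 542 NO_SHIFT/EDITING
reads carry a seed A→G at a registered site, e.g.
`miR-sim-01-5p|5p0|3p0|nta:-|snv:3A>G:EDITING` (position 3 = seed edit).

```r
cm  <- simulate_count_matrix(cfg, n_null = 300, n_per_trend = 10)
res <- differential_isomirs(cm$matrix, cm$design)
sum(res$fdr < 0.05)                          # 61 of 360 rows
table(res$trend[res$fdr < 0.05])
#>     DOWN_BOTH DOWN_W_UP_BAA MONOTONIC_DEC MONOTONIC_INC       UP_BOTH UP_W_DOWN_BAA
#>            10            10            10            10            10            11
```

All 60 planted rows are recovered with their planted trend (one null row
slips in at FDR < 0.05, consistent with the nominal rate).

```r
sv  <- simulate_survival(cfg, n_features = 100, n_patients = 200,
                         true_betas = c(f010 = 0.8, f020 = -0.8))
sig <- signature_search(sv$expr, sv$records, "OS")
sig
#> isomiR OS signature: 2 features, threshold 0.60, AUC 0.866, log-rank p 1.42e-22
#>   features: f010, f020
```

The two planted prognostic features are recovered exactly; the risk-score
median split separates the Kaplan–Meier curves at log-rank p ≈ 1e-22.

## Command line

```sh
Rscript inst/cli/isomirdisp.R simulate --seed 17 --out simdir
Rscript inst/cli/isomirdisp.R call --reference simdir --reads simdir/reads.fastq --out calls
Rscript inst/cli/isomirdisp.R trends --counts counts.tsv --samples samples.tsv --alpha 0.05
Rscript inst/cli/isomirdisp.R signature --counts counts.tsv --samples samples.tsv --event os --group BAA
```

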