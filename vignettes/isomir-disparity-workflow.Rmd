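---
title: "Methods: isomiR profiling, trend analysis and prognostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR profiling, trend analysis and prognostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the parameters that matter, the numerical choices
made where the design was genuinely open, what the synthetic-data
generators do and do not emulate, and the known limitations. It states no
empirical result that the test suite does not itself compute.

## 1. The isomiR model

A mature miRNA is an interval on a hairpin precursor; an isomiR is any
read-supported variant of it. The package models four orthogonal event
types per read:

* **End shifts.** `offset5 > 0` means the 5′ end starts inside the mature
  (trimmed), `offset5 < 0` extended; `offset3 > 0` means the 3′ end runs
  past the mature end (extended), `offset3 < 0` trimmed. The literature
  does not fix a sign convention; this one is chosen and documented so
  that positive numbers at both ends mean "shorter 5′, longer 3′".
* **Templated vs non-templated 3′ bases.** A 3′ extension is templated
  where it equals the hairpin continuation. Trailing read bases that
  mismatch the hairpin are peeled off as non-templated additions (NTA);
  `templated3` is TRUE iff the read carries no NTA bases. A read can be
  3′-trimmed *and* carry NTA, in which case `offset3` is the net end
  displacement (possibly 0) while `nta_seq` is non-empty — such a read is
  still a 3′-shift isoform.
* **SNVs.** Internal mismatches are reported on the canonical mature
  coordinate system, so "position 3" always means seed position 3
  regardless of 5′ trimming. The seed is mature positions 2–7. A→G
  changes are labeled EDITING *only* when a catalogued A-to-I site exists
  at that position (sequence alone never proves editing); catalogued
  SNP/somatic matches become DNA_VARIANT; everything else is UNKNOWN.
* **Artifact filter.** Calls with ≥ 1 UNKNOWN SNV in the first two or
  last two nucleotides of the aligned read are discarded — terminal
  mismatches are the signature of linker-ligation imperfection and
  sequencing error. Annotated terminal SNVs are kept.

The 16 categories are the cross of shift class (NO_SHIFT, SHIFT5,
SHIFT3, SHIFT53) and variant label (NONE, DNA_VARIANT, EDITING,
UNKNOWN); a call whose SNVs carry several distinct labels contributes to
one cell per label, so category tables can sum to more than the number
of calls.

### Read placement

Placement is ungapped: the best alignment maximizes the matched prefix
length (the aligned region always ends on a matching base) subject to
`max_mismatches` internal mismatches (default 2) and at most `max_nta`
unmatched terminal bases (default 3) — defaults inherited from common
small-RNA-pipeline practice, not from any one tool's documentation. Ties
break deterministically: fewest mismatches, leftmost start, smallest
hairpin id. A placement is assigned to the unique mature it overlaps by
≥ 50% of the mature length; reads overlapping zero or two matures are
dropped and counted, never silently lost. Gapped alignment (insertions)
is out of the placement model: reads requiring gaps go unassigned.
Reads must be ≥ 15 nt, mirroring upstream quality-control conventions.

### Nomenclature

`<mature>|5p<offset5>|3p<offset3>|nta:<seq|->|snv:<pos><ref>><alt>:<class>[,...]|-`
is injective over (mature, offsets, NTA, SNV set) and parsed back exactly
by `parse_isomir_name()`; SNVs are ordered by position so the name is
canonical. The GFF writer stores the name plus the few transient fields
(aligned read positions of SNVs) needed for a lossless round trip.

## 2. Quantification choices

* **Expression filter.** A feature is expressed iff
  ⌊geometric mean RPM⌋ > 1 over the scoped samples. The geometric mean
  uses *no pseudocount*: one zero annihilates it. This is deliberate —
  the floor notation only makes sense on the raw geometric mean — and
  configurable only by pre-filtering the matrix yourself. The filter is
  applied to raw RPM (before TMM), since normalization factors do not
  change which features a laboratory would call detected.
* **TMM.** Implemented from scratch following the published estimator:
  reference column = 75th-percentile-of-scaled-counts closest to the
  column mean; M/A computed over features positive in both columns;
  two-sided trims of 30% on M and 5% on A (rank-based, so tie handling
  matches the reference implementation); inverse-variance weights;
  factors rescaled to geometric mean 1. A degenerate column (a single
  positive feature) gets factor 1 with a warning. Note: the precision
  weights depend on count scale, so the *weighted* factors are only
  asymptotically invariant to multiplying a column by a constant; exact
  scale invariance holds for `do_weighting = FALSE`. The test suite
  checks both, and checks weighted factors against an independent
  brute-force transcription and against edgeR to 1e-10.
* **Expression unit.** Downstream statistics use CPM on effective
  library sizes (library size × factor), log2 with pseudocount 1 where a
  log scale is needed. Per-group expressed sets are computed with
  per-group TMM; the four-group differential analysis normalizes all
  groups together.

## 3. Four-group trends

Kruskal–Wallis is computed on mid-ranks with the standard tie
correction; all-identical observations return H = 0, p = 1 rather than
0/0. BH adjustment is the classic step-up rule. Trends are classified
from the 4-tuple of group geometric means in precedence order: strictly
monotonic first, then per-race tumor-vs-normal directions. Strictness is
a choice — the trend taxonomy leaves equality undefined — so any
within-race tie yields UNCLASSIFIED rather than a silent coin flip. Only
features with FDR < α (default 0.05) receive a trend label. An
exhaustive 256-tuple comparison against an independently written rule
table guards the classifier.

## 4. Quartile stratification and gene-level DE

Quartile cuts use the linear-interpolation quantile definition (R type
7); membership is inclusive (≤ Q1 / ≥ Q3) because the boundary rule is
not otherwise fixed, and an error is raised when the split degenerates
(constant expression). The gene filter is the FPKM twin of the RPM rule.

The original workflow delegated gene-level testing to an external
package; this artifact substitutes a documented negative-binomial exact
test: conditional on the pooled sum, group sums are NB with common
dispersion (per-gene method-of-moments estimate
`max(0, (s² − μ)/μ²)` unless supplied), and the two-sided p-value sums
all outcomes no more likely than the observed one — the same
minimum-likelihood convention as the exact binomial test, to which the
NB test degenerates exactly at dispersion 0. Counts are TMM-normalized
within Q1 ∪ Q3 and scaled to the geometric-mean effective library before
testing (the exact test assumes comparable sizes); fold changes are
ratios of normalized group means with pseudocount 1, reported as signed
linear FC, and significance is the fixed conjunction p < 0.01 and
|FC| > 1.5. This is an approximation to a full GLM treatment, stated as
such; it is self-contained and exactly testable against enumeration.
Over-representation uses the hypergeometric upper tail with BH across
sets — an open substitute for commercial pathway software.

## 5. The prognostic cascade

Eligibility requires ≥ 10 patients per event type. The search then
sweeps correlation thresholds 0.60–0.80 in steps of 0.01:

1. **Pruning.** Pairwise |Pearson| on normalized expression; repeatedly
   remove the feature with the largest mean absolute correlation among
   those in any pair above the threshold (ties: lexicographically later
   name removed). Greediness and the mean-|r| removal criterion are
   design choices; only "remove highly correlated features" is given.
2. **Univariate Cox** per feature with BH across the pruned set; keep
   FDR < 0.05. Non-converging features (monotone likelihood, |β| > 20)
   are flagged and excluded with a warning.
3. **Multivariate Cox** on the survivors; keep p < 0.05.
4. **RFE** under an L2-regularized logistic regression of the event flag
   on standardized features (penalty λ = 1, intercept unpenalized),
   dropping the smallest-|coefficient| feature per round, over target
   sizes 3–15 by default (the retained-size range is swept and folded
   into the AUC selection because no fixed size is prescribed anywhere).
   The procedure is deterministic: no resampling, name-based
   tie-breaks.
5. **Scoring.** Risk score = Σᵢ expᵢ·βᵢ with the *univariate*
   coefficients (the workflow's explicit choice; multivariate
   coefficients are used only as a significance gate). Median split,
   score ≤ median → low risk. Log-rank χ²₍₁₎ and ROC-AUC of the score
   against the binary event flag. Time-dependent AUC would be a
   defensible alternative; plain ROC-AUC is chosen and documented since
   the AUC definition is otherwise unspecified.

The signature with the highest AUC wins; ties prefer fewer features,
then the smaller threshold. Cross-application to another cohort keeps
the original coefficients but re-splits at the target cohort's own
median; a signature is NOT_TESTABLE there if any feature is absent from
the target expression matrix.

**Cox numerics.** Efron tie handling; Newton–Raphson with step-halving;
convergence at gradient max-norm < 1e-8 (50 iterations max); Wald
p-values. Untied event times use the vectorized Breslow-equivalent
terms, tied times the full Efron correction. The test suite checks
coefficients and standard errors against an independent implementation
and the score equation to 1e-6 on every fit. One subtlety found during
testing: duplicating every patient *does* introduce ties, so the Efron
estimate moves slightly under duplication (exact invariance is a
Breslow property); the tests assert closeness, not identity.

## 6. What the synthetic data emulates — and what it does not

`make_reference()` builds random hairpins (60–90 nt) each carrying one
20–23 nt mature with ≥ 5 nt of flank (so ±2 nt templated shifts are
always observable) and ≥ 1 seed adenosine; every seed A is registered as
an editing site, and matures are rejection-sampled to occur exactly once
across all hairpins so placement is unambiguous by construction.
`simulate_reads()` draws categories from configurable fractions
(defaults: 35% canonical, 10/20/10% templated 5′/3′/both shifts of 1–2
nt, 15% NTA of 1–3 bases from {A, T} emulating adenylation/uridylation,
10% seed-edited), choosing each NTA base to differ from the hairpin
continuation so the planted annotation is recoverable, and records exact
per-read truth. `simulate_count_matrix()` plants trend-shaped NB means
(effect 4 by default, dispersion 0.1, base means log-uniform on
20–500 — typical bulk small-RNA count scales); monotonic trends use a
per-step factor of effect^(1/3) so the extreme groups span the stated
effect. `simulate_survival()` draws log-normal expression, exponential
times with hazard h₀·exp(Σβx), and independent uniform censoring on a
horizon calibrated by root-finding so the expected censored fraction
equals the target (censoring independent of covariates, so Cox
estimates stay unbiased).

A green test therefore establishes that the *algorithms* recover planted
structure under their own generative assumptions. It does not establish
robustness to what real sequencing adds: base-call errors and quality
variation (qualities are constant), multi-mapping across paralogous
miRNA families (matures are unique by construction), cross-mapping of
edited reads, adapter contamination, batch effects, overdispersion
heterogeneity, or the covariate imbalance of real cohorts.

## 7. Degenerate inputs and edge rules

* Zero library size, empty groups, constant features, all-zero count
  pairs, single-class labels: hard errors or defined returns (p = 1),
  never NaN propagation.
* Samples with a missing survival time or event flag are excluded from
  survival work but retained for expression; a partial endpoint
  (time without flag) degrades to missing with a warning.
* `signature_search` returns an explicit `no_signature` object when no
  threshold yields a surviving feature — distinguishable from an error.
* All generators are seed-deterministic; the search cascade contains no
  randomness at all, so identical inputs give identical signatures.

## 8. Known limitations

* The NB exact test with moment dispersion is less powerful and less
  calibrated than a fitted GLM with shrunken dispersions; it was chosen
  for exact testability and self-containment.
* Wald univariate Cox p-values on heavy-tailed expression are slightly
  anti-conservative in the extreme tail; with hundreds of features a
  small fraction of all-null cohorts will pass the FDR gate. Their
  signatures carry no out-of-sample signal (the acceptance suite checks
  cross-applied AUC ≈ 0.5 on independent null cohorts) — but training
  AUC after AUC-maximizing selection is always optimistic, and no
  internal correction for that selection is attempted.
* ROC-AUC against the raw event flag ignores censoring times; patients
  censored early count as non-events.
* Survival models are unadjusted for clinical covariates (stage, age,
  smoking) by design.
* The caller is reference-bounded: novel miRNA discovery and
  genome-wide mapping are out of scope.
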