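---
title: "From transition-ion intensities to candidate kidney-injury markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transition-ion intensities to candidate kidney-injury markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swathmarkers)
```

## The problem

In data-independent acquisition (SWATH) proteomics, the extraction software
exports peak areas of transition ions — fragment-ion signals of peptides —
for every sample and technical injection. Before any biology can be read off
these numbers, they must be normalized, cleaned of unreliable measurements,
and rolled up to protein-level areas. `swathmarkers` implements this
post-extraction stage for a three-group tissue study — healthy Baseline
animals, animals in acute decompensated heart failure (ADHF), and animals
after ~4 weeks of recovery — and the downstream discovery of candidate
protein markers of kidney injury, recovery, and long-term renal impairment.

## The quantification model

The ion table is long-format: one row per (protein, peptide, transition ion,
sample, injection) with a non-negative intensity. Missing (below-detection)
measurements are absent rows, never zeros. Four stages run in a fixed order:

1. **AUC normalization.** Every sample is scaled by (grand mean of sample
   totals) / (its own total), so all samples end at the same total ion
   intensity. Only measurements present in the table enter the totals; no
   imputation. This removes sample-level loading and injection-efficiency
   differences, under the assumption that total ion mass is comparable
   across samples — an assumption that fails when a large mass fraction of
   the proteome truly changes in one direction (see *Limitations*).
2. **Lower detection limit (LOD).** For each ion, the per-sample values (the
   mean over that sample's injections — the injection median is not yet
   computed at this stage) are pooled across all groups, and the limit is
   Q1 − 1.5 × IQR. A sample's measurements are removed when its value falls
   *strictly* below the limit; ties are retained, so a constant ion
   (IQR = 0) or an ion seen in a single sample is never excluded here.
   Quartiles use linear interpolation between closest order statistics
   (`stats::quantile` type 7), exposed in `qc_config()` so tests and
   implementation always share the rule.
3. **Replicate-CV filter.** Per (ion, sample), the percent CV over technical
   injections (requires ≥ 2). An ion is removed from the *entire dataset*
   when the fraction of samples with CV > 25% reaches 20%. The fraction's
   denominator counts biological samples where a CV is computable for that
   ion, which is robust to missingness; `qc_config(cv_denominator =
   "design")` switches to the full design size. Ions with no computable CV
   anywhere cannot be qualified and are excluded with their own reason code.
4. **Rollup.** Per (ion, sample) the median over surviving injections; ion
   medians sum to peptide areas; peptide areas sum to protein areas. A
   protein with no surviving ion in a sample yields a missing cell, not 0.

## Differential abundance and marker discovery

Three pairwise contrasts span the time course: Baseline vs HeartFailure
(`B_HF`), HeartFailure vs Recovery (`HF_R`), Baseline vs Recovery (`B_R`).
Per protein and contrast, an unequal-variance (Welch) test is run on the
untransformed areas — for two groups the Welch one-way ANOVA F is exactly
the squared Welch t, which the test suite verifies — and p-values are
Benjamini–Hochberg adjusted within each contrast as its own family.
Untestable proteins (< 2 non-missing areas in either group) are reported
with missing p-values and excluded from the family. Fold-changes are ratios
of arithmetic group means, reported as a magnitude ≥ 1 plus a direction
relative to the first-listed (reference) group. Testing on log areas is
available (`log_transform = TRUE`) but off by default, since the reported
fold-changes are ratio-scale summaries of the raw areas.

A (protein, contrast) pair *qualifies* at adjusted p < 0.05 and fold
magnitude ≥ 1.2 (`marker_thresholds()`). Qualified proteins are then
categorized by pattern with the precedence **long_term > recovery >
injury**:

* `long_term` — `B_R` qualifies: still different from Baseline after
  recovery;
* `recovery` — else `B_HF` and `HF_R` both qualify: altered in
  decompensation and restored afterwards;
* `injury` — else `B_HF` qualifies alone.

The precedence is a deliberate design choice: the published candidate table
lists a protein qualifying in both `B_HF` and `B_R` under the long-term
markers, and one qualifying in `B_HF` and `HF_R` under the recovery
markers, so pattern membership must be resolved in that order to reproduce
its assignments. A protein qualifying only in `HF_R` falls outside the
three-pattern scheme and receives no call.

Shortlisting keeps categorized proteins whose gene symbol appears in a
biofluid-detectability (secretome) set; a second join flags genes with a
prior AKI association. The packaged annotation files transcribe the
published annotations for the study's differential proteins; both loaders
accept user-supplied full exports (one symbol per line). Symbol matching is
exact after uppercasing; ovine `LOC…` identifiers pass through unmapped.

```{r fixture}
fx <- run_fixture_discovery()
cat(fx$summary, sep = "\n")
```

Thresholding the packaged table is done at its printed precision: adjusted
p-values there are rounded to two decimals, and a printed value equal to the
threshold (e.g. "0.05") denotes a true value below it, because membership of
the source table already required p < 0.05. Exact p-values computed by
`run_differential()` are always compared strictly.

## The synthetic-data generator

`generate_study()` emulates the study's design: group sizes 5/8/7, three
technical injections per sample, 1–6 peptides per protein and 1–6 transition
ions per peptide, protein base abundances log-uniform over four decades.
Each protein's signal is partitioned once into fixed peptide/ion shares
(gamma draws normalized to 1), held constant across samples so rollup is
comparable between groups. Noise is multiplicative log-normal throughout,
each term mean-1 so expected group intensity equals base abundance × true
fold-change:

* technical, between injections — default CV 10% (typical of SWATH
  replicate injections; study-condition runs below use 15%);
* biological, between animals — default CV 30%. The study reports no
  variance components, so this is a package choice of a realistic
  between-animal variability for tissue proteomics, set once and not tuned;
* a per-sample loading factor (default CV 25%) shared by all ions of a
  sample, which is what AUC normalization removes.

True effects are expressed as per-group mean multipliers (Baseline = 1).
Because the three pairwise fold-changes are not independent, `fc_map`
accepts effects for `B_HF` and `B_R` (or `HF_R` when `B_R` is absent) and
derives the third; the ground-truth table records all three implied
magnitudes and directions. Auto-spiked effects alternate up/down
(`fc_direction = "balanced"`) so total ion mass stays comparable between
groups — the regime AUC normalization presumes, and the regime of the study,
whose differential proteins moved in both directions. Below-detection
dropout removes whole ion-sample units with a probability concentrated in
the lowest quartile (`censor_quantile = 0.25`) of noise-free expected
intensities, emulating censoring at the detection limit.

Randomness uses one study-level stream plus per-protein sub-streams keyed on
the protein index, so enlarging a simulation leaves existing proteins'
data untouched.

What the generator does *not* emulate: retention-time drift, interference
between co-eluting peptides, correlated missingness across ions of a
peptide, heavy-tailed contamination, and shared biological factors between
proteins (co-regulation). Passing tests therefore demonstrate correctness of
the computations and calibration under a clean hierarchical log-normal
model, not performance on raw instrument output.

## Validation by simulation

Two simulation studies back the statistical claims, both at the study's
group sizes with 100 proteins and 15% technical CV (sizes chosen to give
stable estimates in minutes on one core; `analysis/03_fdr_power.R` runs
them):

* **Null error control** — 200 simulations with no true effects; the pooled
  proportion of significant (protein, contrast) tests estimates the
  false-discovery proportion under the complete null and stays below the
  0.05 target (BH under the complete null rejects very rarely, so the
  estimate is typically near zero).
* **Power** — 30 simulations per fold magnitude over {1.2, 1.5, 2.0, 2.6}
  (the published effect-size range), 10 spiked proteins each. Detection
  power is monotone increasing in the magnitude, and at 2.6-fold the spiked
  detection fraction strictly exceeds the null detection fraction.

## Renal physiology

`creatinine_clearance()` implements U × V / P (urine creatinine × urine flow
rate / plasma creatinine), unit-agnostic in the creatinine concentrations as
long as both use the same units; 24-hour collection volumes convert to
mL/min via `urine_flow_rate()` (divide by 1440). `serial_comparison()`
provides the two comparison modes used on such data: paired t within a
group between two study days (animals missing a pair member are dropped and
reported; all-zero differences give t = 0, p = 1; constant non-zero
differences are flagged degenerate rather than given a meaningless
statistic), and Welch independent t between groups at one day. The measured
physiological values of the animal study are not published as data, so
`simulate_physiology()` provides a clearly-synthetic stand-in with plausible
ovine magnitudes for exercising these operations and the marker–physiology
correlations (`correlate_with_physiology()`, Pearson by default, Spearman
optional; undefined correlations on constant vectors are NA).

## Numerical choices and degenerate inputs

* Quartile rule: type 7 (the common default), configurable 1–9.
* Strict `<` for below-LOD exclusion; values equal to the limit survive.
* A sample with zero total intensity is an error naming the sample, not a
  silent division by zero.
* Welch with both groups constant: equal means give statistic 0, p = 1;
  unequal means an infinite statistic, p = 0.
* BH families exclude missing p-values; family size m counts only testable
  proteins.
* Fold-change requires positive means; proteins violating this are excluded
  upstream.
* Below 2 complete pairs, paired comparisons error rather than report a
  1-degree-of-freedom artifact.

## Limitations

AUC normalization is compositional: if spiked-in changes are strongly
unbalanced in mass (e.g. the most abundant protein doubled), all other
proteins acquire an apparent opposite shift. This is a property of the
published normalization itself, visible in the simulator when spiking
one-directional effects into a small proteome. The Welch tests treat the
protein areas as the unit of analysis and ignore the support count (number
of contributing ions) per cell; no shrinkage or moderated variance is used,
matching the original analysis rather than maximizing power. Gene-symbol
joins are identity-based — no ortholog mapping beyond the symbol — so ovine
`LOC` identifiers never match human annotation sets.
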