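---
title: "Verifying biomarker candidates from LC-PRM data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying biomarker candidates from LC-PRM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmverify)
```

## The problem

Biomarker verification sits between discovery (long candidate lists, few
samples) and validation (few candidates, many samples). Targeted mass
spectrometry in parallel reaction monitoring (PRM) mode is the workhorse of
this phase: a quadrupole isolates each precursor, an orbitrap records all its
fragments, and quantification reads the integrated areas of the extracted ion
chromatograms (XICs) of the top product ions, normalized against spiked
stable-isotope-labeled (SIL, "heavy") copies of each target peptide.

`prmverify` implements the data-processing half of such a verification study
on endometrial-cancer candidates in uterine aspirates — a cohort of 20 tumor
and 18 control samples prepared in full-process duplicates, ~100 light/heavy
peptide pairs from 52 proteins, five product-ion XICs per precursor — as
composable, tested stages:

1. **Blood screen** — reject candidates whose MS1 signal tracks the volume
   fraction of whole blood spiked into split aliquots of two patients'
   aspirates.
2. **Spectral QC** — confirm peptide identity and flag interference with the
   cosine of the spectral contrast angle against a matrix-free reference
   acquisition; resolve failures by ion substitution or background
   imputation; drop peptides below the limit of detection (LOD) in most
   samples.
3. **Quantification** — light/heavy ratios from summed XIC areas, averaged
   over preparation duplicates, with duplicate CV% and sibling-peptide
   Pearson correlation as reproducibility metrics.
4. **Biomarker statistics** — Mann-Whitney U per peptide, Benjamini-Hochberg
   FDR across the panel, a fold-change/adjusted-p significance gate, and
   ROC/AUC with operating points.

Because the raw cohort is not redistributable, the package carries a
synthetic-data generator that emulates the study design from its published
summary statistics; every stage is exercised end to end on generated data.

## Spectral QC

For each (sample, replicate, peptide) the light and the heavy trace are each
scored against the reference profile $A_{ref}$:

$$\cos\theta = \frac{\sum_i A_{exp,i}\,A_{ref,i}}
  {\sqrt{\sum_i A_{exp,i}^2\,\sum_i A_{ref,i}^2}}.$$

A measurement is **accepted** when both cosines are strictly above the
threshold (default 0.98, matching the published rule) on all five ions. A
failing measurement enters a cascade:

* **Interference substitution.** A co-eluting contaminant inflates one
  fragment trace. We flag ions whose observed/reference intensity ratio
  exceeds `detectFactor` (default 3) times the trace's median such ratio —
  a scale-free criterion that works for dominant and minor ions alike. When
  exactly one ion is flagged, it is dropped from *both* labels (so the ratio
  stays commensurable) and the cosines are recomputed on the remaining four
  ions; never fewer than four ions are used. The published processing
  resolved "obvious" interferences manually; this rule is our automated
  counterpart, with the factor exposed in the configuration.
* **Background imputation.** If the summed light area falls below the LOD
  criterion (default `nIons * lodFloor`), the light areas are replaced by a
  background estimate — half the smallest non-censored area of that
  (peptide, ion) across the cohort, falling back to `lodFloor / 2` — and the
  measurement is flagged `below_lod`. This keeps the ratio matrix free of
  missing values, at the price of a floor-level ratio.
* Anything else is `unresolved` and excluded from averaging (the accepted
  replicate's value is kept when only one replicate fails).

A peptide is removed from the study when the fraction of samples below LOD
strictly exceeds 50%; a sample counts as below LOD only when *all* its
replicates are (the published unit, "samples", is ambiguous between sample
and replicate; we chose the sample reading). Both gates are strict
inequalities, as are the significance gates below.

An advisory `ms1TicCheck()` flags samples whose summed MS1 signal deviates
from the cohort median by more than *k* median absolute deviations — the
check that a constant protein amount was injected — without ever dropping a
sample.

A degenerate convention: an all-zero experimental vector returns
$\cos\theta = 0$ (avoiding 0/0) and is routed to the below-LOD branch.
Cosines of exactly proportional vectors are clamped at 1 against roundoff.

## Quantification

The ratio is $\sum_i L_i / \sum_i H_i$ over the ions retained by QC.
Duplicates are averaged arithmetically; CV% uses the $n-1$ standard
deviation (the convention is unstated in the source; the sample SD is the
field default) and is undefined for singletons. Sibling-peptide correlation
is Pearson on raw ratios across samples, for proteins monitored with exactly
two kept peptides; a switch enables log-scale correlation.

## Biomarker statistics

U counts tumor-over-control pairs with ties at one half (midranks); the
two-sided p-value is exact for combined $n \le 12$ without ties and the
tie-corrected normal approximation otherwise (delegated to
`stats::wilcox.test`). AUC is the rank statistic $U/(n_1 n_2)$. BH
adjustment is applied across all tested peptides jointly
(`stats::p.adjust`). Fold change defaults to the ratio of group medians —
consistent with the nonparametric test and quartile-based reporting; the
source never defines it, so a mean-ratio switch exists and exact fold-change
reproduction is not a goal. The reported sensitivity/specificity pair is the
Youden-optimal empirical operating point (ties resolved toward higher
specificity), with sensitivity also read at a fixed 95% specificity; both
sweep thresholds midway between adjacent pooled values.

## The synthetic cohort generator

The generator's role is to realize the *published study conditions*, not to
be tuned: 20 tumor / 18 control samples, two full-process replicates, five
ions per precursor, ~100 peptide pairs from 52 proteins.

* **Group distributions.** Ratios are positive and skewed and only group
  quartiles are printed, so each (peptide, group) gets the log-normal that
  reproduces its printed Q1–Q3 exactly:
  $\mu = (\ln Q_1 + \ln Q_3)/2$, $\sigma = (\ln Q_3 - \ln Q_1)/(2
  z_{0.75})$. The default panel combines the 48 published significant
  peptides (quartiles of 0.00 floored at 0.005, half the printed
  resolution) with 26 two-peptide null proteins (quartiles 0.4–1.2 in both
  groups, a plausible non-differential candidate) to reach the study scale.
* **Within-sample structure.** One true ratio per (sample, peptide), shared
  by both replicates — duplicates are preparations of the same aspirate.
  Sibling peptides of one protein share the sample's latent normal draw, so
  their ratios co-vary as surrogates of one protein do while keeping their
  own marginal quartiles.
* **Noise.** One multiplicative log-normal factor (unit mean, CV =
  `prepCv`, default 0.036 — the published average duplicate CV) per
  (sample, replicate, peptide, label), shared across the ions of a trace.
  Sharing preserves the ion profile shape, so cosine failures come from
  interference or censoring, not from per-ion jitter; real data add per-ion
  noise that this model deliberately omits.
* **Interference.** With probability `interferenceRate` (default 0.02) a
  light measurement has exactly one ion multiplied by `interferenceFactor`
  (default 20); coordinates are kept for recovery tests. Heavy traces are
  clean by default, as in practice the SIL mix is the quiet channel.
* **Censoring.** Areas below `lodFloor` (default 100, against a default
  summed heavy area of $10^6$ arbitrary units) stay in the table at their
  simulated value and are only *flagged*, so that background substitution is
  exercised in the QC stage, not hidden in the generator. Peptides with
  `detectable = FALSE` have their light signal pinned below the floor.
* **Blood series.** Two patients, fractions 0/0.10/0.20/0.40, duplicate
  injections. Blood-derived peptides follow $a(1 + g f)$ with gain $g > 0$;
  others either dilute as $a(1-f)$ or stay flat — both readings of the
  published "no effect or diminished levels" are implemented. The default
  screening panel is 129 candidates with 32 blood-derived, the published
  scale.
* **Reproducibility.** One top-level seed; each operation derives a
  deterministic sub-stream and restores the caller's RNG state. Identical
  seeds give byte-identical datasets.

What passing tests on generated data do **not** show: robustness to per-ion
noise, retention-time drift, chromatographic integration errors, or
non-log-normal abundance distributions. The generator produces areas
directly; there is no peak picking to get wrong upstream of it.

## Problem sizes and numerical choices

The test suite runs cohorts of 4–20 samples per group for logic checks, a
10,000-per-group draw for distribution-law convergence, 200 seeded cohorts
for the sibling-correlation and AUC-recovery checks, and 1,000-instance
oracle sweeps for the QC cascade, AUC and BH adjustment; the acceptance
script uses 500 cohorts of 20/18 per target. These sizes give Monte-Carlo
standard errors well inside the tolerances asserted (for the mean AUC over
500 cohorts, below 0.002).

Other numerics: strict `>`/`<` at every published gate; quartiles via the
default type-7 `quantile`; below-LOD ratios are background-derived rather
than missing; a zero heavy sum is an error (a corrupt internal standard is
not imputable); write/read of transition tables round-trips areas at full
double precision while report tables print 6 significant digits.

## Known limitations

* Fold-change definition is a choice (group-median ratio); printed FC values
  compatible with other definitions will not reproduce exactly.
* The interference detector assumes a *single* contaminated ion per
  measurement; two simultaneously interfered ions land in `unresolved`.
* The substitution cascade recomputes cosines on the remaining four ions;
  the alternative reading — replacing the trace with a sixth candidate ion
  from a longer list — would require XICs the input schema does not carry.
* BH adjustment is not idempotent (no step-up procedure is); re-adjusting an
  adjusted vector inflates it.
* P-values for tied data use the normal approximation; for the 20/18 design
  this is standard practice.

## A minimal run

```{r example, eval = FALSE}
cfg <- generatorConfig(seed = 1)
te <- simulateCohort(cfg)
res <- runPipeline(te, provenance(te)$library, outputDir = "prm_results")
res$log
head(res$results)
```
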