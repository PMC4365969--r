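---
title: "Models and methods behind clonecord"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonecord}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonecord)
```

`clonecord` compares somatic SNV call sets, allelic-imbalance profiles and
gene-panel copy-number calls between matched primary tumors and their liver
metastases. This vignette records the models, the parameters that matter,
and the design choices made where the procedure was genuinely open — the
package's own account of its science. No empirical claim here goes beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## The clonal model

Each patient trio is modeled as a truncal clone present in every tumor cell
of both tissues (cancer-cell fraction, CCF, equal to 1) plus private
subclones confined to one tissue at low CCF. With tumor purity $\rho$ (the
fraction of sampled cells that are tumor cells) and a heterozygous mutation
in a diploid region, the expected variant allele frequency is

$$\mathrm{E}[\mathrm{VAF}] = \frac{\rho\, c}{2},$$

implemented in `expected_vaf()`. Under linear progression the metastasis is
seeded late by the dominant primary clone: most variants are truncal, and
they run at high VAF, while private variants — subclones that arose after
seeding, in either tissue — run at low VAF. Under parallel progression the
two tissues diverge instead. The directional concordance percentages
(`patient_summary()`, `cohort_summary()`) and the shared-versus-private VAF
contrast (`vaf_group_stats()`) quantify exactly this distinction.

For a germline heterozygous allele inside a region of loss of
heterozygosity, the read fraction is a copy-weighted mixture of tumor cells
(one copy at the locus) and admixed normal cells (two copies). At purity
0.6 and CCF 1 an allele on the lost haplotype has expected frequency
$0.4/1.4 \approx 0.286$, i.e. a folded BAF deviation of about 0.214 — the
quantity the imbalance segmentation detects.

## The synthetic cohort

The generator (`sim_config()`, `simulate_cohort()`) emulates the study
conditions its analysis assumes; its defaults are fixed, not tuning knobs:

* **Depth**: negative binomial, mean 400, size 20 — matching ~385× median
  target coverage with a realistic spread (roughly 130–750×). Allele counts
  are Binomial(depth, expected VAF), strands split Binomial(·, 1/2).
* **Mutation load**: Poisson counts with means 9 truncal and 2.5 private
  per side (cohort medians near 8.5 / 2.5 / 2), truncal truncated below at
  3 so every trio is evaluable. One configurable POLE-ultramutant patient
  multiplies the means ~50-fold (the 741/872-variant analogue).
* **Purity**: uniform on (0.3, 0.7). The source cohort reports no per-sample
  purities, so this range is config-only and not validated against data.
* **Private CCF**: uniform on (0.1, 0.6), chosen once so private mean VAFs
  land near 10–13% at default purity while truncal VAFs sit several-fold
  higher.
* **Spectra**: truncal draws place 70% of mass on the four CpG>TpG channels
  (deamination/"aging"), private draws 70% on C>A plus non-CpG C>T, POLE
  draws 80% on TCT>TAT and TCG>TTG (5:3). Half the records are stored on
  the purine strand to exercise canonicalization.
* **Callers**: detection probability $\mathrm{plateau} \cdot
  \mathrm{logistic}((v - v_{50})/s)$ with $v_{50}$ = 0.10 (G, steep), 0.02
  (L), 0.03 with a lower plateau (M) — a consensus-style caller that misses
  low-VAF variants flanked by two sensitive callers, so the union is
  strictly more sensitive than any single caller.
* **Artifacts**: each false-positive class is constructed to trip exactly
  one named filter (strand-biased calls carry alt and ref reads on opposing
  strands; low-MQ calls draw MQ in 5–25; homopolymer calls sit beside a
  6-base run; and so on), making the filter tests targeted. Germline-like
  decoys (dbSNP without COSMIC) go to the sensitive callers and are removed
  by the database rule.
* **Het SNPs**: 2,000 per patient (observed median ≈ 1,986), BAF 0.5 in the
  normal; inside true imbalance regions the tumor BAF follows the LOH
  mixture above with the retained/lost haplotype chosen per SNP (the folded
  display makes the direction irrelevant).
* **Copy number**: an 87-gene panel plus invariant controls; tumor probe
  counts scale as $2 + \rho(\mathrm{CN} - 2)$ with log-normal noise
  (SD 0.05) — so low-purity gains can genuinely be missed, as on real
  panels.

What the simulator does **not** emulate: alignment and read-level error
(artifacts are drawn from annotation distributions, not from reads),
indels/MSI/translocations, locus-specific mappability, and correlated
caller errors. Passing tests therefore validate the analysis logic and its
statistical behavior under the stated generative model, not the upstream
callers themselves.

## Filters and their boundary conventions

Thresholds are as published, with the printed inequality directions taken
literally: mapping quality fails strictly below 30.0 (30.0 passes), depth
fails strictly below 5, strand bias fails strictly above −0.10, quality by
depth passes at exactly 3, "variant depth > 2" means at least 3 alt reads,
and normal depth passes at exactly 5. Three underdetermined points were
resolved as package conventions:

* **Strand-bias score.** No formula is published. We use
  $sb = |f_{alt} - f_{ref}| - 1$ with $f$ the forward-strand fraction of
  each read class (a class with no reads is treated as concordant), so
  perfectly concordant usage gives −1 and the rule $sb > -0.10$ removes
  only extreme divergence. Any alternative score can be supplied in the
  `sb` column; the filter only consumes the annotation.
* **Quality by depth.** The denominator is the tumor total depth.
* **Scope.** The five site filters and three somatic filters apply to the
  consensus-style caller's output (they belong to that pipeline); the
  consequence and dbSNP/COSMIC rules apply to the sensitive callers.
  The proximity rule removes *both* members of a close pair
  ($|pos_1 - pos_2| \le 5$), and the homopolymer rule counts the longest
  run containing or immediately adjacent to the variant position.

Manual read-level curation of unioned variants is replaced by a
reproducible surrogate: a unioned variant is dropped when its merged
alt-read count is below 2 (`curate_callset()`). This is a documented
divergence from interactive review.

## Concordance statistics and rendering

Variant identity is `(chrom, pos, ref, alt)`; presence in a tissue means
membership in that tissue's final filtered call set (no read-level rescue —
a conservative convention). Medians over an even number of patients are the
mean of the two central order statistics; percentages render half away from
zero at one decimal (so a cohort median of 81.65 prints 81.7, where R's
default half-to-even would print 81.6); group mean VAFs render as integer
percent, and the Total row's mean VAFs are unweighted means of the
per-patient means, matching the source table's dialect (a pooled
per-variant mean would be dominated by the ultramutant patient). Group
comparison tests are package conventions where the source names none:
Wilcoxon rank-sum for VAF groups (skewed distributions), Fisher's exact
test for recurrence enrichment, a two-proportion test for gene-subset
concordance; their p-values are descriptive, not reproduction targets.

## Allelic-imbalance segmentation

The source identifies broad regions visually from BAF plots; the package's
reproducible surrogate smooths folded deviations $|BAF - 0.5|$ with a
running median over 11 SNPs, calls maximal runs of at least 10 SNPs whose
smoothed deviation strictly exceeds 0.1, and merges runs separated by at
most 3 sub-threshold SNPs. All four parameters are exposed. The threshold
is strict, so a deviation sitting exactly at 0.1 never seeds a region, and
the footprint is monotone non-increasing in the threshold. At the default
depth the balanced-sampling noise of the deviation is ~0.02 after
smoothing, while clonal LOH at purity ≥ 0.35 exceeds 0.1, so the default
separates cleanly; very low purity LOH is genuinely undetectable — a known
limitation shared with the visual method. Heterozygous SNPs are selected by
a transparent interval rule (normal depth ≥ 20, BAF in [0.25, 0.75]) rather
than a genotype-likelihood test.

## Copy number

Probe counts divide by the geometric mean of invariant control probes and
anchor diploid at 2; the copy estimate is $2 \cdot$ tumor/normal. "Average
count above 3" is read as a strict gain threshold on this scale; the loss
threshold (< 1) is symmetric by construction and is *not* part of the
source procedure. Purity attenuates simulated estimates as
$2 + \rho(CN-2)$, and calls are made on the attenuated value.

## Numerical and degenerate-input conventions

Empty groups render `NA` (a patient with zero private variants has no
private mean VAF); a patient with two empty call sets is an error rather
than a silent row; zero tumor depth makes quality-by-depth undefined and is
an error; chromosomes with fewer SNPs than the smoothing window are skipped
with a message; two empty region sets give an undefined (NA) Jaccard. All
randomized code consumes R's RNG only, seeded once per cohort, so a fixed
seed and configuration reproduce every output file byte for byte.

## Problem sizes used by the checks

The test suite and acceptance script run the fixture-based reproductions at
the cohort's actual size (18 patients, 186 discovery variants) and the
simulation properties at sizes chosen for statistical resolution: 50
patients for truncal-fraction recovery (binomial SE ≈ 0.013 at n ≈ 1,000
pooled mutations, against a ±0.05 band), 8 patients with an elevated
artifact rate for filter-targeting rates, 800-SNP chromosomes for LOH
recovery, and an 8-patient default-condition pipeline for the cohort-level
summaries. Auxiliary tables (het SNPs, CN panel) are scaled down in
analyses that do not consume them.
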