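# clonecord

Comparative genomics of matched normal / primary-tumor / liver-metastasis
trios from high-depth targeted panel sequencing. `clonecord` answers the
question behind liver-limited metastatic colorectal cancer cohorts: does the
metastasis arise late from the dominant primary clone (linear progression,
most alterations shared) or early and independently (parallel progression,
divergent profiles)? It is written for cancer-genomics analysts who have
per-caller somatic SNV call sets, het-SNP pileups and gene-panel probe
counts per patient — or who want a fully synthetic but statistically
faithful cohort to validate such an analysis end to end.

## What it computes

* **Multi-caller integration** — three callers of differing low-VAF
  sensitivity (a consensus-style "G", and two sensitive callers "L", "M")
  are filtered and unioned with provenance. The G call sets pass five site
  filters (two variants within a 5-base window; homopolymer run > 5;
  strand-bias score > −0.10; mapping quality < 30.0; depth < 5) and three
  somatic filters (quality/depth ≥ 3; alt reads > 2; normal depth ≥ 5);
  the L/M call sets keep only missense/nonsense/splice SNVs not in dbSNP
  unless in COSMIC. Venn partitions, per-caller sensitivity against
  orthogonally validated variants, and TP/TN validation rates follow.
* **Shared/private concordance** — per patient, variants are *shared*
  (present in both tumors' final call sets, matched by `chrom:pos:ref:alt`)
  or *private*; the per-patient table reports counts, group mean VAFs and
  the two directional percentages, with cohort totals, medians and ranges.
  Under the purity/CCF model the expected VAF of a clonal diploid-het
  mutation is ρ·c/2, so truncal (shared) variants sit at high VAF and
  private subclones low — the quantitative signature of linear progression.
* **Mutation spectra** — 96-channel pyrimidine-centered trinucleotide
  spectra; CpG>TpG fraction (deamination/aging), TCT>TAT + TCG>TTG fraction
  (POLE ultramutator), cosine comparison of shared vs private spectra.
* **Allelic imbalance** — heterozygous germline SNPs (normal depth ≥ 20,
  BAF in [0.25, 0.75]) yield folded tumor BAF deviation tracks |BAF − 0.5|;
  running-median segmentation calls broad imbalance regions whose
  base-pair Jaccard measures primary–metastasis agreement.
* **Gene-panel copy number** — probe counts normalized against invariant
  controls (diploid ≈ 2), copy estimate 2·tumor/normal, gain called above 3
  (strict), loss below 1; per-trio call agreement.
* **Cohort simulator** — generates patient trios with a truncal clone
  (CCF 1) plus private subclones (CCF ~ U(0.1, 0.6)), ~400× negative
  binomial depth with binomial allele sampling, signature-skewed contexts
  per clone class, broad LOH regions, CN events, and three emulated callers
  with logistic VAF→sensitivity curves plus targeted artifact classes —
  every stage of the analysis is testable against known truth without any
  sequencing data.

## Worked example

```r
library(clonecord)

d <- tempfile("cohort")
clonecord_cli(c("simulate", "--outdir", d, "--patients", "8", "--seed", "42"))
for (s in c("filter", "integrate", "concord", "context", "baf", "cn", "report"))
  clonecord_cli(c(s, "--outdir", d))

rep <- readr::read_tsv(file.path(d, "report", "report.tsv"))
subset(rep, statistic %in% c("median_pct_primary_in_met",
                             "mean_vaf_shared_primary",
                             "mean_vaf_private_primary",
                             "cosine_shared_vs_private",
                             "median_baf_jaccard", "median_cn_agreement"))
```

On this seed the report contains:

```
statistic                    value
median_pct_primary_in_met  81.67
mean_vaf_shared_primary     0.2468
mean_vaf_private_primary    0.1105
median_baf_jaccard          0.6916
median_cn_agreement         0.9885
cosine_shared_vs_private    0.0245
```

Read: a median of ~82% of each simulated primary's variants recur in its
metastasis; shared variants run at ~25% mean VAF versus ~11% for private
ones (the truncal clone is clonal, private subclones are not); shared and
private mutation spectra are nearly orthogonal (cosine 0.02, CpG>TpG-rich
trunk versus C>A / non-CpG C>T branches); imbalance regions and copy-number
calls agree strongly between matched tumors. The same functions run on real
per-patient call sets: `read_callset()` ingests VCF, `patient_summary()` /
`cohort_summary()` build the concordance table, `write_table2_report()`
renders it.

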