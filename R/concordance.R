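#' Classify variants as shared or private between matched tumors
#'
#' Shared variants are those present in both the primary's and the
#' metastasis' final call sets (matched by identity key); the remainder are
#' private to one side. The partition is disjoint and exhaustive.
#'
#' @param primary_keys,met_keys Character vectors of variant keys (see
#'   [variant_key()]).
#' @return List with `shared`, `private_primary`, `private_met` key vectors.
#' @export
classify_shared_private <- function(primary_keys, met_keys) {
  primary_keys <- unique(primary_keys)
  met_keys <- unique(met_keys)
  if (length(primary_keys) == 0 && length(met_keys) == 0) {
    abort("no evaluable tumor: both call sets are empty")
  }
  list(
    shared = intersect(primary_keys, met_keys),
    private_primary = setdiff(primary_keys, met_keys),
    private_met = setdiff(met_keys, primary_keys)
  )
}

#' Per-patient concordance summary
#'
#' Builds one row of the per-patient concordance table: shared and private
#' counts, group mean VAFs in each tissue, the two directional concordance
#' percentages and the distinct-variant count. The row satisfies the count
#' identities `n_total_primary = n_shared + n_private_primary`,
#' `n_distinct = n_shared + n_private_primary + n_private_met` and
#' `pct_primary_in_met = 100 * n_shared / n_total_primary`.
#'
#' @param patient_id Patient label.
#' @param primary_calls,met_calls `variant_tbl`s (final filtered call set per
#'   tissue); VAF is taken from `tumor_alt / tumor_depth`, or from a `vaf`
#'   column when read counts are absent.
#' @param timing,prior_chemo Optional clinical labels carried through.
#' @return One-row tibble (a `ConcordanceRow`).
#' @export
patient_summary <- function(patient_id, primary_calls, met_calls,
                            timing = NA_character_, prior_chemo = NA) {
  vaf_of <- function(x) {
    if (nrow(x) == 0) return(numeric(0))
    if (all(c("tumor_alt", "tumor_depth") %in% names(x)) &&
        !anyNA(x$tumor_alt)) x$tumor_alt / x$tumor_depth
    else if ("vaf" %in% names(x)) x$vaf
    else rep(NA_real_, nrow(x))
  }
  pk <- variant_key(primary_calls)
  mk <- variant_key(met_calls)
  cls <- classify_shared_private(pk, mk)
  pv <- vaf_of(primary_calls); names(pv) <- pk
  mv <- vaf_of(met_calls); names(mv) <- mk
  mean_or_na <- function(v) if (length(v) == 0) NA_real_ else mean(v)

  n_sh <- length(cls$shared)
  n_pp <- length(cls$private_primary)
  n_pm <- length(cls$private_met)
  tibble(
    patient_id = patient_id, timing = timing, prior_chemo = prior_chemo,
    n_shared = n_sh,
    mean_vaf_shared_primary = mean_or_na(pv[cls$shared]),
    n_private_primary = n_pp,
    mean_vaf_private_primary = mean_or_na(pv[cls$private_primary]),
    n_total_primary = n_sh + n_pp,
    mean_vaf_total_primary = mean_or_na(pv),
    pct_primary_in_met = 100 * n_sh / (n_sh + n_pp),
    mean_vaf_shared_met = mean_or_na(mv[cls$shared]),
    n_private_met = n_pm,
    mean_vaf_private_met = mean_or_na(mv[cls$private_met]),
    n_total_met = n_sh + n_pm,
    mean_vaf_total_met = mean_or_na(mv),
    pct_met_in_primary = 100 * n_sh / (n_sh + n_pm),
    n_distinct = n_sh + n_pp + n_pm
  )
}

#' Cohort-level concordance summary
#'
#' Sums all count columns, and computes medians (for even n, the mean of the
#' two central order statistics) and ranges of the directional percentages,
#' the per-patient counts, and the per-tumor variant counts pooled over both
#' tissues (2n values for n patients).
#'
#' @param rows Tibble of [patient_summary()] rows.
#' @return List with `totals` (named numeric), `medians`, `ranges`, and
#'   `mean_vafs` (unweighted means of the per-patient group mean VAFs, the
#'   convention of the published per-patient table's Total row).
#' @export
cohort_summary <- function(rows) {
  if (nrow(rows) < 1) abort("cohort_summary: no rows")
  tot <- c(
    n_shared = sum(rows$n_shared),
    n_private_primary = sum(rows$n_private_primary),
    n_private_met = sum(rows$n_private_met),
    n_total_primary = sum(rows$n_total_primary),
    n_total_met = sum(rows$n_total_met),
    n_distinct = sum(rows$n_distinct),
    # SNV load over all tumor specimens (each tumor's call set counted once)
    n_total_snvs = sum(rows$n_total_primary) + sum(rows$n_total_met)
  )
  per_tumor <- c(rows$n_total_primary, rows$n_total_met)
  med <- c(
    pct_primary_in_met = median(rows$pct_primary_in_met),
    pct_met_in_primary = median(rows$pct_met_in_primary),
    n_distinct = median(rows$n_distinct),
    n_shared = median(rows$n_shared),
    n_private_primary = median(rows$n_private_primary),
    n_private_met = median(rows$n_private_met),
    per_tumor = median(per_tumor)
  )
  rng <- list(
    pct_primary_in_met = range(rows$pct_primary_in_met),
    pct_met_in_primary = range(rows$pct_met_in_primary),
    n_distinct = range(rows$n_distinct),
    n_shared = range(rows$n_shared),
    n_private_primary = range(rows$n_private_primary),
    n_private_met = range(rows$n_private_met),
    per_tumor = range(per_tumor)
  )
  mv <- c(
    shared_primary = mean(rows$mean_vaf_shared_primary, na.rm = TRUE),
    private_primary = mean(rows$mean_vaf_private_primary, na.rm = TRUE),
    total_primary = mean(rows$mean_vaf_total_primary, na.rm = TRUE),
    shared_met = mean(rows$mean_vaf_shared_met, na.rm = TRUE),
    private_met = mean(rows$mean_vaf_private_met, na.rm = TRUE),
    total_met = mean(rows$mean_vaf_total_met, na.rm = TRUE)
  )
  list(totals = tot, medians = med, ranges = rng, mean_vafs = mv)
}

#' Shared-versus-private VAF comparison within a tissue
#'
#' Arithmetic mean VAF of shared and private variants plus a two-sided
#' Wilcoxon rank-sum test (the distributional shapes are skewed, so a rank
#' test is used; the choice is a package convention).
#'
#' @param shared_vaf,private_vaf Numeric VAF vectors.
#' @return List with `mean_shared`, `mean_private`, `p_value` (`NA` when a
#'   group is empty).
#' @export
vaf_group_stats <- function(shared_vaf, private_vaf) {
  ms <- if (length(shared_vaf) == 0) NA_real_ else mean(shared_vaf)
  mp <- if (length(private_vaf) == 0) NA_real_ else mean(private_vaf)
  p <- if (length(shared_vaf) == 0 || length(private_vaf) == 0) NA_real_
  else suppressWarnings(wilcox.test(shared_vaf, private_vaf,
                                    alternative = "two.sided")$p.value)
  list(mean_shared = ms, mean_private = mp, p_value = p)
}

#' Recurrence analysis: are recurrently altered genes more often shared?
#'
#' A gene is recurrent when variants in it occur in at least two patients.
#' Tests, with a two-sided Fisher exact test on the 2x2 table of
#' (recurrent vs not) by (shared vs private), whether variants in recurrent
#' genes are enriched among shared variants.
#'
#' @param cohort_variants Tibble with `patient_id`, `gene` and `shared`
#'   (logical) per distinct variant.
#' @return List with `gene_counts` (per-gene patient counts and recurrent
#'   flag), `table` (the 2x2 contingency matrix), `odds_ratio`, `p_value`,
#'   and `pct_recurrent_shared`.
#' @export
recurrence_analysis <- function(cohort_variants) {
  gc <- cohort_variants |>
    distinct(.data$gene, .data$patient_id) |>
    dplyr::count(.data$gene, name = "n_patients") |>
    mutate(recurrent = .data$n_patients >= 2)
  cv <- left_join(cohort_variants, gc[, c("gene", "recurrent")], by = "gene")
  tab <- table(factor(cv$recurrent, levels = c(TRUE, FALSE)),
               factor(cv$shared, levels = c(TRUE, FALSE)),
               dnn = c("recurrent", "shared"))
  ft <- if (all(dim(tab) == c(2, 2)) && sum(tab) > 0 &&
            all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    fisher.test(tab, alternative = "two.sided")
  } else NULL
  n_rec <- sum(cv$recurrent)
  list(
    gene_counts = gc,
    table = tab,
    odds_ratio = if (is.null(ft)) NA_real_ else unname(ft$estimate),
    p_value = if (is.null(ft)) NA_real_ else ft$p.value,
    pct_recurrent_shared = if (n_rec == 0) NA_real_
    else 100 * sum(cv$recurrent & cv$shared) / n_rec
  )
}

#' Concordance of a gene subset versus its complement
#'
#' Among variants present in the metastasis, the percentage already present
#' in the primary, computed separately for a gene subset (e.g. significantly
#' mutated genes) and for all other genes, with a two-sided two-proportion
#' test.
#'
#' @param cohort_variants Tibble with `gene`, `shared` (logical) and
#'   `in_met` (logical: the variant is in the metastasis call set).
#' @param gene_list Character vector defining the subset; it must split the
#'   observed genes non-trivially.
#' @return List with `pct_subset`, `pct_complement`, counts and `p_value`.
#' @export
subset_concordance <- function(cohort_variants, gene_list) {
  if (length(gene_list) == 0) abort("empty gene list")
  met <- cohort_variants[cohort_variants$in_met, , drop = FALSE]
  in_sub <- met$gene %in% gene_list
  if (all(in_sub) || !any(in_sub)) {
    abort("gene list must split the metastasis variants into two non-empty groups")
  }
  k1 <- sum(met$shared[in_sub]); n1 <- sum(in_sub)
  k2 <- sum(met$shared[!in_sub]); n2 <- sum(!in_sub)
  p <- suppressWarnings(prop.test(c(k1, k2), c(n1, n2),
                                  alternative = "two.sided")$p.value)
  list(pct_subset = 100 * k1 / n1, pct_complement = 100 * k2 / n2,
       n_subset = n1, n_complement = n2, p_value = p)
}

#' Per-variant scatter data (VAF in primary vs metastasis)
#'
#' The data layer behind primary-versus-metastasis allele-frequency scatter
#' plots: every distinct variant of a patient with its VAF in each tissue
#' (0 when absent from that tissue's call set).
#'
#' @param patient_id Patient label.
#' @param primary_calls,met_calls Final `variant_tbl`s.
#' @return Tibble with `patient_id`, `key`, `vaf_primary`, `vaf_met`,
#'   `status`.
#' @export
vaf_scatter_data <- function(patient_id, primary_calls, met_calls) {
  pk <- variant_key(primary_calls)
  mk <- variant_key(met_calls)
  cls <- classify_shared_private(pk, mk)
  pv <- setNames(vaf(primary_calls), pk)
  mv <- setNames(vaf(met_calls), mk)
  keys <- c(cls$shared, cls$private_primary, cls$private_met)
  tibble(
    patient_id = patient_id, key = keys,
    vaf_primary = ifelse(keys %in% pk, pv[keys], 0),
    vaf_met = ifelse(keys %in% mk, mv[keys], 0),
    status = rep(c("shared", "private_primary", "private_met"),
                 c(length(cls$shared), length(cls$private_primary),
                   length(cls$private_met)))
  )
}
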