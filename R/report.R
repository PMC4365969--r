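#' Write the per-patient concordance report
#'
#' Renders [patient_summary()] rows in the published table's dialect: counts
#' with group mean VAFs as integer percent in parentheses (`"7 (31%)"`, `NA`
#' for empty groups), directional percentages to one decimal
#' (half-away-from-zero), a Total row (count sums; mean VAFs as unweighted
#' means of the per-patient means), and footnoted cohort medians.
#'
#' @param rows Tibble of [patient_summary()] rows (non-empty).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table2_report <- function(rows, path) {
  if (nrow(rows) == 0) abort("write_table2_report: no rows")
  cell <- function(n, v) sprintf("%d (%s%s)", n, fmt_pct_int(v),
                                 ifelse(is.na(v), "", "%"))
  body <- tibble(
    patient = rows$patient_id,
    timing = rows$timing,
    prior_chemo = ifelse(is.na(rows$prior_chemo), "NA",
                         ifelse(rows$prior_chemo, "yes", "no")),
    shared_primary = cell(rows$n_shared, rows$mean_vaf_shared_primary),
    unique_primary = cell(rows$n_private_primary, rows$mean_vaf_private_primary),
    total_primary = cell(rows$n_total_primary, rows$mean_vaf_total_primary),
    pct_primary_in_met = fmt_pct_1dp(rows$pct_primary_in_met),
    shared_met = cell(rows$n_shared, rows$mean_vaf_shared_met),
    unique_met = cell(rows$n_private_met, rows$mean_vaf_private_met),
    total_met = cell(rows$n_total_met, rows$mean_vaf_total_met),
    pct_met_in_primary = fmt_pct_1dp(rows$pct_met_in_primary),
    distinct = as.character(rows$n_distinct)
  )
  cs <- cohort_summary(rows)
  total <- tibble(
    patient = "Total", timing = "", prior_chemo = "",
    shared_primary = cell(cs$totals[["n_shared"]], cs$mean_vafs[["shared_primary"]]),
    unique_primary = cell(cs$totals[["n_private_primary"]],
                          cs$mean_vafs[["private_primary"]]),
    total_primary = cell(cs$totals[["n_total_primary"]],
                         cs$mean_vafs[["total_primary"]]),
    pct_primary_in_met = fmt_pct_1dp(100 * cs$totals[["n_shared"]] /
                                       cs$totals[["n_total_primary"]]),
    shared_met = cell(cs$totals[["n_shared"]], cs$mean_vafs[["shared_met"]]),
    unique_met = cell(cs$totals[["n_private_met"]], cs$mean_vafs[["private_met"]]),
    total_met = cell(cs$totals[["n_total_met"]], cs$mean_vafs[["total_met"]]),
    pct_met_in_primary = fmt_pct_1dp(100 * cs$totals[["n_shared"]] /
                                       cs$totals[["n_total_met"]]),
    distinct = as.character(cs$totals[["n_distinct"]])
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(body), collapse = "\t"), con)
  tab <- bind_rows(body, total)
  writeLines(apply(tab, 1, paste, collapse = "\t"), con)
  writeLines(sprintf(
    "# Cohort medians: %s%% of variants in the primary are found in the metastasis; %s%% of variants in the metastasis are found in the primary.",
    fmt_pct_1dp(cs$medians[["pct_primary_in_met"]]),
    fmt_pct_1dp(cs$medians[["pct_met_in_primary"]])), con)
  invisible(path)
}

#' Write the cohort summary as a key-value TSV
#'
#' @param cs A [cohort_summary()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(cs, path) {
  rows <- bind_rows(
    tibble(statistic = paste0("total_", names(cs$totals)),
           value = unname(cs$totals)),
    tibble(statistic = paste0("median_", names(cs$medians)),
           value = round_half_up(unname(cs$medians), 2)),
    bind_rows(lapply(names(cs$ranges), function(nm) {
      tibble(statistic = paste0(c("min_", "max_"), nm), value = cs$ranges[[nm]])
    })),
    tibble(statistic = paste0("mean_vaf_", names(cs$mean_vafs)),
           value = round_half_up(unname(cs$mean_vafs), 4))
  )
  readr::write_tsv(rows, path)
  invisible(path)
}
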