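#' Write a simulated cohort to a pipeline directory
#'
#' Lays out the on-disk interface the pipeline stages consume: per-patient
#' per-caller VCFs for both tumor tissues under `calls/`, plus the truth
#' table, het-SNP pileups, copy-number probe counts, true imbalance regions,
#' clinical labels and the configuration (`config.yaml`). All outputs are
#' plain text and byte-stable for a fixed configuration.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(file.path(outdir, "calls"), recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(unclass(cfg), file.path(outdir, "config.yaml"))

  clinical <- bind_rows(lapply(cohort$patients, function(p) {
    tibble(patient_id = p$patient_id, timing = p$timing,
           prior_chemo = p$prior_chemo, purity = round(p$purity, 4),
           pole = p$pole)
  }))
  readr::write_tsv(clinical, file.path(outdir, "clinical.tsv"))
  readr::write_tsv(cohort_truth(cohort), file.path(outdir, "truth.tsv"))

  pileups <- bind_rows(lapply(cohort$patients, function(p) {
    bind_rows(
      cbind(tibble(patient_id = p$patient_id, tissue = "normal"),
            p$normal_pileup),
      cbind(tibble(patient_id = p$patient_id, tissue = "primary"),
            p$primary_pileup),
      cbind(tibble(patient_id = p$patient_id, tissue = "met"), p$met_pileup)
    )
  }))
  readr::write_tsv(pileups, file.path(outdir, "pileups.tsv"))

  readr::write_tsv(
    bind_rows(lapply(cohort$patients, function(p) {
      cbind(tibble(patient_id = p$patient_id), p$imbalance_truth)
    })),
    file.path(outdir, "imbalance_truth.tsv"))
  readr::write_tsv(
    bind_rows(lapply(cohort$patients, function(p) {
      cbind(tibble(patient_id = p$patient_id), p$cn)
    })),
    file.path(outdir, "cn_counts.tsv"))

  for (p in cohort$patients) {
    for (tissue in c("primary", "met")) {
      calls <- if (tissue == "primary") p$primary_calls else p$met_calls
      for (cl in names(calls)) {
        write_callset(calls[[cl]], file.path(
          outdir, "calls", sprintf("%s_%s_%s.vcf", p$patient_id, tissue, cl)))
      }
    }
  }
  invisible(outdir)
}

pipeline_patients <- function(outdir) {
  readr::read_tsv(file.path(outdir, "clinical.tsv"), show_col_types = FALSE)
}

read_stage_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("missing pipeline input: ", path))
  suppressMessages(read_callset(path))
}

#' Pipeline stage: filter raw call sets
#'
#' Applies the site and somatic filters to the consensus-style caller's (G)
#' call sets, writing every variant with its FILTER column populated (PASS or
#' semicolon-joined reason codes), and the post-caller consequence/database
#' rules to the sensitive callers' (L, M) call sets, writing the retained
#' variants. Results go to `<outdir>/filtered/`.
#'
#' @param outdir Pipeline directory produced by [write_cohort()].
#' @param thresholds A [filter_thresholds()] list.
#' @return Invisible tibble of per-file input/output counts.
#' @export
run_filter_stage <- function(outdir, thresholds = filter_thresholds()) {
  dir.create(file.path(outdir, "filtered"), showWarnings = FALSE)
  files <- list.files(file.path(outdir, "calls"), pattern = "\\.vcf$")
  log <- list()
  for (f in files) {
    calls <- read_stage_vcf(file.path(outdir, "calls", f))
    caller <- sub("\\.vcf$", "", strsplit(f, "_")[[1]][3])
    out <- if (caller == "G") {
      if (nrow(calls) > 0) {
        apply_somatic_filters(apply_site_filters(calls, thresholds), thresholds)
      } else calls
    } else {
      kept <- post_caller_filters(calls)
      if (nrow(kept) > 0) kept$filter <- "PASS"
      kept
    }
    write_callset(out, file.path(outdir, "filtered", f))
    log[[f]] <- tibble(file = f, n_in = nrow(calls), n_out = nrow(out))
  }
  invisible(bind_rows(log))
}

#' Pipeline stage: integrate the three callers
#'
#' For each patient and tumor tissue, unions the filter-passing G calls with
#' the post-filtered L and M calls, applies the automated evidence curation,
#' and writes `<outdir>/integrated/<patient>_<tissue>.vcf` with caller
#' provenance in the CALLERS tag, plus the pooled Venn partition
#' (`integrated/venn.tsv`).
#'
#' @param outdir Pipeline directory.
#' @return Invisible pooled Venn tibble.
#' @export
run_integrate_stage <- function(outdir) {
  dir.create(file.path(outdir, "integrated"), showWarnings = FALSE)
  pats <- pipeline_patients(outdir)
  pooled <- list()
  for (pid in pats$patient_id) {
    for (tissue in c("primary", "met")) {
      sets <- lapply(c("G", "L", "M"), function(cl) {
        x <- read_stage_vcf(file.path(outdir, "filtered",
                                      sprintf("%s_%s_%s.vcf", pid, tissue, cl)))
        if (cl == "G" && nrow(x) > 0) x <- x[x$filter == "PASS", , drop = FALSE]
        x
      })
      ic <- curate_callset(union_callsets(sets[[1]], sets[[2]], sets[[3]]))
      if (nrow(ic) > 0) ic$filter <- "PASS"
      write_callset(ic, file.path(outdir, "integrated",
                                  sprintf("%s_%s.vcf", pid, tissue)))
      if (nrow(ic) > 0) {
        pooled[[paste(pid, tissue)]] <-
          ic[, c("chrom", "pos", "ref", "alt", "in_g", "in_l", "in_m")]
      }
    }
  }
  venn <- venn_partition(bind_rows(pooled))
  readr::write_tsv(venn, file.path(outdir, "integrated", "venn.tsv"))
  invisible(venn)
}

read_integrated <- function(outdir, pid, tissue) {
  x <- read_stage_vcf(file.path(outdir, "integrated",
                                sprintf("%s_%s.vcf", pid, tissue)))
  if (nrow(x) > 0) {
    x$in_g <- grepl("G", x$caller)
    x$in_l <- grepl("L", x$caller)
    x$in_m <- grepl("M", x$caller)
  }
  x
}

#' Pipeline stage: shared/private concordance
#'
#' Classifies each patient's integrated call sets into shared and private
#' variants and writes the per-patient report (`concord/table2.tsv`), the
#' cohort summary (`concord/cohort_summary.tsv`) and the per-variant
#' primary-versus-metastasis VAF scatter data (`concord/scatter.tsv`).
#'
#' @param outdir Pipeline directory.
#' @return Invisible tibble of [patient_summary()] rows.
#' @export
run_concord_stage <- function(outdir) {
  dir.create(file.path(outdir, "concord"), showWarnings = FALSE)
  pats <- pipeline_patients(outdir)
  rows <- list(); scatter <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    p_calls <- read_integrated(outdir, pid, "primary")
    m_calls <- read_integrated(outdir, pid, "met")
    rows[[pid]] <- patient_summary(pid, p_calls, m_calls,
                                   timing = pats$timing[i],
                                   prior_chemo = pats$prior_chemo[i])
    scatter[[pid]] <- vaf_scatter_data(pid, p_calls, m_calls)
  }
  rows <- bind_rows(rows)
  write_table2_report(rows, file.path(outdir, "concord", "table2.tsv"))
  write_cohort_summary(cohort_summary(rows),
                       file.path(outdir, "concord", "cohort_summary.tsv"))
  readr::write_tsv(bind_rows(scatter), file.path(outdir, "concord", "scatter.tsv"))
  invisible(rows)
}

#' Pipeline stage: mutational-context spectra
#'
#' Builds 96-channel spectra of shared versus private variants pooled over
#' the non-ultramutant patients, and the ultramutant patient's own spectrum
#' when present; writes the spectra and their comparison (cosine similarity,
#' CpG>TpG and POLE-channel fractions) under `<outdir>/context/`.
#'
#' @param outdir Pipeline directory.
#' @return Invisible list of spectra.
#' @export
run_context_stage <- function(outdir) {
  dir.create(file.path(outdir, "context"), showWarnings = FALSE)
  pats <- pipeline_patients(outdir)
  shared <- list(); private <- list(); pole <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    p_calls <- read_integrated(outdir, pid, "primary")
    m_calls <- read_integrated(outdir, pid, "met")
    if (nrow(p_calls) + nrow(m_calls) == 0) next
    cls <- classify_shared_private(variant_key(p_calls), variant_key(m_calls))
    if (isTRUE(pats$pole[i])) {
      pole[[pid]] <- bind_rows(p_calls,
                               m_calls[variant_key(m_calls) %in% cls$private_met, ])
    } else {
      shared[[pid]] <- p_calls[variant_key(p_calls) %in% cls$shared, ]
      private[[pid]] <- bind_rows(
        p_calls[variant_key(p_calls) %in% cls$private_primary, ],
        m_calls[variant_key(m_calls) %in% cls$private_met, ])
    }
  }
  sp_shared <- build_spectrum(bind_rows(shared))
  sp_private <- build_spectrum(bind_rows(private))
  write_spectrum(sp_shared, file.path(outdir, "context", "spectrum_shared.tsv"))
  write_spectrum(sp_private, file.path(outdir, "context", "spectrum_private.tsv"))
  cmp <- compare_spectra(sp_shared, sp_private)
  stats <- tibble(
    statistic = c("cosine_shared_vs_private", "cpg_tpg_shared",
                  "cpg_tpg_private", "pole_fraction_shared"),
    value = c(cmp$cosine, cpg_tpg_fraction(sp_shared),
              cpg_tpg_fraction(sp_private), pole_fraction(sp_shared))
  )
  sp_pole <- NULL
  if (length(pole) > 0) {
    sp_pole <- build_spectrum(bind_rows(pole))
    write_spectrum(sp_pole, file.path(outdir, "context", "spectrum_pole.tsv"))
    stats <- bind_rows(stats, tibble(statistic = "pole_fraction_ultramutant",
                                     value = pole_fraction(sp_pole)))
  }
  readr::write_tsv(stats, file.path(outdir, "context", "context_stats.tsv"))
  invisible(list(shared = sp_shared, private = sp_private, pole = sp_pole))
}

#' Pipeline stage: allelic imbalance
#'
#' Selects heterozygous SNPs from each patient's normal pileup, builds folded
#' BAF tracks for both tumor tissues, segments broad imbalance regions, and
#' writes per-tissue region BED files, the pooled track table and per-patient
#' primary-metastasis region concordance under `<outdir>/baf/`.
#'
#' @param outdir Pipeline directory.
#' @param window,dev_threshold,min_run,max_gap Segmentation parameters, see
#'   [segment_imbalance()].
#' @return Invisible concordance tibble.
#' @export
run_baf_stage <- function(outdir, window = 11L, dev_threshold = 0.1,
                          min_run = 10L, max_gap = 3L) {
  dir.create(file.path(outdir, "baf"), showWarnings = FALSE)
  pileups <- readr::read_tsv(file.path(outdir, "pileups.tsv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(chrom = "c"))
  conc <- list(); tracks <- list()
  for (pid in unique(pileups$patient_id)) {
    pp <- pileups[pileups$patient_id == pid, ]
    het <- call_het_snps(pp[pp$tissue == "normal", ])
    regions <- list()
    for (tissue in c("primary", "met")) {
      tr <- baf_track(het, pp[pp$tissue == tissue, ],
                      sample_label = paste(pid, tissue))
      seg <- segment_imbalance(tr, window, dev_threshold, min_run, max_gap)
      regions[[tissue]] <- seg
      write_intervals_bed(seg, file.path(outdir, "baf",
                                         sprintf("regions_%s_%s.bed", pid, tissue)))
      tracks[[paste(pid, tissue)]] <-
        cbind(tibble(patient_id = pid, tissue = tissue),
              tr[, c("chrom", "pos", "normal_baf", "tumor_baf", "deviation")])
    }
    rc <- region_concordance(regions$primary, regions$met)
    conc[[pid]] <- tibble(patient_id = pid, jaccard = rc$jaccard,
                          shared_bp = rc$shared_bp,
                          private_primary_bp = rc$private_primary_bp,
                          private_met_bp = rc$private_met_bp)
  }
  readr::write_tsv(bind_rows(tracks), file.path(outdir, "baf", "tracks.tsv"))
  conc <- bind_rows(conc)
  readr::write_tsv(conc, file.path(outdir, "baf", "baf_concordance.tsv"))
  invisible(conc)
}

#' Pipeline stage: gene-panel copy number
#'
#' Normalizes each patient's probe counts against the invariant controls,
#' calls gains and losses in both tumors against the matched normal, and
#' writes pooled calls plus per-patient concordance under `<outdir>/cn/`.
#'
#' @param outdir Pipeline directory.
#' @return Invisible concordance tibble.
#' @export
run_cn_stage <- function(outdir) {
  dir.create(file.path(outdir, "cn"), showWarnings = FALSE)
  counts <- readr::read_tsv(file.path(outdir, "cn_counts.tsv"),
                            show_col_types = FALSE)
  calls <- list(); conc <- list()
  for (pid in unique(counts$patient_id)) {
    prof <- cn_profile_patient(counts[counts$patient_id == pid, ])
    for (tissue in c("primary", "met")) {
      calls[[paste(pid, tissue)]] <-
        cbind(tibble(patient_id = pid, tissue = tissue), prof[[tissue]])
    }
    conc[[pid]] <- tibble(patient_id = pid,
                          agreement = prof$concordance$agreement,
                          n_discordant = nrow(prof$concordance$discordant))
  }
  readr::write_tsv(bind_rows(calls), file.path(outdir, "cn", "cn_calls.tsv"))
  conc <- bind_rows(conc)
  readr::write_tsv(conc, file.path(outdir, "cn", "cn_concordance.tsv"))
  invisible(conc)
}

#' Pipeline stage: cohort report
#'
#' Merges the stage summaries (concordance medians and totals, Venn
#' partition, median BAF-region Jaccard, median copy-number agreement) into
#' one key-value table at `<outdir>/report/report.tsv`.
#'
#' @param outdir Pipeline directory.
#' @return Invisible report tibble.
#' @export
run_report_stage <- function(outdir) {
  dir.create(file.path(outdir, "report"), showWarnings = FALSE)
  cs <- readr::read_tsv(file.path(outdir, "concord", "cohort_summary.tsv"),
                        show_col_types = FALSE)
  venn <- readr::read_tsv(file.path(outdir, "integrated", "venn.tsv"),
                          show_col_types = FALSE)
  baf <- readr::read_tsv(file.path(outdir, "baf", "baf_concordance.tsv"),
                         show_col_types = FALSE)
  cn <- readr::read_tsv(file.path(outdir, "cn", "cn_concordance.tsv"),
                        show_col_types = FALSE)
  ctx <- readr::read_tsv(file.path(outdir, "context", "context_stats.tsv"),
                         show_col_types = FALSE)
  report <- bind_rows(
    cs,
    tibble(statistic = paste0("venn_fraction_", venn$region),
           value = round_half_up(venn$fraction, 4)),
    tibble(statistic = "median_baf_jaccard",
           value = round_half_up(median(baf$jaccard, na.rm = TRUE), 4)),
    tibble(statistic = "median_cn_agreement",
           value = round_half_up(median(cn$agreement), 4)),
    ctx |> mutate(value = round_half_up(.data$value, 4))
  )
  readr::write_tsv(report, file.path(outdir, "report", "report.tsv"))
  invisible(report)
}

#' Command-line entry point
#'
#' Dispatches the pipeline stages: `simulate`, `filter`, `integrate`,
#' `concord`, `context`, `baf`, `cn`, `report`. `simulate` requires
#' `--outdir` plus optionally `--patients`, `--seed` and `--config` (a YAML
#' file of [sim_config()] keys); all other stages take `--outdir` and run on
#' the files a previous stage wrote. Rerunning any stage with the same seed
#' and configuration produces byte-identical outputs.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("simulate", "--outdir", "cohort", "--patients", "18", "--seed", "7")`.
#' @return Exit status 0, invisibly; errors raise conditions (the script
#'   wrapper maps them to a nonzero exit).
#' @export
clonecord_cli <- function(argv) {
  if (length(argv) < 1) abort("usage: clonecord <subcommand> --outdir DIR [...]")
  sub <- argv[1]
  opts <- list()
  i <- 2
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--") || i == length(argv)) {
      abort(paste0("malformed argument: ", key))
    }
    opts[[substring(key, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  outdir <- opts$outdir %||% abort("--outdir is required")
  stages <- c("simulate", "filter", "integrate", "concord", "context",
              "baf", "cn", "report")
  if (!sub %in% stages) {
    abort(paste0("unknown subcommand '", sub, "'; expected one of: ",
                 paste(stages, collapse = ", ")))
  }
  if (sub == "simulate") {
    keys <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
    keys <- keys[names(keys) %in% names(formals(sim_config))]
    if (!is.null(opts$patients)) keys$n_patients <- as.integer(opts$patients)
    if (!is.null(opts$seed)) keys$seed <- as.integer(opts$seed)
    cfg <- do.call(sim_config, keys)
    inform(sprintf("simulate: %d patients, seed %d", cfg$n_patients, cfg$seed))
    write_cohort(simulate_cohort(cfg), outdir)
  } else if (sub == "filter") {
    run_filter_stage(outdir)
  } else if (sub == "integrate") {
    run_integrate_stage(outdir)
  } else if (sub == "concord") {
    run_concord_stage(outdir)
  } else if (sub == "context") {
    run_context_stage(outdir)
  } else if (sub == "baf") {
    run_baf_stage(outdir)
  } else if (sub == "cn") {
    run_cn_stage(outdir)
  } else if (sub == "report") {
    run_report_stage(outdir)
  }
  invisible(0L)
}
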