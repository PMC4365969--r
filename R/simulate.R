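#' Configuration for the synthetic trio cohort generator
#'
#' Defaults emulate the study conditions of a targeted-panel comparison of
#' matched primary / liver-metastasis pairs: sequencing depth around 400x
#' (negative binomial), about 2,000 heterozygous germline SNPs per patient, a
#' truncal clone shared by both tumor tissues plus low-CCF private subclones
#' (count medians near 8.5 shared / 2.5 private per side), one optional POLE
#' ultramutant patient with ~50-fold mutation load, an 87-gene copy-number
#' panel, and three emulated callers of differing low-VAF sensitivity.
#'
#' @param n_patients Number of patient trios.
#' @param seed Integer seed; every downstream draw derives from it.
#' @param purity_range Tumor purity drawn uniformly from this interval.
#' @param depth_mean,depth_size Negative-binomial read-depth model (mean,
#'   dispersion `size`); applies to tumor loci and het-SNP pileups.
#' @param n_truncal_mean Mean truncal (shared) mutations per patient
#'   (Poisson, truncated below at 3 so every trio is evaluable).
#' @param n_private_primary_mean,n_private_met_mean Mean private mutation
#'   counts per side (Poisson).
#' @param private_ccf_range Cancer-cell fraction of private subclones,
#'   uniform on this interval; truncal CCF is 1.
#' @param pole_patient Index of the POLE ultramutant patient (`NA` for none).
#' @param pole_multiplier Mutation-load multiplier for the POLE patient.
#' @param truncal_cpg_mass Probability mass the truncal spectrum places on
#'   CpG>TpG channels.
#' @param private_mass Mass the private spectrum places on C>A plus non-CpG
#'   C>T channels.
#' @param pole_mass Mass the POLE spectrum places on TCT>TAT + TCG>TTG.
#' @param caller_profiles Named list (`G`, `L`, `M`) of detection profiles:
#'   `v50` (VAF of half-detection), `slope` (logistic scale), `plateau`
#'   (maximum detection probability). Defaults: a steep consensus-caller-like
#'   curve with half-detection at VAF 0.10 (G), a sensitive low-frequency
#'   caller at 0.02 (L), and a sensitive caller at 0.03 with a lower plateau
#'   (M).
#' @param artifact_rate Mean count (Poisson) of injected false-positive calls
#'   per artifact class per caller call set; each class is constructed to
#'   trip exactly one named filter.
#' @param perfect_callers If `TRUE`, every true mutation with at least one
#'   alt read is called by every caller and no artifacts are injected (used
#'   for parameter-recovery analyses).
#' @param n_het_snps Heterozygous germline SNPs per patient.
#' @param n_imbalance_shared Truncal allelic-imbalance regions per patient
#'   (present in both tumor tissues).
#' @param p_imbalance_private Probability of one extra private imbalance
#'   region per tumor tissue.
#' @param cn_panel_size,cn_controls Copy-number panel genes and invariant
#'   control probes.
#' @param cn_shared_gains,cn_shared_losses Truncal CN events per patient.
#' @param p_cn_private Probability of one private CN gain per tissue.
#' @param cn_base_count Expected probe count for a diploid gene.
#' @param cn_noise_sd Log-normal multiplicative noise SD on probe counts
#'   (0 disables noise).
#' @param n_genes,n_drivers Gene-pool sizes for mutation annotation;
#'   truncal mutations preferentially hit the driver subset.
#' @param p_driver_truncal,p_driver_private Probability a truncal / private
#'   mutation falls in the driver subset.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 18, seed = 1,
                       purity_range = c(0.3, 0.7),
                       depth_mean = 400, depth_size = 20,
                       n_truncal_mean = 9,
                       n_private_primary_mean = 2.5,
                       n_private_met_mean = 2.5,
                       private_ccf_range = c(0.1, 0.6),
                       pole_patient = 16, pole_multiplier = 50,
                       truncal_cpg_mass = 0.7, private_mass = 0.7,
                       pole_mass = 0.8,
                       caller_profiles = list(
                         G = list(v50 = 0.10, slope = 0.015, plateau = 0.999),
                         L = list(v50 = 0.02, slope = 0.008, plateau = 0.998),
                         M = list(v50 = 0.03, slope = 0.010, plateau = 0.990)
                       ),
                       artifact_rate = 2,
                       perfect_callers = FALSE,
                       n_het_snps = 2000,
                       n_imbalance_shared = 3, p_imbalance_private = 0.3,
                       cn_panel_size = 87, cn_controls = 10,
                       cn_shared_gains = 3, cn_shared_losses = 2,
                       p_cn_private = 0.3,
                       cn_base_count = 500, cn_noise_sd = 0.05,
                       n_genes = 400, n_drivers = 40,
                       p_driver_truncal = 0.5, p_driver_private = 0.1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_patients >= 1,
    all(cfg$purity_range > 0), all(cfg$purity_range <= 1),
    all(cfg$private_ccf_range > 0), all(cfg$private_ccf_range <= 1),
    cfg$depth_mean > 0, cfg$depth_size > 0, cfg$artifact_rate >= 0,
    cfg$n_het_snps >= 0, cfg$cn_panel_size >= 1, cfg$cn_controls >= 1
  )
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Expected allele fraction under the purity / CCF mixture model
#'
#' For a somatic heterozygous mutation in an otherwise diploid region the
#' expected VAF is `purity * ccf / 2` (one mutant copy among two in every
#' tumor cell carrying it, diluted by normal cells). The LOH states give the
#' expected B-allele frequency of a germline heterozygous allele inside a
#' region where the affected tumor cells carry a single copy at the locus:
#' read fractions are copy-weighted mixtures of tumor cells (1 copy) and
#' normal cells (2 copies). With purity 0.6 and CCF 1, an allele on the lost
#' haplotype has expected frequency 0.4/1.4 = 0.286.
#'
#' @param purity Tumor cell fraction of the sample, in `(0, 1]`.
#' @param ccf Cancer-cell fraction of the clone carrying the event, `(0, 1]`.
#' @param copy_state `"diploid_het"`, `"loh_retained"` (allele kept by the
#'   tumor) or `"loh_lost"` (allele lost).
#' @return Expected allele fraction in `[0, 1]`.
#' @export
expected_vaf <- function(purity, ccf, copy_state = "diploid_het") {
  stopifnot(all(purity > 0 & purity <= 1), all(ccf > 0 & ccf <= 1))
  n <- max(length(purity), length(ccf), length(copy_state))
  purity <- rep_len(purity, n); ccf <- rep_len(ccf, n)
  copy_state <- rep_len(copy_state, n)
  bad <- !copy_state %in% c("diploid_het", "loh_retained", "loh_lost")
  if (any(bad)) abort(paste0("invalid copy_state: ", copy_state[bad][1]))
  # locus copies: LOH tumor cells 1, unaffected tumor cells and normals 2
  total <- purity * (ccf + (1 - ccf) * 2) + (1 - purity) * 2
  out <- numeric(n)
  d <- copy_state == "diploid_het"
  out[d] <- (purity * ccf / 2)[d]
  r <- copy_state == "loh_retained"
  out[r] <- ((purity * 1 + (1 - purity) * 1) / total)[r]
  l <- copy_state == "loh_lost"
  out[l] <- ((purity * (1 - ccf) * 1 + (1 - purity) * 1) / total)[l]
  out
}

#' Sample read counts at loci
#'
#' Depth is negative-binomial; alt reads are binomial at the expected VAF;
#' strands split symmetrically. Uses the current RNG state, so results are
#' reproducible under `set.seed()`.
#'
#' @param evaf Expected VAF per locus, in `[0, 1]`.
#' @param depth_mean,depth_size Negative-binomial depth model.
#' @return Tibble with `tumor_depth`, `tumor_alt`, `alt_fw`, `alt_rv`,
#'   `ref_fw`, `ref_rv`.
#' @export
sample_read_counts <- function(evaf, depth_mean = 400, depth_size = 20) {
  stopifnot(all(evaf >= 0 & evaf <= 1))
  n <- length(evaf)
  depth <- pmax(1L, rnbinom(n, mu = depth_mean, size = depth_size))
  alt <- rbinom(n, depth, evaf)
  alt_fw <- rbinom(n, alt, 0.5)
  ref_fw <- rbinom(n, depth - alt, 0.5)
  tibble(tumor_depth = as.integer(depth), tumor_alt = as.integer(alt),
         alt_fw = as.integer(alt_fw), alt_rv = as.integer(alt - alt_fw),
         ref_fw = as.integer(ref_fw),
         ref_rv = as.integer(depth - alt - ref_fw))
}

# per-mode channel weights over the 96 canonical channels
channel_weights <- function(mode, config = sim_config()) {
  ch <- channels96()
  w <- numeric(96)
  if (mode == "truncal") {
    hot <- ch$sub == "C>T" & ch$threep == "G"            # 16 CpG>TpG channels
    w[hot] <- config$truncal_cpg_mass / sum(hot)
    w[!hot] <- (1 - config$truncal_cpg_mass) / sum(!hot)
  } else if (mode == "private") {
    hot <- ch$sub == "C>A" | (ch$sub == "C>T" & ch$threep != "G")
    w[hot] <- config$private_mass / sum(hot)
    w[!hot] <- (1 - config$private_mass) / sum(!hot)
  } else if (mode == "pole") {
    i1 <- ch$channel == "TCT>TAT"; i2 <- ch$channel == "TCG>TTG"
    w[i1] <- config$pole_mass * 5 / 8
    w[i2] <- config$pole_mass * 3 / 8
    rest <- !(i1 | i2)
    w[rest] <- (1 - config$pole_mass) / sum(rest)
  } else if (mode == "uniform") {
    w[] <- 1 / 96
  } else {
    abort(paste0("unknown spectrum mode: ", mode))
  }
  w
}

#' Draw substitution channels from a signature-skewed spectrum
#'
#' Modes: `"truncal"` concentrates mass on CpG>TpG channels (deamination /
#' 'aging' process), `"private"` on C>A plus non-CpG C>T channels, `"pole"`
#' on TCT>TAT and TCG>TTG (polymerase-epsilon ultramutator), `"uniform"`
#' over all 96 channels. Exact masses come from the configuration.
#'
#' @param mode Spectrum mode.
#' @param n Number of draws.
#' @param config A [sim_config()].
#' @return Tibble with `ref`, `alt`, `context`, `channel` (pyrimidine-centered
#'   encoding).
#' @export
draw_context_channel <- function(mode, n = 1, config = sim_config()) {
  ch <- channels96()
  w <- channel_weights(mode, config)
  idx <- sample.int(96, n, replace = TRUE, prob = w)
  tibble(
    ref = substr(ch$sub[idx], 1, 1),
    alt = substr(ch$sub[idx], 3, 3),
    context = ch$context[idx],
    channel = ch$channel[idx]
  )
}

# random reference window with no homopolymer run > max_run, center = ref
random_hp_window <- function(ref, width = 11, max_run = 5) {
  center <- (width + 1L) %/% 2L
  vapply(ref, function(r) {
    repeat {
      b <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
      b[center] <- r
      w <- paste(b, collapse = "")
      if (homopolymer_run_length(w, center) <= max_run) return(w)
    }
  }, character(1), USE.NAMES = FALSE)
}

# strand-flip mutation records to their reverse-complement encoding
flip_strand <- function(df, flip) {
  if (!any(flip)) return(df)
  df$ref[flip] <- revcomp3(df$ref[flip])
  df$alt[flip] <- revcomp3(df$alt[flip])
  df$context[flip] <- revcomp3(df$context[flip])
  df
}

# per-patient mutation truth table
draw_truth <- function(config, patient_id, purity, pole) {
  mult <- if (pole) config$pole_multiplier else 1
  n_tr <- max(3L, rpois(1, config$n_truncal_mean * mult))
  n_pp <- rpois(1, config$n_private_primary_mean * mult)
  n_pm <- rpois(1, config$n_private_met_mean * mult)
  n <- n_tr + n_pp + n_pm
  clone <- rep(c("truncal", "primary_private", "metastasis_private"),
               c(n_tr, n_pp, n_pm))
  ctx <- bind_rows(
    draw_context_channel(if (pole) "pole" else "truncal", n_tr, config),
    if (n_pp + n_pm > 0)
      draw_context_channel(if (pole) "pole" else "private", n_pp + n_pm, config)
  )
  is_driver <- runif(n) < ifelse(clone == "truncal",
                                 config$p_driver_truncal,
                                 config$p_driver_private)
  ccf_p <- ifelse(clone == "truncal", 1,
                  ifelse(clone == "primary_private",
                         runif(n, config$private_ccf_range[1],
                               config$private_ccf_range[2]), 0))
  ccf_m <- ifelse(clone == "truncal", 1,
                  ifelse(clone == "metastasis_private",
                         runif(n, config$private_ccf_range[1],
                               config$private_ccf_range[2]), 0))
  truth <- tibble(
    patient_id = patient_id,
    mutation_id = sprintf("%s_M%04d", patient_id, seq_len(n)),
    chrom = as.character(sample.int(22, n, replace = TRUE)),
    pos = sample.int(1e8L, n),
    ref = ctx$ref, alt = ctx$alt, context = ctx$context, channel = ctx$channel,
    gene = ifelse(is_driver,
                  sprintf("DRV%03d",
                          sample.int(config$n_drivers, n, replace = TRUE)),
                  sprintf("GEN%03d",
                          sample.int(config$n_genes, n, replace = TRUE))),
    clone = clone,
    consequence = sample(c("missense", "nonsense", "splice"), n,
                         replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    dbsnp = FALSE,
    cosmic = is_driver & runif(n) < 0.8,
    ccf_primary = ccf_p, ccf_met = ccf_m,
    evaf_primary = ifelse(ccf_p > 0,
                          expected_vaf(purity, pmax(ccf_p, 1e-12)), 0),
    evaf_met = ifelse(ccf_m > 0,
                      expected_vaf(purity, pmax(ccf_m, 1e-12)), 0),
    purity = purity
  )
  flip_strand(truth, runif(n) < 0.5)
}

# filter-clean annotation block for k calls
clean_annotations <- function(k, config) {
  tibble(
    mq = round(pmin(70, pmax(40, rnorm(k, 55, 4))), 2),
    qual_per_depth = round(runif(k, 8, 20), 2),
    normal_depth = as.integer(pmax(20L, rnbinom(k, mu = config$depth_mean,
                                                size = config$depth_size))),
    normal_alt = 0L
  )
}

#' Artifact classes targeted by the filter stage
#'
#' Site-level classes (injected into the consensus-style caller's output):
#' `strand_bias`, `mapping_quality`, `homopolymer`, `low_depth`,
#' `quality_depth`, `variant_depth`, `proximity`. The `germline` class
#' (known polymorphisms absent from COSMIC) is injected into the sensitive
#' callers' output and removed by the post-caller database rule.
#'
#' @return Character vector of class names.
#' @export
artifact_classes <- function() {
  c("strand_bias", "mapping_quality", "homopolymer", "low_depth",
    "quality_depth", "variant_depth", "proximity", "germline")
}

# one artifact call set of class `cls` (k seeds; proximity emits pairs)
artifact_calls <- function(cls, k, config) {
  if (k == 0) return(NULL)
  ctx <- draw_context_channel("uniform", k, config)
  dp <- pmax(30L, rnbinom(k, mu = config$depth_mean,
                          size = config$depth_size))
  ac <- pmax(3L, rbinom(k, dp, runif(k, 0.05, 0.25)))
  afw <- rbinom(k, ac, 0.5)
  rfw <- rbinom(k, dp - ac, 0.5)
  out <- cbind(
    tibble(
      chrom = as.character(sample.int(22, k, replace = TRUE)),
      pos = sample.int(1e8L, k),
      ref = ctx$ref, alt = ctx$alt, context = ctx$context,
      gene = sprintf("GEN%03d", sample.int(config$n_genes, k, replace = TRUE)),
      consequence = "missense", dbsnp = FALSE, cosmic = FALSE,
      tumor_depth = as.integer(dp), tumor_alt = as.integer(ac),
      alt_fw = as.integer(afw), alt_rv = as.integer(ac - afw),
      ref_fw = as.integer(rfw),
      ref_rv = as.integer(dp - ac - rfw),
      artifact = cls, truth_id = NA_character_
    ),
    clean_annotations(k, config)
  )
  out$hp_window <- random_hp_window(out$ref)
  fix_strands <- function(o) {
    o$alt_rv <- o$tumor_alt - o$alt_fw
    o$ref_fw <- as.integer(rbinom(nrow(o), o$tumor_depth - o$tumor_alt, 0.5))
    o$ref_rv <- o$tumor_depth - o$tumor_alt - o$ref_fw
    o
  }
  if (cls == "strand_bias") {
    # alt reads on one strand, ref reads on the other: maximal divergence
    flip <- runif(k) < 0.5
    out$alt_fw <- as.integer(ifelse(flip, out$tumor_alt, 0L))
    out$alt_rv <- out$tumor_alt - out$alt_fw
    out$ref_fw <- as.integer(ifelse(flip, 0L, out$tumor_depth - out$tumor_alt))
    out$ref_rv <- out$tumor_depth - out$tumor_alt - out$ref_fw
  } else if (cls == "mapping_quality") {
    out$mq <- round(runif(k, 5, 25), 2)
  } else if (cls == "homopolymer") {
    out$hp_window <- paste0("GC", strrep("A", 6), out$ref, "CG")
  } else if (cls == "low_depth") {
    out$tumor_depth <- as.integer(sample(3:4, k, replace = TRUE))
    out$tumor_alt <- out$tumor_depth
    out$alt_fw <- as.integer(rbinom(k, out$tumor_alt, 0.5))
    out <- fix_strands(out)
  } else if (cls == "quality_depth") {
    out$qual_per_depth <- round(runif(k, 0.5, 2.5), 2)
  } else if (cls == "variant_depth") {
    out$tumor_alt <- as.integer(sample(1:2, k, replace = TRUE))
    out$alt_fw <- as.integer(rbinom(k, out$tumor_alt, 0.5))
    out <- fix_strands(out)
  } else if (cls == "proximity") {
    mate <- out
    mate$pos <- mate$pos + sample.int(5, k, replace = TRUE)
    m2 <- draw_context_channel("uniform", k, config)
    mate$ref <- m2$ref; mate$alt <- m2$alt; mate$context <- m2$context
    mate$hp_window <- random_hp_window(mate$ref)
    out <- bind_rows(out, mate)
  } else if (cls == "germline") {
    out$dbsnp <- TRUE
    out$cosmic <- FALSE
  } else {
    abort(paste0("unknown artifact class: ", cls))
  }
  out
}

#' Emulate one variant caller on simulated sequencing evidence
#'
#' Each true mutation with sampled VAF `v` is called with probability
#' `plateau * plogis((v - v50) / slope)` (a monotone VAF-to-sensitivity
#' curve); false-positive calls from the requested artifact classes are
#' injected on top. Under `perfect_callers` every mutation with at least one
#' alt read is called and no artifacts are added.
#'
#' @param evidence Tibble of true mutations with sampled read counts and
#'   annotations (as built by [simulate_patient()]).
#' @param profile Caller profile (`v50`, `slope`, `plateau`).
#' @param config A [sim_config()].
#' @param classes Artifact classes to inject for this caller (see
#'   [artifact_classes()]).
#' @param caller_label Label stored in the `caller` column.
#' @return A `variant_tbl` with `truth_id` (mutation id; `NA` for artifacts)
#'   and `artifact` (class; `NA` for true calls) columns.
#' @export
emulate_caller <- function(evidence, profile, config = sim_config(),
                           classes = character(), caller_label = NA_character_) {
  v <- evidence$tumor_alt / evidence$tumor_depth
  p_det <- if (isTRUE(config$perfect_callers)) {
    as.numeric(evidence$tumor_alt > 0)
  } else {
    profile$plateau * stats::plogis((v - profile$v50) / profile$slope)
  }
  called <- evidence[runif(nrow(evidence)) < p_det, , drop = FALSE]
  if (nrow(called) > 0) called$artifact <- NA_character_

  fps <- if (!isTRUE(config$perfect_callers) && length(classes) > 0) {
    bind_rows(lapply(classes, function(cls) {
      artifact_calls(cls, rpois(1, config$artifact_rate), config)
    }))
  } else NULL

  out <- bind_rows(called, fps)
  if (nrow(out) == 0) {
    out <- variant_tbl()
    out$truth_id <- character(0)
    out$artifact <- character(0)
    out$hp_window <- character(0)
    return(out)
  }
  out$qual <- round(out$qual_per_depth * out$tumor_depth, 1)
  out$sb <- round(sb_score(out$alt_fw, out$alt_rv, out$ref_fw, out$ref_rv), 4)
  out$caller <- caller_label
  out$validation <- "untested"
  validate_variant_tbl(out)
}

# het-SNP pileups for a patient: normal plus both tumor tissues
draw_pileups <- function(config, purity, regions) {
  n <- config$n_het_snps
  chrom <- as.character(sort(sample.int(22, n, replace = TRUE)))
  pos <- integer(n)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- sort(sample.int(1e8L, length(idx)))
  }
  in_region <- function(tissue) {
    r <- regions[regions$tissue %in% c("both", tissue), , drop = FALSE]
    hit <- rep(FALSE, n)
    for (i in seq_len(nrow(r))) {
      hit <- hit | (chrom == r$chrom[i] & pos >= r$start[i] & pos <= r$end[i])
    }
    hit
  }
  tissue_pileup <- function(tissue) {
    if (is.null(tissue)) {
      ebaf <- rep(0.5, n)
    } else {
      hit <- in_region(tissue)
      state <- ifelse(hit,
                      ifelse(runif(n) < 0.5, "loh_retained", "loh_lost"),
                      "diploid_het")
      ebaf <- ifelse(hit, expected_vaf(purity, 1, state), 0.5)
    }
    depth <- pmax(1L, rnbinom(n, mu = config$depth_mean,
                              size = config$depth_size))
    alt <- rbinom(n, depth, ebaf)
    tibble(chrom = chrom, pos = pos, depth = as.integer(depth),
           alt = as.integer(alt), baf = alt / depth)
  }
  list(normal = tissue_pileup(NULL),
       primary = tissue_pileup("primary"),
       met = tissue_pileup("metastasis"))
}

# true allelic-imbalance regions (shared plus optional private per tissue)
draw_imbalance_regions <- function(config) {
  n_sh <- config$n_imbalance_shared
  mk <- function(k, tissue) {
    if (k == 0) return(NULL)
    chrom <- as.character(sample.int(22, k, replace = FALSE))
    start <- sample.int(5e7L, k)
    len <- as.integer(runif(k, 2e7, 4e7))
    tibble(chrom = chrom, start = start, end = start + len, tissue = tissue)
  }
  bind_rows(
    mk(n_sh, "both"),
    mk(rbinom(1, 1, config$p_imbalance_private), "primary"),
    mk(rbinom(1, 1, config$p_imbalance_private), "metastasis")
  )
}

# gene-panel copy-number truth and probe counts
draw_cn <- function(config, purity) {
  genes <- sprintf("CNG%03d", seq_len(config$cn_panel_size))
  ctrls <- sprintf("CTRL%02d", seq_len(config$cn_controls))
  cn_p <- cn_m <- rep(2, config$cn_panel_size)
  ev <- sample.int(config$cn_panel_size,
                   min(config$cn_panel_size,
                       config$cn_shared_gains + config$cn_shared_losses))
  gains <- head(ev, config$cn_shared_gains)
  losses <- tail(ev, config$cn_shared_losses)
  cn_p[gains] <- cn_m[gains] <- sample(4:6, length(gains), replace = TRUE)
  cn_p[losses] <- cn_m[losses] <- sample(0:1, length(losses), replace = TRUE)
  free <- setdiff(seq_len(config$cn_panel_size), ev)
  if (length(free) > 0 && runif(1) < config$p_cn_private) {
    i <- sample(free, 1); cn_p[i] <- sample(4:6, 1); free <- setdiff(free, i)
  }
  if (length(free) > 0 && runif(1) < config$p_cn_private) {
    i <- sample(free, 1); cn_m[i] <- sample(4:6, 1)
  }
  noise <- function(k) {
    if (config$cn_noise_sd <= 0) rep(1, k)
    else exp(rnorm(k, 0, config$cn_noise_sd))
  }
  att <- function(cn) 2 + purity * (cn - 2)  # purity-attenuated copy estimate
  count <- function(cnvec) {
    round(config$cn_base_count * cnvec / 2 * noise(length(cnvec)), 1)
  }
  tibble(
    gene = c(genes, ctrls),
    is_control = c(rep(FALSE, length(genes)), rep(TRUE, length(ctrls))),
    cn_true_primary = c(cn_p, rep(2, length(ctrls))),
    cn_true_met = c(cn_m, rep(2, length(ctrls))),
    count_normal = count(rep(2, length(genes) + length(ctrls))),
    count_primary = count(c(att(cn_p), rep(2, length(ctrls)))),
    count_met = count(c(att(cn_m), rep(2, length(ctrls))))
  )
}

#' Simulate one patient trio
#'
#' Draws the patient's purity, clonal truth (truncal plus private mutations
#' with signature-skewed contexts), sequencing evidence for both tumor
#' tissues, three emulated caller call sets per tissue, het-SNP pileups for
#' all three samples (shifted inside true allelic-imbalance regions), and
#' copy-number panel counts. Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @param patient_id Patient label, e.g. `"P01"`.
#' @param pole Whether this patient is the POLE ultramutant.
#' @return A `patient_trio` list: `patient_id`, `timing`, `prior_chemo`,
#'   `purity`, `pole`, `truth`, `primary_calls` / `met_calls` (lists of
#'   `variant_tbl` by caller `G`, `L`, `M`), pileups, `imbalance_truth`,
#'   `cn`.
#' @export
simulate_patient <- function(config, patient_id = "P01", pole = FALSE) {
  purity <- runif(1, config$purity_range[1], config$purity_range[2])
  truth <- draw_truth(config, patient_id, purity, pole)

  evidence_for <- function(tissue) {
    ccf <- if (tissue == "primary") truth$ccf_primary else truth$ccf_met
    evaf <- if (tissue == "primary") truth$evaf_primary else truth$evaf_met
    present <- ccf > 0
    ev <- truth[present, c("chrom", "pos", "ref", "alt", "context", "gene",
                           "consequence", "dbsnp", "cosmic", "mutation_id")]
    names(ev)[names(ev) == "mutation_id"] <- "truth_id"
    counts <- sample_read_counts(evaf[present], config$depth_mean,
                                 config$depth_size)
    ev <- cbind(ev, counts, clean_annotations(nrow(ev), config))
    ev$hp_window <- random_hp_window(ev$ref)
    as_tibble(ev)
  }

  call_tissue <- function(ev) {
    list(
      G = emulate_caller(ev, config$caller_profiles$G, config,
                         classes = setdiff(artifact_classes(), "germline"),
                         caller_label = "G"),
      L = emulate_caller(ev, config$caller_profiles$L, config,
                         classes = "germline", caller_label = "L"),
      M = emulate_caller(ev, config$caller_profiles$M, config,
                         classes = "germline", caller_label = "M")
    )
  }

  ev_p <- evidence_for("primary")
  ev_m <- evidence_for("met")
  regions <- draw_imbalance_regions(config)
  pileups <- draw_pileups(config, purity, regions)

  structure(list(
    patient_id = patient_id,
    timing = sample(c("synchronous", "metachronous"), 1, prob = c(14, 4)),
    prior_chemo = runif(1) < 0.5,
    purity = purity, pole = pole,
    truth = truth,
    primary_calls = call_tissue(ev_p),
    met_calls = call_tissue(ev_m),
    normal_pileup = pileups$normal,
    primary_pileup = pileups$primary,
    met_pileup = pileups$met,
    imbalance_truth = regions,
    cn = draw_cn(config, purity)
  ), class = "patient_trio")
}

#' Simulate a cohort of patient trios
#'
#' Seeds the RNG from `config$seed` and generates `config$n_patients` trios;
#' identical configuration yields identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort` with elements `patients` (list of
#'   `patient_trio`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(config$n_patients))
  patients <- lapply(seq_len(config$n_patients), function(i) {
    simulate_patient(config, ids[i],
                     pole = !is.na(config$pole_patient) &&
                       i == config$pole_patient)
  })
  structure(list(patients = patients, config = config), class = "sim_cohort")
}

#' Collect the cohort truth table
#'
#' @param cohort A [simulate_cohort()] result.
#' @return One tibble of all patients' mutation truth records.
#' @export
cohort_truth <- function(cohort) {
  bind_rows(lapply(cohort$patients, function(p) p$truth))
}

#' Export simulated loci as a reference FASTA
#'
#' Writes one short record per mutation locus containing its trinucleotide
#' context (synthetic sequence; for I/O interface testing only).
#'
#' @param truth A truth table from [cohort_truth()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_loci_fasta <- function(truth, path) {
  seqs <- Biostrings::DNAStringSet(truth$context)
  names(seqs) <- sprintf("%s|%s:%d", truth$mutation_id, truth$chrom, truth$pos)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
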