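#' Per-patient concordance fixture (18-trio cohort)
#'
#' Machine-readable transcription of the published per-patient summary of
#' unique and common variants: shared / private counts, group mean VAFs
#' (integer percent; `NA` where a group is empty) and the printed directional
#' percentages. Two printed percentages (patients 6 and 7, metastasis
#' direction) are internally inconsistent with the printed counts in the same
#' rows; the `pct_*_printed` columns keep the printed values while analysis
#' recomputes percentages from counts.
#'
#' @return Tibble of 18 rows.
#' @export
table2_fixture <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 13, byrow = TRUE)
    tibble(
      patient_id = sprintf("P%02d", as.integer(m[, 1])),
      timing = ifelse(m[, 2] == 1, "synchronous", "metachronous"),
      prior_chemo = m[, 3] == 1,
      n_shared = as.integer(m[, 4]),
      vaf_shared_primary = m[, 5] / 100,
      n_private_primary = as.integer(m[, 6]),
      vaf_private_primary = m[, 7] / 100,
      pct_primary_in_met_printed = m[, 8],
      vaf_shared_met = m[, 9] / 100,
      n_private_met = as.integer(m[, 10]),
      vaf_private_met = m[, 11] / 100,
      pct_met_in_primary_printed = m[, 12],
      n_distinct = as.integer(m[, 13])
    )
  }
  fx <- tribble_(
    #    syn chemo n_sh v_sh  n_pp v_pp   pct_pm  v_shm n_pm v_pm   pct_mp  dist
    1,   1,  1,    7,  31,    6,   5,    53.8,   47,   2,  18,    77.8,   15,
    2,   1,  0,   11,  29,    1,   3,    91.7,   42,   0,  NA,   100.0,   12,
    3,   1,  0,   10,  53,    0,  NA,   100.0,   32,   2,  15,    83.3,   12,
    4,   1,  1,    9,   9,    3,   8,    75.0,   33,   1,   3,    90.0,   13,
    5,   0,  1,   11,  32,    3,  14,    78.6,   37,   2,  21,    84.6,   16,
    6,   1,  0,   10,  21,    2,   5,    83.3,   35,   5,  12,    62.5,   17,
    7,   0,  1,    8,  46,    2,  22,    80.0,   64,   6,  13,    53.3,   16,
    8,   1,  0,    5,  71,    0,  NA,   100.0,   34,   1,  15,    83.3,    6,
    9,   1,  1,    4,  45,    0,  NA,   100.0,   29,   1,   7,    80.0,    5,
    10,  1,  1,    5,  51,    5,  10,    50.0,   60,   5,  15,    50.0,   15,
    11,  1,  1,    6,  54,    2,  16,    75.0,   41,   1,  19,    85.71,   9,
    12,  1,  0,    7,  37,    1,   4,    87.5,   39,   0,  NA,   100.0,    8,
    13,  0,  0,    6,  40,   10,   8,    37.5,   58,   3,  12,    66.67,  19,
    14,  1,  0,   11,  21,    5,   4,    68.75,  18,   7,  15,    61.11,  23,
    15,  1,  1,    3,  72,   14,  17,    17.65,  42,   0,  NA,   100.0,   17,
    16,  0,  0,  608,  12,  133,   9,    82.1,   20, 264,  17,    69.7, 1005,
    17,  1,  1,   10,  38,    1,   5,    90.91,  34,   4,   4,    71.43,  15,
    18,  1,  0,    9,  25,    3,  18,    75.0,   45,   1,   3,    90.0,   13
  )
  fx
}

#' Expand the concordance fixture into minimal synthetic call sets
#'
#' For each patient, generates `n_shared` variant keys placed in both
#' tissues' call sets and private keys in one, with every group's VAF
#' constant at the fixture's printed group mean (the table prints only group
#' means, so within-group spread is deliberately not reproduced). Running the
#' classification on the expansion reproduces every count and every
#' count-consistent percentage of the fixture.
#'
#' @param fixture A [table2_fixture()]-shaped tibble.
#' @return List of per-patient lists (`patient_id`, `timing`, `prior_chemo`,
#'   `primary_calls`, `met_calls`).
#' @export
expand_fixture <- function(fixture = table2_fixture()) {
  bad <- fixture$n_distinct !=
    fixture$n_shared + fixture$n_private_primary + fixture$n_private_met
  if (any(bad)) {
    abort(paste0("fixture count identity violated for patient ",
                 fixture$patient_id[bad][1]))
  }
  lapply(seq_len(nrow(fixture)), function(i) {
    fx <- fixture[i, ]
    mk_calls <- function(n, offset, vafs) {
      if (n == 0) return(cbind(variant_tbl(), tibble(vaf = numeric(0))))
      out <- variant_tbl(chrom = fx$patient_id, pos = offset + seq_len(n),
                         ref = "C", alt = "T")
      out$vaf <- vafs
      out
    }
    shared_p <- mk_calls(fx$n_shared, 0L, rep(fx$vaf_shared_primary, fx$n_shared))
    shared_m <- mk_calls(fx$n_shared, 0L, rep(fx$vaf_shared_met, fx$n_shared))
    priv_p <- mk_calls(fx$n_private_primary, 10000L,
                       rep(fx$vaf_private_primary, fx$n_private_primary))
    priv_m <- mk_calls(fx$n_private_met, 20000L,
                       rep(fx$vaf_private_met, fx$n_private_met))
    list(
      patient_id = fx$patient_id, timing = fx$timing,
      prior_chemo = fx$prior_chemo,
      primary_calls = bind_rows(shared_p, priv_p),
      met_calls = bind_rows(shared_m, priv_m)
    )
  })
}

#' Run the concordance analysis over an expanded fixture
#'
#' @param fixture A [table2_fixture()]-shaped tibble.
#' @return Tibble of [patient_summary()] rows, one per patient.
#' @export
fixture_concordance_rows <- function(fixture = table2_fixture()) {
  bind_rows(lapply(expand_fixture(fixture), function(p) {
    patient_summary(p$patient_id, p$primary_calls, p$met_calls,
                    timing = p$timing, prior_chemo = p$prior_chemo)
  }))
}

#' Orthogonal-validation fixture
#'
#' Re-encodes the published validation tallies: 186 discovered variants
#' (union of three callers; 136/156/109 per caller, 72 called by all three,
#' 43 by exactly one), of which 179 presence claims were assessed and 170
#' confirmed; and 35 absence claims (variants called in only one tissue,
#' checked in the other) of which 34 were confirmed. Caller bits among the
#' 170 confirmed variants reproduce the printed per-caller marginals
#' 129 / 149 / 96. Only the printed marginals are encoded; the full joint
#' distribution is a consistent reconstruction.
#'
#' @return List with `presence` (186-row tibble: key columns, presence bits
#'   `in_g`/`in_l`/`in_m`, `claim = "present"`, `validation`) and `absence`
#'   (35-row tibble: `claim = "absent"`, `validation`).
#' @export
validation_fixture <- function() {
  region <- rep(c("G", "L", "M", "GL", "GM", "LM", "GLM"),
                c(15, 24, 4, 38, 11, 22, 72))
  # non-confirmed counts per region chosen to hit the printed per-caller
  # confirmed marginals: statuses among the 16 non-confirmed records are
  # 9 failed validation, 6 without usable primers, 1 uninterpretable
  status <- rep("confirmed_present", length(region))
  pick <- function(reg, k) head(which(region == reg & status == "confirmed_present"), k)
  status[pick("G", 1)] <- "untested"
  status[pick("M", 1)] <- "untested"
  status[pick("GM", 2)] <- "untested"
  status[pick("LM", 2)] <- "untested"
  status[pick("LM", 1)] <- "uninterpretable"
  status[pick("G", 2)] <- "confirmed_absent"
  status[pick("M", 1)] <- "confirmed_absent"
  status[pick("GM", 2)] <- "confirmed_absent"
  status[pick("LM", 4)] <- "confirmed_absent"
  n <- length(region)
  presence <- tibble(
    chrom = "V", pos = seq_len(n), ref = "C", alt = "T",
    in_g = grepl("G", region), in_l = grepl("L", region),
    in_m = grepl("M", region),
    claim = "present", validation = status
  )
  absence <- tibble(
    chrom = "V", pos = 1000L + seq_len(35), ref = "C", alt = "T",
    claim = "absent",
    validation = c(rep("confirmed_absent", 34), "confirmed_present"),
    tissue_checked = rep(c("metastasis", "primary"), c(17, 18))
  )
  list(presence = presence, absence = absence)
}
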