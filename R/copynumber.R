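#' Normalize panel probe counts against invariant controls
#'
#' Divides each gene's raw count by the geometric mean of the invariant
#' control probes and scales so that a diploid gene's expected normalized
#' value is 2. Global multiplicative factors (library size, hybridization
#' efficiency) cancel.
#'
#' @param raw Named numeric vector of gene probe counts.
#' @param controls Numeric vector of invariant control counts (> 0).
#' @return Normalized counts on the copy-number scale (diploid ~ 2).
#' @export
normalize_counts <- function(raw, controls) {
  if (length(controls) == 0 || any(controls <= 0)) {
    abort("control counts must be positive")
  }
  2 * raw / geometric_mean(controls)
}

#' Call copy-number gains and losses from matched normalized counts
#'
#' The copy estimate is `2 * tumor / normal` per gene; a gene is a gain when
#' the estimate strictly exceeds `gain_threshold` (3 by default, i.e. an
#' average count above 3 on the diploid-normalized scale), a loss when it is
#' strictly below `loss_threshold`, and neutral otherwise.
#'
#' @param tumor_norm,normal_norm Named numeric vectors over the same genes
#'   (normalized counts from [normalize_counts()]).
#' @param gain_threshold Copy estimate above which a gain is called (strict).
#' @param loss_threshold Copy estimate below which a loss is called (strict).
#' @return Tibble (`gene`, `copy_estimate`, `call`), `call` in
#'   `{"loss", "neutral", "gain"}`.
#' @export
call_gain_loss <- function(tumor_norm, normal_norm,
                           gain_threshold = 3, loss_threshold = 1) {
  if (length(tumor_norm) != length(normal_norm) ||
      (!is.null(names(tumor_norm)) && !is.null(names(normal_norm)) &&
       !identical(names(tumor_norm), names(normal_norm)))) {
    abort("tumor and normal gene vectors must match")
  }
  if (any(normal_norm == 0)) abort("zero normalized count in normal")
  est <- unname(2 * tumor_norm / normal_norm)
  tibble(
    gene = names(tumor_norm) %||% as.character(seq_along(tumor_norm)),
    copy_estimate = est,
    call = ifelse(est > gain_threshold, "gain",
                  ifelse(est < loss_threshold, "loss", "neutral"))
  )
}

#' Copy-number concordance between matched tumors
#'
#' @param primary_calls,met_calls [call_gain_loss()] tibbles over the same
#'   gene panel.
#' @return List with `agreement` (fraction of genes with identical calls)
#'   and `discordant` (genes with both calls).
#' @export
cn_concordance <- function(primary_calls, met_calls) {
  if (!identical(primary_calls$gene, met_calls$gene)) {
    abort("gene panels differ between primary and metastasis")
  }
  same <- primary_calls$call == met_calls$call
  list(
    agreement = mean(same),
    discordant = tibble(
      gene = primary_calls$gene[!same],
      call_primary = primary_calls$call[!same],
      call_met = met_calls$call[!same]
    )
  )
}

#' Run the copy-number stage on one simulated patient
#'
#' Normalizes the three samples' probe counts against the control probes and
#' calls gains/losses in each tumor against the matched normal.
#'
#' @param cn A patient's `cn` tibble from [simulate_patient()].
#' @param gain_threshold,loss_threshold Passed to [call_gain_loss()].
#' @return List with `primary`, `met` call tibbles and `concordance`.
#' @export
cn_profile_patient <- function(cn, gain_threshold = 3, loss_threshold = 1) {
  genes <- cn[!cn$is_control, , drop = FALSE]
  ctrl <- cn[cn$is_control, , drop = FALSE]
  norm <- function(col) {
    setNames(normalize_counts(genes[[col]], ctrl[[col]]), genes$gene)
  }
  nn <- norm("count_normal")
  calls_p <- call_gain_loss(norm("count_primary"), nn,
                            gain_threshold, loss_threshold)
  calls_m <- call_gain_loss(norm("count_met"), nn,
                            gain_threshold, loss_threshold)
  list(primary = calls_p, met = calls_m,
       concordance = cn_concordance(calls_p, calls_m))
}
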