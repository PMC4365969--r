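#' Filter thresholds for site and somatic filtering
#'
#' Defaults encode the study's published rules: a candidate is removed when
#' another candidate lies within a 5-base window, when it sits in a
#' homopolymer run longer than 5 bases, when the strand-bias score exceeds
#' -0.10, when mapping quality is below 30.0, or when tumor depth is below 5.
#' A surviving candidate is somatic only when quality/depth is at least 3,
#' more than 2 reads support the alternate allele, and the matched normal has
#' depth of at least 5.
#'
#' @param proximity_window Window (bases) for the two-variants-in-proximity
#'   rule; both members of a close pair are removed.
#' @param homopolymer_max Longest tolerated homopolymer run containing or
#'   adjacent to the variant.
#' @param sb_max Maximum tolerated strand-bias score (fail when `sb > sb_max`).
#' @param mq_min Minimum mapping quality (fail when `mq < mq_min`, strict).
#' @param depth_min Minimum tumor depth (fail when `tumor_depth < depth_min`).
#' @param qd_min Minimum quality-by-depth (`qual / tumor_depth >= qd_min`).
#' @param alt_min_exclusive Alt-supporting reads must exceed this (strict
#'   `>`; the default 2 means at least 3 reads).
#' @param normal_depth_min Minimum depth in the matched normal (inclusive).
#' @return A named list of thresholds.
#' @export
filter_thresholds <- function(proximity_window = 5L, homopolymer_max = 5L,
                              sb_max = -0.10, mq_min = 30.0, depth_min = 5L,
                              qd_min = 3, alt_min_exclusive = 2L,
                              normal_depth_min = 5L) {
  list(proximity_window = proximity_window, homopolymer_max = homopolymer_max,
       sb_max = sb_max, mq_min = mq_min, depth_min = depth_min,
       qd_min = qd_min, alt_min_exclusive = alt_min_exclusive,
       normal_depth_min = normal_depth_min)
}

#' Longest homopolymer run touching a position
#'
#' Returns the length of the longest run of one identical base that contains
#' the given position or is immediately adjacent to it (a variant breaking a
#' long run is still error-prone, so flanking runs count).
#'
#' @param window Reference bases around the locus (single string, length >=
#'   11 recommended).
#' @param pos 1-based index of the variant base within `window`.
#' @return Integer run length.
#' @export
homopolymer_run_length <- function(window, pos = (nchar(window) + 1L) %/% 2L) {
  n <- nchar(window)
  if (n < 3) abort("homopolymer window too short")
  if (pos < 1 || pos > n) abort("position outside window")
  bases <- strsplit(window, "")[[1]]
  r <- rle(bases)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a run "touches" pos if it contains pos or abuts it on either side
  touching <- starts <= pos + 1L & ends >= pos - 1L
  max(r$lengths[touching])
}

#' Strand-bias score
#'
#' The published pipeline filters on a 'strand bias' score greater than
#' -0.10 without defining the score; this package uses
#' `sb = |f_alt - f_ref| - 1`, where `f_alt` and `f_ref` are the forward-strand
#' fractions of alt- and ref-supporting reads. Concordant strand usage gives
#' -1, extreme divergence approaches 0, so the rule `sb > -0.10` removes only
#' severely strand-biased calls. Any alternative score can be supplied
#' directly in the `sb` column.
#'
#' @param alt_fw,alt_rv,ref_fw,ref_rv Stranded read counts.
#' @return Numeric score in `[-1, 0]` (`NA` when a class has no reads).
#' @export
sb_score <- function(alt_fw, alt_rv, ref_fw, ref_rv) {
  f_alt <- alt_fw / (alt_fw + alt_rv)
  f_ref <- ref_fw / (ref_fw + ref_rv)
  # a read class with no reads carries no bias evidence: treat as concordant
  f_alt <- ifelse(is.nan(f_alt), ifelse(is.nan(f_ref), 0.5, f_ref), f_alt)
  f_ref <- ifelse(is.nan(f_ref), f_alt, f_ref)
  abs(f_alt - f_ref) - 1
}

#' Apply the five site-level filters
#'
#' Flags each variant with the site filters it fails: `window5` (another
#' candidate within `proximity_window` bases on the same chromosome; both
#' members fail), `homopolymer` (run > `homopolymer_max`, computed from the
#' `hp_window` column when present, else from `hp_run`), `strand_bias`
#' (`sb > sb_max`), `mapping_quality` (`mq < mq_min`, strict, so `mq == 30`
#' passes), and `depth` (`tumor_depth < depth_min`). All variants are kept in
#' the output with `site_pass` and a semicolon-joined `site_reasons` column;
#' the `filter` column is set to `PASS` or the reason codes.
#'
#' @param calls A `variant_tbl`; needs `mq`, `sb`, `tumor_depth`, and either
#'   `hp_window` (reference bases centered on the variant) or `hp_run`
#'   (precomputed run length). A missing homopolymer source is treated as run
#'   length 1.
#' @param thresholds A [filter_thresholds()] list.
#' @return `calls` with `site_pass`, `site_reasons` and `filter` columns.
#' @export
apply_site_filters <- function(calls, thresholds = filter_thresholds()) {
  calls <- validate_variant_tbl(calls)
  if (nrow(calls) == 0) {
    calls$site_pass <- logical(0)
    calls$site_reasons <- character(0)
    return(calls)
  }
  for (col in c("mq", "sb", "tumor_depth")) {
    if (!col %in% names(calls) || all(is.na(calls[[col]]))) {
      abort(paste0("apply_site_filters: annotation '", col, "' is missing"))
    }
    if (anyNA(calls[[col]])) {
      i <- which(is.na(calls[[col]]))[1]
      abort(sprintf("apply_site_filters: '%s' is NA for variant %s",
                    col, variant_key(calls)[i]))
    }
  }

  hp <- if ("hp_window" %in% names(calls) && !all(is.na(calls$hp_window))) {
    vapply(calls$hp_window, homopolymer_run_length, integer(1),
           USE.NAMES = FALSE)
  } else if ("hp_run" %in% names(calls)) {
    ifelse(is.na(calls$hp_run), 1L, calls$hp_run)
  } else {
    rep(1L, nrow(calls))
  }

  # proximity: any other candidate within the window on the same chromosome
  near <- vapply(seq_len(nrow(calls)), function(i) {
    same <- calls$chrom == calls$chrom[i]
    d <- abs(calls$pos - calls$pos[i])
    any(same & d <= thresholds$proximity_window & seq_len(nrow(calls)) != i)
  }, logical(1))

  fails <- cbind(
    window5 = near,
    homopolymer = hp > thresholds$homopolymer_max,
    strand_bias = calls$sb > thresholds$sb_max,
    mapping_quality = calls$mq < thresholds$mq_min,
    depth = calls$tumor_depth < thresholds$depth_min
  )
  reasons <- apply(fails, 1, function(f) paste(colnames(fails)[f], collapse = ";"))
  calls$site_pass <- !apply(fails, 1, any)
  calls$site_reasons <- reasons
  calls$filter <- ifelse(calls$site_pass, "PASS", reasons)
  calls
}

#' Apply the three somatic filters
#'
#' A site-passing variant is called somatic only when all of the following
#' hold: quality by depth `qual / tumor_depth >= qd_min`, alt-supporting
#' reads `tumor_alt > alt_min_exclusive`, and matched-normal depth
#' `normal_depth >= normal_depth_min`. Failure reasons are `quality_depth`,
#' `variant_depth` and `normal_depth`.
#'
#' @param calls A `variant_tbl` with `qual`, `tumor_alt`, `tumor_depth` and
#'   `normal_depth`.
#' @param thresholds A [filter_thresholds()] list.
#' @return `calls` with `somatic_pass`, `somatic_reasons` and updated
#'   `filter` columns.
#' @export
apply_somatic_filters <- function(calls, thresholds = filter_thresholds()) {
  calls <- validate_variant_tbl(calls)
  if (nrow(calls) == 0) {
    calls$somatic_pass <- logical(0)
    calls$somatic_reasons <- character(0)
    return(calls)
  }
  for (col in c("qual", "tumor_alt", "tumor_depth", "normal_depth")) {
    if (!col %in% names(calls) || anyNA(calls[[col]])) {
      abort(paste0("apply_somatic_filters: annotation '", col, "' is missing"))
    }
  }
  if (any(calls$tumor_depth == 0)) {
    abort("apply_somatic_filters: zero tumor depth (quality/depth undefined)")
  }
  fails <- cbind(
    quality_depth = calls$qual / calls$tumor_depth < thresholds$qd_min,
    variant_depth = calls$tumor_alt <= thresholds$alt_min_exclusive,
    normal_depth = calls$normal_depth < thresholds$normal_depth_min
  )
  reasons <- apply(fails, 1, function(f) paste(colnames(fails)[f], collapse = ";"))
  calls$somatic_pass <- !apply(fails, 1, any)
  calls$somatic_reasons <- reasons
  prev <- if ("filter" %in% names(calls)) calls$filter else rep(NA, nrow(calls))
  prev <- ifelse(is.na(prev) | prev == "PASS" | prev == ".", "", prev)
  combined <- ifelse(reasons == "", prev,
                     ifelse(prev == "", reasons, paste(prev, reasons, sep = ";")))
  calls$filter <- ifelse(combined == "", "PASS", combined)
  calls
}

#' Post-caller consequence and database filters
#'
#' The post-processing applied to the sensitive callers' output: keep only
#' missense, nonsense and splice-site SNVs; remove dbSNP members unless they
#' are also in COSMIC; and, when the matched normal's call set is supplied,
#' remove tumor calls also present in the normal (only variants unique to the
#' tumor sample are somatic).
#'
#' @param calls A `variant_tbl` with `consequence`, `dbsnp`, `cosmic`.
#' @param normal_keys Optional character vector of variant keys called in the
#'   matched normal.
#' @return The retained subset of `calls`.
#' @export
post_caller_filters <- function(calls, normal_keys = NULL) {
  calls <- validate_variant_tbl(calls)
  if (nrow(calls) == 0) return(calls)
  for (col in c("consequence", "dbsnp", "cosmic")) {
    if (!col %in% names(calls) || anyNA(calls[[col]])) {
      abort(paste0("post_caller_filters: annotation '", col, "' is missing"))
    }
  }
  keep <- calls$consequence %in% c("missense", "nonsense", "splice") &
    (!calls$dbsnp | calls$cosmic)
  if (!is.null(normal_keys)) {
    keep <- keep & !(variant_key(calls) %in% normal_keys)
  }
  calls[keep, , drop = FALSE]
}
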