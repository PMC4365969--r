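#' Union three callers' somatic call sets with provenance
#'
#' Variants are matched by their identity key `(chrom, pos, ref, alt)`.
#' Presence bits `in_g`, `in_l`, `in_m` record which callers reported each
#' variant; merged annotations are taken from the record with the highest
#' tumor depth; per-caller VAFs are kept in `vaf_g`, `vaf_l`, `vaf_m`.
#'
#' @param g_set,l_set,m_set `variant_tbl`s from the same sample (any may be
#'   empty).
#' @return An integrated `variant_tbl` with presence bits, per-caller VAFs
#'   and a `callers` string (e.g. `"G,L,M"`). Two records with identical
#'   `(chrom, pos)` but conflicting alleles raise an error.
#' @export
union_callsets <- function(g_set, l_set, m_set) {
  sets <- list(G = g_set, L = l_set, M = m_set)
  tagged <- bind_rows(lapply(names(sets), function(lbl) {
    s <- sets[[lbl]]
    if (is.null(s) || nrow(s) == 0) return(NULL)
    s <- as_tibble(s)
    s$.src <- lbl
    s$.key <- variant_key(s)
    s
  }))
  if (is.null(tagged) || nrow(tagged) == 0) {
    out <- variant_tbl()
    out$in_g <- out$in_l <- out$in_m <- logical(0)
    out$vaf_g <- out$vaf_l <- out$vaf_m <- numeric(0)
    out$callers <- character(0)
    return(out)
  }
  # same locus must not carry conflicting ref alleles across callers
  locus <- paste(tagged$chrom, tagged$pos)
  conflict <- tapply(tagged$ref, locus, function(r) length(unique(r)) > 1)
  if (any(conflict)) {
    abort(paste0("conflicting ref alleles at ", names(conflict)[conflict][1]))
  }

  keys <- unique(tagged$.key)
  merged <- lapply(keys, function(k) {
    recs <- tagged[tagged$.key == k, , drop = FALSE]
    best <- recs[order(-ifelse(is.na(recs$tumor_depth), -1, recs$tumor_depth)), ][1, ]
    vaf_of <- function(lbl) {
      r <- recs[recs$.src == lbl, , drop = FALSE]
      if (nrow(r) == 0) NA_real_ else r$tumor_alt[1] / r$tumor_depth[1]
    }
    best$in_g <- "G" %in% recs$.src
    best$in_l <- "L" %in% recs$.src
    best$in_m <- "M" %in% recs$.src
    best$vaf_g <- vaf_of("G"); best$vaf_l <- vaf_of("L"); best$vaf_m <- vaf_of("M")
    best
  })
  out <- bind_rows(merged)
  out$callers <- paste0(ifelse(out$in_g, "G", ""), ifelse(out$in_l, "L", ""),
                        ifelse(out$in_m, "M", ""))
  out$callers <- gsub("(?<=.)(?=.)", ",", out$callers, perl = TRUE)
  out$caller <- out$callers
  out$.src <- NULL
  out$.key <- NULL
  validate_variant_tbl(out)
}

#' Automated evidence curation of an integrated call set
#'
#' Reproducible surrogate for the study's manual read-level inspection: a
#' unioned variant is dropped when its merged alt-read count is below
#' `min_alt`.
#'
#' @param ic Integrated call set from [union_callsets()].
#' @param min_alt Minimum merged alt-supporting reads (default 2).
#' @return The retained subset.
#' @export
curate_callset <- function(ic, min_alt = 2L) {
  if (nrow(ic) == 0) return(ic)
  ic[is.na(ic$tumor_alt) | ic$tumor_alt >= min_alt, , drop = FALSE]
}

#' Venn partition of an integrated call set
#'
#' @param ic Integrated call set with presence bits.
#' @return Tibble of the seven non-empty caller-combination regions
#'   (`region`, `count`, `fraction`), plus attribute checksum: counts sum to
#'   `nrow(ic)`.
#' @export
venn_partition <- function(ic) {
  if (nrow(ic) == 0) abort("venn_partition: empty call set")
  lab <- paste0(ifelse(ic$in_g, "G", ""), ifelse(ic$in_l, "L", ""),
                ifelse(ic$in_m, "M", ""))
  regions <- c("G", "L", "M", "GL", "GM", "LM", "GLM")
  counts <- unname(vapply(regions, function(r) sum(lab == r), integer(1)))
  tibble(region = regions, count = counts, fraction = counts / nrow(ic))
}

#' Per-caller sensitivity against validated variants
#'
#' Among variants confirmed present by orthogonal sequencing, the fraction
#' carrying each caller's presence bit.
#'
#' @param ic Integrated call set with `validation` and presence bits.
#' @return Tibble (`caller`, `detected`, `total`, `sensitivity_pct`), the
#'   percentage rounded half-away-from-zero to one decimal.
#' @export
caller_sensitivity <- function(ic) {
  conf <- ic[ic$validation == "confirmed_present", , drop = FALSE]
  if (nrow(conf) == 0) abort("no confirmed_present variants")
  det <- c(G = sum(conf$in_g), L = sum(conf$in_l), M = sum(conf$in_m))
  tibble(
    caller = names(det),
    detected = as.integer(det),
    total = nrow(conf),
    sensitivity_pct = unname(round_half_up(100 * det / nrow(conf), 1))
  )
}

#' Orthogonal validation rates
#'
#' True-positive rate: among assessed presence claims (validation attempted
#' and interpretable), the fraction confirmed present. True-negative rate:
#' among assessed absence claims, the fraction whose absence was confirmed.
#' `untested` and `uninterpretable` records are excluded from denominators.
#'
#' @param claims Tibble with `claim` (`"present"` or `"absent"`) and
#'   `validation` (`confirmed_present`, `confirmed_absent`, `untested`,
#'   `uninterpretable`). For presence claims, `confirmed_absent` means the
#'   claim failed validation; for absence claims, `confirmed_absent` means
#'   the absence was confirmed.
#' @return List with `tp_rate` and `tn_rate` (integer percent,
#'   half-away-from-zero), and the underlying counts.
#' @export
validation_rates <- function(claims) {
  assessed <- claims[claims$validation %in%
                       c("confirmed_present", "confirmed_absent"), ,
                     drop = FALSE]
  pres <- assessed[assessed$claim == "present", , drop = FALSE]
  abs_ <- assessed[assessed$claim == "absent", , drop = FALSE]
  if (nrow(pres) == 0) abort("no assessed presence claims")
  if (nrow(abs_) == 0) abort("no assessed absence claims")
  tp <- sum(pres$validation == "confirmed_present")
  tn <- sum(abs_$validation == "confirmed_absent")
  list(
    tp_rate = round_half_up(100 * tp / nrow(pres)),
    tn_rate = round_half_up(100 * tn / nrow(abs_)),
    n_presence_assessed = nrow(pres), n_presence_confirmed = tp,
    n_absence_assessed = nrow(abs_), n_absence_confirmed = tn
  )
}
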