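#' The 96 canonical trinucleotide substitution channels
#'
#' Channels are pyrimidine-centered: six substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G) by sixteen flanking-base combinations, in the conventional
#' lexicographic order. A channel label looks like `"ACG>ATG"` (context with
#' the reference middle base, then the context with the alternate base).
#'
#' @return Tibble with `channel`, `sub` (e.g. `"C>T"`), `fivep`, `threep`,
#'   `context` (reference trinucleotide).
#' @export
channels96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(threep = bases, fivep = bases, sub = subs,
                      stringsAsFactors = FALSE)[, c("sub", "fivep", "threep")]
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  ctx <- paste0(grid$fivep, ref, grid$threep)
  tibble(
    channel = paste0(ctx, ">", paste0(grid$fivep, alt, grid$threep)),
    sub = grid$sub, fivep = grid$fivep, threep = grid$threep, context = ctx
  )
}

revcomp3 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Assign a substitution to its canonical pyrimidine-centered channel
#'
#' If the reference base is a purine, the reference, alternate and context are
#' reverse-complemented before assignment, so both strand encodings of the
#' same event map to one channel.
#'
#' @param ref,alt Single bases; `ref != alt`.
#' @param context Reference trinucleotide with middle base `ref`.
#' @return Character vector of channel labels (see [channels96()]).
#' @export
canonical_channel <- function(ref, alt, context) {
  if (any(!c(ref, alt) %in% c("A", "C", "G", "T")) ||
      any(!strsplit(paste(context, collapse = ""), "")[[1]] %in%
          c("A", "C", "G", "T"))) {
    abort("ambiguous base in ref/alt/context (only A, C, G, T allowed)")
  }
  if (any(substr(context, 2, 2) != ref)) {
    abort("context middle base must equal ref")
  }
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, revcomp3(ref), ref)
  alt2 <- ifelse(flip, revcomp3(alt), alt)
  ctx2 <- ifelse(flip, revcomp3(context), context)
  paste0(ctx2, ">", paste0(substr(ctx2, 1, 1), alt2, substr(ctx2, 3, 3)))
}

#' Build a 96-channel mutation spectrum from a call set
#'
#' @param calls A `variant_tbl` whose every row has a `context`.
#' @return Tibble of 96 rows (`channel`, `sub`, `fivep`, `threep`, `count`,
#'   `freq`); `sum(count)` equals `nrow(calls)`. For an empty call set all
#'   counts are zero and `freq` is `NA`.
#' @export
build_spectrum <- function(calls) {
  calls <- validate_variant_tbl(calls)
  ch <- channels96()
  if (nrow(calls) == 0) {
    ch$count <- 0L
    ch$freq <- NA_real_
    return(ch)
  }
  if (anyNA(calls$context)) {
    i <- which(is.na(calls$context))[1]
    abort(paste0("missing context for variant ", variant_key(calls)[i]))
  }
  lab <- canonical_channel(calls$ref, calls$alt, calls$context)
  counts <- table(factor(lab, levels = ch$channel))
  ch$count <- as.integer(counts)
  ch$freq <- ch$count / sum(ch$count)
  ch
}

#' CpG>TpG fraction of a spectrum
#'
#' Mass on C>T channels whose 3' base is G (a CpG dinucleotide), the context
#' associated with deamination of methylated cytosine ('aging' signature).
#'
#' @param spectrum A [build_spectrum()] tibble.
#' @return Fraction in `[0, 1]`.
#' @export
cpg_tpg_fraction <- function(spectrum) {
  tot <- sum(spectrum$count)
  if (tot == 0) abort("empty spectrum")
  sum(spectrum$count[spectrum$sub == "C>T" & spectrum$threep == "G"]) / tot
}

#' POLE ultramutator fraction of a spectrum
#'
#' Mass on the two channels characteristic of polymerase-epsilon proofreading
#' deficiency: TCT>TAT and TCG>TTG.
#'
#' @param spectrum A [build_spectrum()] tibble.
#' @return Fraction in `[0, 1]`.
#' @export
pole_fraction <- function(spectrum) {
  tot <- sum(spectrum$count)
  if (tot == 0) abort("empty spectrum")
  sum(spectrum$count[spectrum$channel %in% c("TCT>TAT", "TCG>TTG")]) / tot
}

#' Compare two spectra
#'
#' @param a,b [build_spectrum()] tibbles with positive totals.
#' @return List with `cosine` (cosine similarity of the frequency vectors,
#'   in `[0, 1]`) and `difference` (per-channel `freq_a - freq_b`, summing
#'   to 0).
#' @export
compare_spectra <- function(a, b) {
  if (sum(a$count) == 0 || sum(b$count) == 0) abort("empty spectrum")
  if (!identical(a$channel, b$channel)) abort("spectra channel order differs")
  fa <- a$count / sum(a$count)
  fb <- b$count / sum(b$count)
  list(
    cosine = sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2)),
    difference = tibble(channel = a$channel, difference = fa - fb)
  )
}

#' Write a spectrum as TSV
#'
#' @param spectrum A [build_spectrum()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(spectrum[, c("channel", "count", "freq")], path)
  invisible(path)
}
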