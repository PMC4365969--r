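#' Construct a somatic SNV call table
#'
#' The central container of the package: one row per candidate somatic single
#' nucleotide variant, carrying the read evidence and annotations the filter,
#' integration and concordance stages consume. Columns not supplied are filled
#' with permissive defaults so partially annotated call sets (e.g. minimal
#' fixtures) remain usable; stages that need a missing annotation raise an
#' error naming it.
#'
#' @param chrom Chromosome names (character).
#' @param pos 1-based positions (integer).
#' @param ref,alt Single reference / alternate bases; `ref != alt`.
#' @param tumor_depth,tumor_alt Total and alt-supporting read counts in tumor.
#' @param alt_fw,alt_rv,ref_fw,ref_rv Stranded read counts
#'   (`alt_fw + alt_rv == tumor_alt` when all are given).
#' @param normal_depth,normal_alt Read counts in the matched normal.
#' @param mq Mapping quality (phred-like).
#' @param sb Strand-bias score (typically <= 0; see [sb_score()]).
#' @param qual Variant quality.
#' @param consequence One of `"missense"`, `"nonsense"`, `"splice"`,
#'   `"synonymous"`, `"other"`.
#' @param dbsnp,cosmic Logical membership flags.
#' @param context Reference trinucleotide centered on `pos` (middle base must
#'   equal `ref`).
#' @param gene Gene symbol (optional annotation used by recurrence analysis).
#' @param caller Caller label, subset of `"G"`, `"L"`, `"M"` (comma-joined).
#' @param validation One of `"untested"`, `"confirmed_present"`,
#'   `"confirmed_absent"`, `"uninterpretable"`.
#' @return A tibble of class `variant_tbl`.
#' @export
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        tumor_depth = NA_integer_, tumor_alt = NA_integer_,
                        alt_fw = NA_integer_, alt_rv = NA_integer_,
                        ref_fw = NA_integer_, ref_rv = NA_integer_,
                        normal_depth = NA_integer_, normal_alt = NA_integer_,
                        mq = NA_real_, sb = NA_real_, qual = NA_real_,
                        consequence = NA_character_,
                        dbsnp = NA, cosmic = NA,
                        context = NA_character_, gene = NA_character_,
                        caller = NA_character_,
                        validation = "untested") {
  out <- tibble(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    tumor_depth = as.integer(tumor_depth), tumor_alt = as.integer(tumor_alt),
    alt_fw = as.integer(alt_fw), alt_rv = as.integer(alt_rv),
    ref_fw = as.integer(ref_fw), ref_rv = as.integer(ref_rv),
    normal_depth = as.integer(normal_depth), normal_alt = as.integer(normal_alt),
    mq = as.double(mq), sb = as.double(sb), qual = as.double(qual),
    consequence = as.character(consequence),
    dbsnp = as.logical(dbsnp), cosmic = as.logical(cosmic),
    context = as.character(context), gene = as.character(gene),
    caller = as.character(caller),
    validation = as.character(validation)
  )
  validate_variant_tbl(out)
}

#' Validate the invariants of a variant table
#'
#' Checks positional, allelic and read-count invariants and returns the table
#' invisibly augmented with class `variant_tbl`. Invariants on columns that are
#' entirely `NA` are skipped (partially annotated tables are legal).
#'
#' @param x A data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return `x` as a `variant_tbl` tibble.
#' @export
validate_variant_tbl <- function(x) {
  x <- as_tibble(x)
  req <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    class(x) <- c("variant_tbl", class(x))
    return(x)
  }
  if (any(x$pos < 1)) abort("variant positions must be >= 1")
  if (any(x$ref == x$alt)) abort("ref and alt alleles must differ")
  if (!all(nchar(x$ref) == 1 & nchar(x$alt) == 1)) {
    abort("only single-base SNVs are supported")
  }
  if (all(c("tumor_depth", "tumor_alt") %in% names(x))) {
    ok <- is.na(x$tumor_alt) | is.na(x$tumor_depth) |
      (x$tumor_alt >= 0 & x$tumor_alt <= x$tumor_depth)
    if (!all(ok)) abort("tumor_alt must lie in [0, tumor_depth]")
  }
  if (all(c("alt_fw", "alt_rv", "tumor_alt") %in% names(x))) {
    ok <- is.na(x$alt_fw) | is.na(x$alt_rv) | is.na(x$tumor_alt) |
      (x$alt_fw + x$alt_rv == x$tumor_alt)
    if (!all(ok)) abort("alt_fw + alt_rv must equal tumor_alt")
  }
  if ("context" %in% names(x)) {
    ctx <- x$context[!is.na(x$context)]
    ref <- x$ref[!is.na(x$context)]
    if (length(ctx) > 0 &&
        !all(nchar(ctx) == 3 & substr(ctx, 2, 2) == ref)) {
      abort("context must be a trinucleotide whose middle base equals ref")
    }
  }
  if (!inherits(x, "variant_tbl")) class(x) <- c("variant_tbl", class(x))
  x
}

#' Variant identity keys
#'
#' Variants are matched across callers, tissues and truth tables by the key
#' `(chrom, pos, ref, alt)`; with an SNV-only scope this is unambiguous.
#'
#' @param x A variant table (or any data frame with the four key columns).
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Variant allele frequency
#'
#' @param x A variant table with `tumor_alt` and `tumor_depth`.
#' @return Numeric vector `tumor_alt / tumor_depth` in `[0, 1]`.
#' @export
vaf <- function(x) {
  x$tumor_alt / x$tumor_depth
}
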