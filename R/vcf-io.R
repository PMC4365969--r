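#' Read a somatic call set from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [variant_tbl()]. Only
#' biallelic SNV records are kept: multiallelic records are split into one row
#' per alternate allele, and non-SNV records (indels, MNVs, symbolic alleles)
#' are skipped with a logged count. Annotations are taken from the INFO column
#' using the tags this package writes (`DP`, `AD`, `SAF`/`SAR`/`SRF`/`SRR`,
#' `NDP`/`NAD`, `MQ`, `SB`, `CSQ`, `GENE`, `CTX`, `DBSNP`, `COSMIC`,
#' `CALLERS`, `VSTAT`); unknown tags are ignored and absent tags yield `NA`.
#'
#' @param path Path to a VCF file.
#' @param caller_label Optional caller label (`"G"`, `"L"` or `"M"`) stored in
#'   the `caller` column; defaults to the file's `CALLERS` tag when present.
#' @return A `variant_tbl`, with attribute `n_skipped` giving the number of
#'   non-SNV records dropped.
#' @export
read_callset <- function(path, caller_label = NULL) {
  if (!file.exists(path)) abort(paste0("no such VCF file: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(fix) || nrow(fix) == 0) {
    out <- variant_tbl()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n_header <- length(vcf@meta) + 1L  # meta lines + #CHROM line

  pos <- suppressWarnings(as.integer(fix$POS))
  bad <- which(is.na(pos))
  if (length(bad) > 0) {
    abort(sprintf("malformed VCF record at line %d of %s: POS '%s'",
                  n_header + bad[1], path, fix$POS[bad[1]]))
  }

  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    info <- parse_vcf_info(fix$INFO[i])
    for (j in seq_along(alts)) {
      if (nchar(fix$REF[i]) != 1 || nchar(alts[j]) != 1 ||
          !(fix$REF[i] %in% c("A", "C", "G", "T")) ||
          !(alts[j] %in% c("A", "C", "G", "T"))) {
        n_skipped <- n_skipped + 1L
        next
      }
      ad <- info_counts(info[["AD"]], j)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = fix$CHROM[i], pos = pos[i], ref = fix$REF[i], alt = alts[j],
        tumor_depth = info_int(info[["DP"]]),
        tumor_alt = unname(ad["alt"]),
        alt_fw = info_int(info[["SAF"]]), alt_rv = info_int(info[["SAR"]]),
        ref_fw = info_int(info[["SRF"]]), ref_rv = info_int(info[["SRR"]]),
        normal_depth = info_int(info[["NDP"]]),
        normal_alt = info_int(info[["NAD"]]),
        mq = info_num(info[["MQ"]]), sb = info_num(info[["SB"]]),
        qual = suppressWarnings(as.double(fix$QUAL[i])),
        consequence = info[["CSQ"]] %||% NA_character_,
        dbsnp = "DBSNP" %in% names(info),
        cosmic = "COSMIC" %in% names(info),
        context = info[["CTX"]] %||% NA_character_,
        gene = info[["GENE"]] %||% NA_character_,
        caller = caller_label %||% info[["CALLERS"]] %||% NA_character_,
        validation = info[["VSTAT"]] %||% "untested",
        filter = fix$FILTER[i] %||% NA_character_,
        hp_window = info[["HPW"]] %||% NA_character_,
        truth_id = info[["TID"]] %||% NA_character_,
        artifact = info[["ART"]] %||% NA_character_
      )
    }
  }
  out <- if (length(rows) == 0) variant_tbl() else
    validate_variant_tbl(bind_rows(rows))
  if (n_skipped > 0) {
    inform(sprintf("read_callset: skipped %d non-SNV record(s) in %s",
                   n_skipped, basename(path)))
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

parse_vcf_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) > 1) p[2] else TRUE)
  names(vals) <- vapply(kv, `[`, "", 1)
  vals
}

info_int <- function(x) {
  if (is.null(x) || isTRUE(x)) return(NA_integer_)
  suppressWarnings(as.integer(x))
}

info_num <- function(x) {
  if (is.null(x) || isTRUE(x)) return(NA_real_)
  suppressWarnings(as.double(x))
}

# AD = ref,alt1[,alt2...]; returns c(ref =, alt =) for the j-th alternate
info_counts <- function(x, j) {
  if (is.null(x) || isTRUE(x)) return(c(ref = NA_integer_, alt = NA_integer_))
  v <- suppressWarnings(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  c(ref = v[1], alt = if (length(v) >= j + 1) v[j + 1] else NA_integer_)
}

#' Write a call set as a VCF 4.2 file
#'
#' Inverse of [read_callset()]: emits plain-text VCF with the package's INFO
#' tags so that a write/read round trip preserves every field the downstream
#' stages use. Output is byte-stable for identical input.
#'
#' @param x A `variant_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(x, path) {
  x <- validate_variant_tbl(x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clonecord",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Tumor read depth\">",
    "##INFO=<ID=AD,Number=R,Type=Integer,Description=\"Tumor ref,alt read counts\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt reads forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reads reverse strand\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Ref reads forward strand\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Ref reads reverse strand\">",
    "##INFO=<ID=NDP,Number=1,Type=Integer,Description=\"Normal read depth\">",
    "##INFO=<ID=NAD,Number=1,Type=Integer,Description=\"Normal alt read count\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias score\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Reference trinucleotide context\">",
    "##INFO=<ID=DBSNP,Number=0,Type=Flag,Description=\"Present in dbSNP\">",
    "##INFO=<ID=COSMIC,Number=0,Type=Flag,Description=\"Present in COSMIC\">",
    "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Calling algorithms\">",
    "##INFO=<ID=VSTAT,Number=1,Type=String,Description=\"Orthogonal validation status\">",
    "##INFO=<ID=HPW,Number=1,Type=String,Description=\"Reference bases around the locus (homopolymer check)\">",
    "##INFO=<ID=TID,Number=1,Type=String,Description=\"Simulated truth mutation id\">",
    "##INFO=<ID=ART,Number=1,Type=String,Description=\"Simulated artifact class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    info <- c(
      info_tag_int("DP", x$tumor_depth[i]),
      if (!is.na(x$tumor_alt[i]) && !is.na(x$tumor_depth[i]))
        sprintf("AD=%d,%d", x$tumor_depth[i] - x$tumor_alt[i], x$tumor_alt[i]),
      info_tag_int("SAF", x$alt_fw[i]), info_tag_int("SAR", x$alt_rv[i]),
      info_tag_int("SRF", x$ref_fw[i]), info_tag_int("SRR", x$ref_rv[i]),
      info_tag_int("NDP", x$normal_depth[i]), info_tag_int("NAD", x$normal_alt[i]),
      info_tag_num("MQ", x$mq[i]), info_tag_num("SB", x$sb[i]),
      info_tag_chr("CSQ", x$consequence[i]), info_tag_chr("GENE", x$gene[i]),
      info_tag_chr("CTX", x$context[i]),
      if (isTRUE(x$dbsnp[i])) "DBSNP", if (isTRUE(x$cosmic[i])) "COSMIC",
      info_tag_chr("CALLERS", x$caller[i]),
      info_tag_chr("VSTAT", x$validation[i]),
      if ("hp_window" %in% names(x)) info_tag_chr("HPW", x$hp_window[i]),
      if ("truth_id" %in% names(x)) info_tag_chr("TID", x$truth_id[i]),
      if ("artifact" %in% names(x)) info_tag_chr("ART", x$artifact[i])
    )
    filt <- if ("filter" %in% names(x) && !is.na(x$filter[i])) x$filter[i] else "."
    body[i] <- paste(
      x$chrom[i], x$pos[i], ".", x$ref[i], x$alt[i],
      if (is.na(x$qual[i])) "." else sprintf("%.6g", x$qual[i]),
      filt,
      if (length(info) == 0) "." else paste(unlist(info), collapse = ";"),
      sep = "\t"
    )
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_tag_int <- function(tag, v) if (is.na(v)) NULL else sprintf("%s=%d", tag, v)
info_tag_num <- function(tag, v) if (is.na(v)) NULL else sprintf("%s=%.6g", tag, v)
info_tag_chr <- function(tag, v) if (is.na(v)) NULL else sprintf("%s=%s", tag, v)

#' Read genomic intervals from a BED file
#'
#' BED is 0-based half-open; this package works in 1-based inclusive
#' coordinates throughout (VCF convention), so `start` is shifted by +1.
#'
#' @param path BED file (first three columns used).
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_intervals_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         comment = "#")
  tibble(chrom = as.character(bed[[1]]),
         start = as.integer(bed[[2]]) + 1L,
         end = as.integer(bed[[3]]))
}

#' Write genomic intervals to a BED file
#'
#' @param x Tibble with `chrom`, `start`, `end` in 1-based inclusive
#'   coordinates.
#' @param path Output BED path (0-based half-open on disk).
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(x, path) {
  lines <- sprintf("%s\t%d\t%d", x$chrom, x$start - 1L, x$end)
  writeLines(lines, path)
  invisible(path)
}

#' Extract trinucleotide contexts from a reference FASTA
#'
#' @param fasta_path FASTA file readable by \pkg{Biostrings}.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Character vector of trinucleotides centered on each position.
#' @export
context_from_fasta <- function(fasta_path, chrom, pos) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  names(ref) <- sub("\\s.*$", "", names(ref))
  vapply(seq_along(chrom), function(i) {
    if (!chrom[i] %in% names(ref)) {
      abort(paste0("sequence not in FASTA: ", chrom[i]))
    }
    as.character(Biostrings::subseq(ref[[chrom[i]]], pos[i] - 1L, pos[i] + 1L))
  }, character(1))
}
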