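#' Annotate database membership from plain locus-allele lists
#'
#' Sets the `dbsnp` and `cosmic` flags of a call set from membership list
#' files — plain TSVs with columns `chrom`, `pos`, `ref`, `alt` — so no live
#' database connection is ever needed. Variants are matched by identity key.
#'
#' @param calls A `variant_tbl`.
#' @param dbsnp_path,cosmic_path Paths to membership TSVs (either may be
#'   `NULL` to leave that flag untouched).
#' @return `calls` with updated membership flags.
#' @export
annotate_membership <- function(calls, dbsnp_path = NULL, cosmic_path = NULL) {
  calls <- validate_variant_tbl(calls)
  keys <- variant_key(calls)
  read_keys <- function(path) {
    # a lone "T" allele must not parse as logical TRUE
    x <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(chrom = "c", pos = "i",
                                                 ref = "c", alt = "c"))
    variant_key(x)
  }
  if (!is.null(dbsnp_path)) calls$dbsnp <- keys %in% read_keys(dbsnp_path)
  if (!is.null(cosmic_path)) calls$cosmic <- keys %in% read_keys(cosmic_path)
  calls
}

#' The bundled copy-number panel gene list
#'
#' An 87-name synthetic placeholder list standing in for a commercial
#' cancer copy-number panel; the real panel's gene names are not
#' distributed with the package.
#'
#' @return Character vector of 87 gene names.
#' @export
cn_panel_genes <- function() {
  readLines(system.file("extdata", "cn_panel_genes_synthetic.txt",
                        package = "clonecord"))
}
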