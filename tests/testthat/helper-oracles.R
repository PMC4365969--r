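# Independent brute-force oracles used across tests.

# longest identical-base run containing or adjacent to position `pos`,
# by scanning every run explicitly
oracle_hp_run <- function(window, pos) {
  b <- strsplit(window, "")[[1]]
  best <- 0L
  i <- 1L
  while (i <= length(b)) {
    j <- i
    while (j < length(b) && b[j + 1] == b[i]) j <- j + 1L
    if (i <= pos + 1L && j >= pos - 1L) best <- max(best, j - i + 1L)
    i <- j + 1L
  }
  best
}

# Venn region counts by enumerating membership triples per key
oracle_venn <- function(g, l, m) {
  keys <- unique(c(g, l, m))
  lab <- vapply(keys, function(k) {
    paste0(if (k %in% g) "G" else "", if (k %in% l) "L" else "",
           if (k %in% m) "M" else "")
  }, "")
  regions <- c("G", "L", "M", "GL", "GM", "LM", "GLM")
  vapply(regions, function(r) sum(lab == r), integer(1))
}

# per-position interval arithmetic on small integer coordinates
oracle_region_concordance <- function(a, b, max_pos = 2000) {
  cover <- function(x, chrom) {
    pos <- rep(FALSE, max_pos)
    xx <- x[x$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(xx))) pos[xx$start[i]:xx$end[i]] <- TRUE
    pos
  }
  chroms <- unique(c(a$chrom, b$chrom))
  inter <- uni <- pa <- pb <- 0L
  for (cc in chroms) {
    ca <- cover(a, cc); cb <- cover(b, cc)
    inter <- inter + sum(ca & cb)
    uni <- uni + sum(ca | cb)
    pa <- pa + sum(ca & !cb)
    pb <- pb + sum(cb & !ca)
  }
  list(jaccard = if (uni == 0) NA_real_ else inter / uni,
       shared_bp = inter, private_primary_bp = pa, private_met_bp = pb)
}

# minimal clean variant table that passes all filters
clean_calls <- function(n, chrom = "1", pos = seq_len(n) * 1000L) {
  x <- variant_tbl(
    chrom = rep(chrom, n), pos = pos, ref = "C", alt = "T",
    tumor_depth = 100L, tumor_alt = 20L, alt_fw = 10L, alt_rv = 10L,
    ref_fw = 40L, ref_rv = 40L, normal_depth = 80L, normal_alt = 0L,
    mq = 60, sb = -0.9, qual = 900, consequence = "missense",
    dbsnp = FALSE, cosmic = FALSE
  )
  x$hp_window <- "ACGTACGTACG"
  x
}
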