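#' Select heterozygous germline SNPs from a normal-tissue pileup
#'
#' Retains positions with depth of at least `min_depth` in the normal and a
#' B-allele frequency inside the heterozygous band (a transparent interval
#' rule rather than a genotype-likelihood test).
#'
#' @param pileup Tibble with `chrom`, `pos`, `depth`, `alt` (and optionally
#'   `baf`; recomputed as `alt / depth`).
#' @param min_depth Minimum normal depth (default 20, inclusive).
#' @param het_band Two-sided BAF interval accepted as heterozygous
#'   (inclusive; default `[0.25, 0.75]`).
#' @return The retained pileup rows, with a `baf` column.
#' @export
call_het_snps <- function(pileup, min_depth = 20L, het_band = c(0.25, 0.75)) {
  baf <- pileup$alt / pileup$depth
  keep <- pileup$depth >= min_depth & baf >= het_band[1] & baf <= het_band[2]
  out <- pileup[keep, , drop = FALSE]
  out$baf <- baf[keep]
  out
}

#' Deviation of B-allele frequency from balance
#'
#' The folded (mirrored) BAF used throughout: distance of the observed BAF
#' from 0.5, towards either 0 or 1, so imbalance direction is ignored.
#'
#' @param baf Numeric in `[0, 1]`.
#' @return `|baf - 0.5|`, in `[0, 0.5]`.
#' @export
baf_deviation <- function(baf) {
  stopifnot(all(baf >= 0 & baf <= 1, na.rm = TRUE))
  abs(baf - 0.5)
}

#' Build a per-sample BAF track
#'
#' Joins tumor BAFs onto the het-SNP positions selected from the normal;
#' positions are strictly increasing within each chromosome.
#'
#' @param het_snps Output of [call_het_snps()] on the normal pileup.
#' @param tumor_pileup Tumor pileup tibble (`chrom`, `pos`, `depth`, `alt`).
#' @param sample_label Label stored on the track.
#' @return Tibble with `chrom`, `pos`, `normal_baf`, `tumor_baf`, `depth`
#'   (tumor) and `deviation`, ordered by chromosome and position.
#' @export
baf_track <- function(het_snps, tumor_pileup, sample_label = NA_character_) {
  tp <- tumor_pileup
  tp$tumor_baf <- tp$alt / tp$depth
  merged <- dplyr::inner_join(
    het_snps[, c("chrom", "pos", "baf")],
    tp[, c("chrom", "pos", "depth", "tumor_baf")],
    by = c("chrom", "pos")
  )
  merged <- merged[order(merged$chrom, merged$pos), , drop = FALSE]
  stopifnot(!anyDuplicated(paste(merged$chrom, merged$pos)))
  tibble(
    chrom = merged$chrom, pos = merged$pos,
    normal_baf = merged$baf, tumor_baf = merged$tumor_baf,
    depth = merged$depth,
    deviation = baf_deviation(merged$tumor_baf),
    sample = sample_label
  )
}

# maximal runs of TRUE, merging runs separated by <= max_gap FALSEs
runs_with_gaps <- function(flag, max_gap) {
  r <- rle(flag)
  # absorb short FALSE gaps between TRUE runs
  if (length(r$lengths) >= 3) {
    for (i in seq(2, length(r$values) - 1)) {
      if (!r$values[i] && r$lengths[i] <= max_gap &&
          r$values[i - 1] && r$values[i + 1]) {
        r$values[i] <- TRUE
      }
    }
  }
  flag2 <- inverse.rle(r)
  r2 <- rle(flag2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  keep <- r2$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Segment broad allelic-imbalance regions from a BAF track
#'
#' Smooths the folded deviations with a running median over `window` SNPs per
#' chromosome, then reports maximal runs of at least `min_run` SNPs whose
#' smoothed deviation strictly exceeds `dev_threshold`; runs separated by at
#' most `max_gap` sub-threshold SNPs are merged. Each region spans the first
#' to last SNP of its run (1-based inclusive). Chromosomes with fewer than
#' `window` SNPs are skipped with a message.
#'
#' @param track A [baf_track()] tibble.
#' @param window Running-median window (SNPs, odd).
#' @param dev_threshold Smoothed-deviation threshold (strict `>`).
#' @param min_run Minimum run length (SNPs).
#' @param max_gap Maximum below-threshold gap merged into a run (SNPs).
#' @return Tibble of intervals (`chrom`, `start`, `end`, `n_snps`,
#'   `mean_deviation`), non-overlapping and sorted.
#' @export
segment_imbalance <- function(track, window = 11L, dev_threshold = 0.1,
                              min_run = 10L, max_gap = 3L) {
  out <- list()
  for (cc in unique(track$chrom)) {
    tr <- track[track$chrom == cc, , drop = FALSE]
    if (nrow(tr) < window) {
      inform(sprintf("segment_imbalance: chromosome %s has %d < %d SNPs; skipped",
                     cc, nrow(tr), window))
      next
    }
    sm <- as.numeric(runmed(tr$deviation, k = window, endrule = "median"))
    above <- sm > dev_threshold
    if (!any(above)) next
    runs <- runs_with_gaps(above, max_gap)
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, "start"]; b <- runs[i, "end"]
      if (b - a + 1L < min_run) next
      out[[length(out) + 1L]] <- tibble(
        chrom = cc, start = tr$pos[a], end = tr$pos[b],
        n_snps = b - a + 1L,
        mean_deviation = mean(tr$deviation[a:b])
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  n_snps = integer(), mean_deviation = numeric()))
  }
  res <- bind_rows(out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

intervals_to_granges <- function(x) {
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Base-pair concordance of two region sets
#'
#' Jaccard index of the two interval unions in base pairs, plus the shared
#' footprint and each side's private footprint. Coordinates are 1-based
#' inclusive; overlap arithmetic is done with \pkg{GenomicRanges}.
#'
#' @param regions_primary,regions_met Interval tibbles (`chrom`, `start`,
#'   `end`).
#' @return List with `jaccard`, `shared_bp`, `private_primary_bp`,
#'   `private_met_bp`. Two empty sets give Jaccard `NA`.
#' @export
region_concordance <- function(regions_primary, regions_met) {
  gp <- GenomicRanges::reduce(intervals_to_granges(regions_primary))
  gm <- GenomicRanges::reduce(intervals_to_granges(regions_met))
  # put both on the union of sequence levels so set operations are silent
  lev <- union(GenomeInfoDb::seqlevels(gp), GenomeInfoDb::seqlevels(gm))
  GenomeInfoDb::seqlevels(gp) <- lev
  GenomeInfoDb::seqlevels(gm) <- lev
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(gp, gm)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(gp, gm)))
  list(
    jaccard = if (uni == 0) NA_real_ else inter / uni,
    shared_bp = inter,
    private_primary_bp = sum(GenomicRanges::width(
      GenomicRanges::setdiff(gp, gm))),
    private_met_bp = sum(GenomicRanges::width(
      GenomicRanges::setdiff(gm, gp)))
  )
}
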