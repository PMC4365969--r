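test_that("het-SNP selection applies the depth and band rules inclusively", {
  pu <- tibble::tibble(chrom = "1", pos = 1:5,
                       depth = c(19L, 20L, 100L, 100L, 100L),
                       alt = c(10L, 10L, 2L, 25L, 75L))
  het <- call_het_snps(pu)
  # depth 19 excluded; BAF 0.02 homozygous; band edges 0.25/0.75 included
  expect_equal(het$pos, c(2L, 4L, 5L))
})

test_that("the retained het-SNP count follows the depth-model tail", {
  cfg <- sim_config(n_patients = 1, seed = 33, pole_patient = NA)
  set.seed(33)
  p <- simulate_patient(cfg, "P01")
  het <- call_het_snps(p$normal_pileup)
  # depth >= 20 is essentially certain at NB(mean 400); the loss comes from
  # binomial BAF leaving [0.25, 0.75], itself tiny at depth ~400
  p_keep <- mean(pnbinom(19, mu = cfg$depth_mean, size = cfg$depth_size,
                         lower.tail = FALSE))
  expect_gt(nrow(het) / cfg$n_het_snps, 0.99 * p_keep)
})

test_that("BAF deviation folds towards 0.5 and matches the LOH mixture", {
  expect_equal(baf_deviation(0.5), 0)
  expect_equal(baf_deviation(1.0), 0.5)
  expect_equal(baf_deviation(0.0), 0.5)
  # clonal LOH at purity 0.6, infinite depth
  expect_equal(baf_deviation(expected_vaf(0.6, 1, "loh_lost")),
               0.5 - 0.4 / 1.4, tolerance = 1e-12)
  expect_error(baf_deviation(1.2))
})

test_that("segmentation recovers a known LOH segment and stays silent elsewhere", {
  set.seed(37)
  n <- 800
  purity <- 0.6
  mk_track <- function(loh_idx) {
    pos <- sort(sample.int(1e8L, n))
    state <- ifelse(seq_len(n) %in% loh_idx,
                    ifelse(runif(n) < 0.5, "loh_retained", "loh_lost"),
                    "diploid_het")
    ebaf <- ifelse(state == "diploid_het", 0.5,
                   expected_vaf(purity, 1, state))
    depth <- pmax(1L, rnbinom(n, mu = 400, size = 20))
    alt <- rbinom(n, depth, ebaf)
    tibble::tibble(chrom = "1", pos = pos, normal_baf = 0.5,
                   tumor_baf = alt / depth, depth = depth,
                   deviation = abs(alt / depth - 0.5))
  }
  tr <- mk_track(200:600)
  seg <- segment_imbalance(tr)
  expect_equal(nrow(seg), 1)
  true_iv <- tibble::tibble(chrom = "1", start = tr$pos[200], end = tr$pos[600])
  rc <- region_concordance(seg, true_iv)
  expect_gte(rc$shared_bp / (true_iv$end - true_iv$start + 1), 0.9)

  balanced <- mk_track(integer())
  expect_equal(nrow(segment_imbalance(balanced)), 0)

  # all-balanced exact case
  flat <- tibble::tibble(chrom = "1", pos = 1:100 * 10L, normal_baf = 0.5,
                         tumor_baf = 0.5, depth = 100L, deviation = 0)
  expect_equal(nrow(segment_imbalance(flat)), 0)
})

test_that("segmentation threshold is strict and monotone", {
  # smoothed deviations exactly at the threshold are excluded
  tr <- tibble::tibble(chrom = "1", pos = 1:50 * 100L, normal_baf = 0.5,
                       tumor_baf = 0.6, depth = 100L, deviation = 0.1)
  expect_equal(nrow(segment_imbalance(tr, dev_threshold = 0.1)), 0)
  expect_equal(nrow(segment_imbalance(tr, dev_threshold = 0.099)), 1)

  # footprint never grows as the threshold rises
  set.seed(41)
  dev <- abs(rnorm(400, 0.1, 0.08))
  tr2 <- tibble::tibble(chrom = "1", pos = sort(sample.int(1e6L, 400)),
                        normal_baf = 0.5, tumor_baf = 0.5 + pmin(dev, 0.5),
                        depth = 100L, deviation = pmin(dev, 0.5))
  fp <- vapply(c(0.05, 0.1, 0.15, 0.2), function(th) {
    seg <- segment_imbalance(tr2, dev_threshold = th)
    if (nrow(seg) == 0) 0 else sum(seg$end - seg$start + 1)
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))

  # output intervals are sorted and non-overlapping
  seg <- segment_imbalance(tr2, dev_threshold = 0.05)
  if (nrow(seg) > 1) {
    expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
  }
})

test_that("chromosomes with too few SNPs are skipped with a message", {
  tr <- tibble::tibble(chrom = "1", pos = 1:5 * 10L, normal_baf = 0.5,
                       tumor_baf = 0.9, depth = 50L, deviation = 0.4)
  expect_message(seg <- segment_imbalance(tr), "skipped")
  expect_equal(nrow(seg), 0)
})

test_that("region concordance matches the per-position oracle", {
  expect_equal(region_concordance(
    tibble::tibble(chrom = "1", start = 10L, end = 20L),
    tibble::tibble(chrom = "1", start = 10L, end = 20L))$jaccard, 1)
  expect_equal(region_concordance(
    tibble::tibble(chrom = "1", start = 10L, end = 20L),
    tibble::tibble(chrom = "1", start = 30L, end = 40L))$jaccard, 0)

  set.seed(43)
  for (i in 1:15) {
    mk <- function() {
      k <- sample(1:4, 1)
      start <- sample.int(1500, k)
      tibble::tibble(chrom = sample(c("1", "2"), k, replace = TRUE),
                     start = start,
                     end = pmin(2000L, start + sample.int(300, k)))
    }
    a <- mk(); b <- mk()
    got <- region_concordance(a, b)
    want <- oracle_region_concordance(a, b)
    expect_equal(got$jaccard, want$jaccard, tolerance = 1e-12)
    expect_equal(got$shared_bp, want$shared_bp)
    expect_equal(got$private_primary_bp, want$private_primary_bp)
    expect_equal(got$private_met_bp, want$private_met_bp)
  }
})

test_that("matched tumors share more imbalance footprint than permuted pairs", {
  cfg <- sim_config(n_patients = 4, seed = 47, n_het_snps = 1200)
  coh <- simulate_cohort(cfg)
  seg_of <- function(p, tissue) {
    het <- call_het_snps(p$normal_pileup)
    tr <- baf_track(het, if (tissue == "primary") p$primary_pileup else p$met_pileup)
    segment_imbalance(tr)
  }
  segs_p <- lapply(coh$patients, seg_of, tissue = "primary")
  segs_m <- lapply(coh$patients, seg_of, tissue = "met")
  matched <- vapply(1:4, function(i) {
    region_concordance(segs_p[[i]], segs_m[[i]])$jaccard
  }, numeric(1))
  permuted <- vapply(1:4, function(i) {
    j <- (i %% 4) + 1
    rc <- region_concordance(segs_p[[i]], segs_m[[j]])$jaccard
    if (is.na(rc)) 0 else rc
  }, numeric(1))
  expect_gt(median(matched, na.rm = TRUE), median(permuted))
})
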