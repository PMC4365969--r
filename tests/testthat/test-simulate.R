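test_that("expected VAF follows the purity/CCF mixture algebra", {
  expect_equal(expected_vaf(1.0, 1.0, "diploid_het"), 0.5)
  expect_equal(expected_vaf(0.6, 1.0, "diploid_het"), 0.3)
  # allele on the lost haplotype at purity 0.6: (1-p)*1 / (p*1 + (1-p)*2)
  expect_equal(expected_vaf(0.6, 1.0, "loh_lost"), 0.4 / 1.4, tolerance = 1e-12)
  expect_equal(expected_vaf(0.6, 1.0, "loh_retained"), 1 / 1.4, tolerance = 1e-12)
  # retained + lost BAFs are complementary at full CCF
  p <- runif(5, 0.2, 0.9)
  expect_equal(expected_vaf(p, 1, "loh_retained") + expected_vaf(p, 1, "loh_lost"),
               rep(1, 5), tolerance = 1e-12)
  expect_error(expected_vaf(0.5, 1, "triploid"), "copy_state")
  expect_error(expected_vaf(0, 1), "purity")
})

test_that("read-count sampling respects the binomial model and the seed", {
  set.seed(1)
  z <- sample_read_counts(rep(0, 50))
  expect_true(all(z$tumor_alt == 0))
  expect_true(all(z$alt_fw + z$alt_rv == z$tumor_alt))
  expect_true(all(z$ref_fw + z$ref_rv == z$tumor_depth - z$tumor_alt))

  # near-deterministic depth -> alt fraction concentrates around 0.5
  set.seed(2)
  z2 <- sample_read_counts(rep(0.5, 200), depth_mean = 10000,
                           depth_size = 1e9)
  frac_in <- mean(abs(z2$tumor_alt / z2$tumor_depth - 0.5) <= 0.02)
  expect_gt(frac_in, 0.95)

  set.seed(99); a <- sample_read_counts(c(0.1, 0.4))
  set.seed(99); b <- sample_read_counts(c(0.1, 0.4))
  expect_identical(a, b)
})

test_that("context draws carry the configured signature mass", {
  cfg <- sim_config()
  set.seed(5)
  pole <- draw_context_channel("pole", 1000, cfg)
  expect_gte(sum(pole$channel %in% c("TCT>TAT", "TCG>TTG")), 700)

  set.seed(6)
  tr <- draw_context_channel("truncal", 2000, cfg)
  cpg <- grepl("^.CG>.TG$", tr$channel)
  expect_equal(mean(cpg), cfg$truncal_cpg_mass, tolerance = 0.05)

  ch <- channels96()
  expect_equal(nrow(ch), 96)
  expect_true(all(tr$channel %in% ch$channel))
  expect_true(all(draw_context_channel("private", 500, cfg)$channel %in%
                    ch$channel))
  expect_error(draw_context_channel("odd", 1, cfg), "unknown")
})

test_that("caller detection follows the configured sensitivity curves", {
  cfg <- sim_config()
  ev <- clean_calls(500)
  ev$context <- "ACA"; ev$gene <- "GEN001"; ev$truth_id <- sprintf("M%03d", 1:500)
  ev$qual_per_depth <- 10
  # VAF 0.5 under every default profile: detection essentially certain
  ev$tumor_depth <- 200L; ev$tumor_alt <- 100L
  ev$alt_fw <- 50L; ev$alt_rv <- 50L; ev$ref_fw <- 50L; ev$ref_rv <- 50L
  for (pr in names(cfg$caller_profiles)) {
    prof <- cfg$caller_profiles[[pr]]
    # curve evaluation: detection probability at VAF 0.5 is at least 0.99
    expect_gte(prof$plateau * plogis((0.5 - prof$v50) / prof$slope), 0.99)
    # and the empirical rate over 500 seeded draws sits within 3 binomial SE
    set.seed(10)
    called <- emulate_caller(ev, prof, cfg)
    expect_gte(nrow(called) / 500, 0.99 - 3 * sqrt(0.99 * 0.01 / 500))
  }
  # VAF 0.02 under the steep G-like profile: mostly missed
  ev$tumor_alt <- 4L; ev$alt_fw <- 2L; ev$alt_rv <- 2L
  ev$ref_fw <- 98L; ev$ref_rv <- 98L
  set.seed(11)
  called <- emulate_caller(ev, cfg$caller_profiles$G, cfg)
  expect_lt(nrow(called) / 500, 0.2)
})

test_that("perfect-caller mode reproduces the truth exactly", {
  cfg <- sim_config(n_patients = 1, seed = 21, perfect_callers = TRUE,
                    pole_patient = NA, depth_mean = 5000)
  set.seed(21)
  p <- simulate_patient(cfg, "P01")
  truth_p <- p$truth[p$truth$ccf_primary > 0, ]
  for (cl in c("G", "L", "M")) {
    calls <- p$primary_calls[[cl]]
    expect_setequal(calls$truth_id, truth_p$mutation_id)
    expect_true(all(is.na(calls$artifact)))
  }
})

test_that("every emitted call maps to the truth or is a flagged artifact", {
  cfg <- sim_config(n_patients = 2, seed = 31, artifact_rate = 3,
                    pole_patient = NA)
  coh <- simulate_cohort(cfg)
  for (p in coh$patients) {
    for (calls in c(p$primary_calls, p$met_calls)) {
      ok <- !is.na(calls$truth_id) | !is.na(calls$artifact)
      expect_true(all(ok))
      real <- calls[!is.na(calls$truth_id), ]
      expect_true(all(real$truth_id %in% p$truth$mutation_id))
    }
  }
})

test_that("clonal truth invariants hold and private VAFs sit below truncal", {
  cfg <- sim_config(n_patients = 6, seed = 41)
  truth <- cohort_truth(simulate_cohort(cfg))
  tr <- truth[truth$clone == "truncal", ]
  expect_true(all(tr$ccf_primary == 1 & tr$ccf_met == 1))
  pp <- truth[truth$clone == "primary_private", ]
  expect_true(all(pp$ccf_met == 0) && all(pp$ccf_primary > 0))
  pm <- truth[truth$clone == "metastasis_private", ]
  expect_true(all(pm$ccf_primary == 0) && all(pm$ccf_met > 0))
  expect_lt(median(pp$evaf_primary), median(tr$evaf_primary))
  expect_lt(median(pm$evaf_met), median(tr$evaf_met))
  expect_true(all(substr(truth$context, 2, 2) == truth$ref))
})

test_that("the caller union is at least as sensitive as each single caller", {
  cfg <- sim_config(n_patients = 4, seed = 51, pole_patient = NA)
  coh <- simulate_cohort(cfg)
  for (p in coh$patients) {
    truth_ids <- p$truth$mutation_id[p$truth$ccf_primary > 0]
    sens <- vapply(p$primary_calls, function(x) {
      mean(truth_ids %in% x$truth_id)
    }, numeric(1))
    union_ids <- unique(unlist(lapply(p$primary_calls, function(x) x$truth_id)))
    expect_gte(mean(truth_ids %in% union_ids), max(sens))
  }
})

test_that("identical configuration regenerates an identical cohort", {
  cfg <- sim_config(n_patients = 2, seed = 61)
  a <- cohort_truth(simulate_cohort(cfg))
  b <- cohort_truth(simulate_cohort(cfg))
  expect_identical(a, b)
})
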