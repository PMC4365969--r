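test_that("shared/private classification is disjoint and exhaustive", {
  cls <- classify_shared_private(c("A", "B", "C"), c("B", "C", "D"))
  expect_setequal(cls$shared, c("B", "C"))
  expect_equal(cls$private_primary, "A")
  expect_equal(cls$private_met, "D")
  expect_length(intersect(cls$shared, cls$private_primary), 0)

  same <- classify_shared_private(c("A", "B"), c("A", "B"))
  expect_length(same$private_primary, 0)
  expect_length(same$private_met, 0)

  expect_error(classify_shared_private(character(), character()),
               "no evaluable tumor")
})

test_that("patient rows satisfy the concordance count identities", {
  set.seed(13)
  cfg <- sim_config(n_patients = 4, seed = 13, pole_patient = NA)
  coh <- simulate_cohort(cfg)
  for (p in coh$patients) {
    row <- patient_summary(p$patient_id, p$primary_calls$L, p$met_calls$L)
    expect_equal(row$n_total_primary, row$n_shared + row$n_private_primary)
    expect_equal(row$n_total_met, row$n_shared + row$n_private_met)
    expect_equal(row$n_distinct,
                 row$n_shared + row$n_private_primary + row$n_private_met)
    expect_equal(row$pct_primary_in_met,
                 100 * row$n_shared / row$n_total_primary)
    expect_equal(row$pct_met_in_primary,
                 100 * row$n_shared / row$n_total_met)
  }
})

test_that("cohort summary is invariant to row order and right for one row", {
  rows <- fixture_concordance_rows()
  cs1 <- cohort_summary(rows)
  cs2 <- cohort_summary(rows[sample(nrow(rows)), ])
  expect_equal(cs1, cs2)

  one <- cohort_summary(rows[1, ])
  expect_equal(unname(one$medians["pct_primary_in_met"]),
               rows$pct_primary_in_met[1])
  expect_equal(unname(one$totals["n_shared"]), rows$n_shared[1])
})

test_that("VAF group statistics: means, null case and simulated separation", {
  gs <- vaf_group_stats(c(0.2, 0.4), c(0.1))
  expect_equal(gs$mean_shared, 0.3)
  expect_equal(gs$mean_private, 0.1)

  same <- vaf_group_stats(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_gt(same$p_value, 0.5)

  expect_true(is.na(vaf_group_stats(numeric(), c(0.1))$p_value))

  # simulated cohorts: shared mean VAF above private mean in both tissues
  wins <- 0L
  for (seed in 1:10) {
    coh <- simulate_cohort(sim_config(n_patients = 5, seed = 100 + seed,
                                      pole_patient = NA,
                                      perfect_callers = TRUE))
    truth <- cohort_truth(coh)
    sh <- truth$evaf_primary[truth$clone == "truncal"]
    pr <- truth$evaf_primary[truth$clone == "primary_private"]
    if (length(pr) > 0 && mean(sh) > mean(pr)) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("recurrence analysis flags multi-patient genes and detects enrichment", {
  cv <- tibble::tibble(
    patient_id = c("P1", "P2", "P1"),
    gene = c("X", "X", "Y"),
    shared = c(TRUE, TRUE, FALSE)
  )
  ra <- recurrence_analysis(cv)
  expect_true(ra$gene_counts$recurrent[ra$gene_counts$gene == "X"])
  expect_false(ra$gene_counts$recurrent[ra$gene_counts$gene == "Y"])

  # margins of the published recurrence table: 634/786 recurrent variants
  # shared versus 106/145 among non-recurrent; enrichment OR > 1
  rec <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 393),
    gene = paste0("R", seq_len(786) %% 40),
    shared = rep(c(TRUE, FALSE), c(634, 152))
  )
  non <- tibble::tibble(
    patient_id = "P1",
    gene = paste0("U", seq_len(145)),
    shared = rep(c(TRUE, FALSE), c(106, 39))
  )
  ra2 <- recurrence_analysis(dplyr::bind_rows(rec, non))
  oracle <- fisher.test(matrix(c(634, 152, 106, 39), 2, byrow = TRUE))
  expect_gt(ra2$odds_ratio, 1)
  expect_equal(ra2$p_value, oracle$p.value, tolerance = 1e-8)
  expect_equal(ra2$pct_recurrent_shared, 100 * 634 / 786, tolerance = 1e-9)
})

test_that("gene-subset concordance rejects degenerate splits and recovers construction", {
  cv <- tibble::tibble(
    gene = c(rep("A", 10), rep("B", 10)),
    shared = c(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
    in_met = TRUE
  )
  sc <- subset_concordance(cv, "A")
  expect_equal(sc$pct_subset, 100)
  expect_equal(sc$pct_complement, 50)
  expect_error(subset_concordance(cv, c("A", "B")), "split")
  expect_error(subset_concordance(cv, character()), "empty")
})

test_that("scatter data covers every distinct variant with zero-filled VAFs", {
  p <- mini_scatter <- variant_tbl(chrom = "1", pos = 1:3, ref = "C", alt = "T",
                                   tumor_depth = 100L,
                                   tumor_alt = c(50L, 20L, 10L))
  m <- variant_tbl(chrom = "1", pos = 2:4, ref = "C", alt = "T",
                   tumor_depth = 100L, tumor_alt = c(25L, 10L, 40L))
  sc <- vaf_scatter_data("P01", p, m)
  expect_equal(nrow(sc), 4)
  expect_equal(sc$vaf_primary[sc$key == "1:1:C:T"], 0.5)
  expect_equal(sc$vaf_met[sc$key == "1:1:C:T"], 0)
  expect_equal(sc$vaf_met[sc$key == "1:4:C:T"], 0.4)
  expect_setequal(sc$status[sc$key %in% c("1:2:C:T", "1:3:C:T")], "shared")
})
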