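test_that("homopolymer run length matches direct counting", {
  expect_equal(homopolymer_run_length("ACGTACGTACG", 6), 1L)   # no run
  expect_equal(homopolymer_run_length("TTAAAAAATTG", 6), 6L)   # inside a run
  # variant base sandwiched between two 5-runs: flanking runs count
  expect_equal(homopolymer_run_length("GGGGGTCCCCC", 6), 5L)
  expect_error(homopolymer_run_length("AC", 1), "short")
  expect_error(homopolymer_run_length("ACGTACGTACG", 20), "outside")
})

test_that("homopolymer run length agrees with a brute-force scan", {
  set.seed(42)
  for (i in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T"), 11, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    expect_equal(homopolymer_run_length(w, 6), oracle_hp_run(w, 6), info = w)
  }
})

test_that("each site filter fires on its own criterion", {
  x <- clean_calls(1)
  x$tumor_depth <- 4L; x$tumor_alt <- 3L; x$alt_fw <- 2L; x$alt_rv <- 1L
  x$ref_fw <- 1L; x$ref_rv <- 0L
  out <- apply_site_filters(x)
  expect_false(out$site_pass)
  expect_equal(out$site_reasons, "depth")

  # two otherwise-clean variants 4 bases apart: both flagged
  y <- apply_site_filters(clean_calls(2, pos = c(100L, 104L)))
  expect_equal(y$site_reasons, c("window5", "window5"))
  expect_equal(y$filter, c("window5", "window5"))

  # mapping-quality rule is strict: exactly 30.0 passes
  z <- clean_calls(2)
  z$mq <- c(30.0, 29.99)
  out <- apply_site_filters(z)
  expect_equal(out$site_pass, c(TRUE, FALSE))
  expect_equal(out$site_reasons[2], "mapping_quality")

  # strand bias: -0.10 passes (strict >), above fails
  s <- clean_calls(2)
  s$sb <- c(-0.10, -0.05)
  expect_equal(apply_site_filters(s)$site_pass, c(TRUE, FALSE))

  # homopolymer windows: run of 6 fails, run of 5 passes
  h <- clean_calls(2)
  h$hp_window <- c("TAAAAAATGCA", "TTAAAAATGCA")  # runs of 6 and 5 at center
  out <- apply_site_filters(h)
  expect_equal(out$site_reasons[1], "homopolymer")
  expect_true(out$site_pass[2])

  expect_error(apply_site_filters(clean_calls(1)[, setdiff(names(clean_calls(1)), "sb")]),
               "sb")
})

test_that("somatic filters use the published boundary conventions", {
  # all three at their boundary values: QD = 3 inclusive, alt > 2 strict,
  # normal depth >= 5 inclusive
  x <- clean_calls(1)
  x$qual <- 300; x$tumor_depth <- 100L; x$tumor_alt <- 3L
  x$alt_fw <- 2L; x$alt_rv <- 1L; x$normal_depth <- 5L
  out <- apply_somatic_filters(x)
  expect_true(out$somatic_pass)

  x2 <- x; x2$tumor_alt <- 2L; x2$alt_rv <- 0L
  expect_equal(apply_somatic_filters(x2)$somatic_reasons, "variant_depth")

  x3 <- x; x3$normal_depth <- 4L
  expect_equal(apply_somatic_filters(x3)$somatic_reasons, "normal_depth")

  x4 <- x; x4$qual <- 299
  expect_equal(apply_somatic_filters(x4)$somatic_reasons, "quality_depth")

  x5 <- x; x5$tumor_depth <- 0L; x5$tumor_alt <- 0L
  x5$alt_fw <- 0L; x5$alt_rv <- 0L
  expect_error(apply_somatic_filters(x5), "zero tumor depth")
})

test_that("post-caller filters keep only non-synonymous, non-dbSNP-only calls", {
  x <- clean_calls(4)
  x$consequence <- c("synonymous", "missense", "missense", "nonsense")
  x$dbsnp <- c(FALSE, TRUE, TRUE, FALSE)
  x$cosmic <- c(FALSE, TRUE, FALSE, FALSE)
  out <- post_caller_filters(x)
  # synonymous removed; dbSNP+COSMIC kept; dbSNP-only removed; clean kept
  expect_equal(out$pos, x$pos[c(2, 4)])

  # tumor calls present in the matched normal are removed
  out2 <- post_caller_filters(x, normal_keys = variant_key(x)[4])
  expect_equal(out2$pos, x$pos[2])
})

test_that("filters are idempotent and partition their input", {
  set.seed(7)
  cfg <- sim_config(n_patients = 1, seed = 7, artifact_rate = 6,
                    pole_patient = NA)
  p <- simulate_patient(cfg, "P01")
  g <- p$primary_calls$G
  once <- apply_somatic_filters(apply_site_filters(g))
  twice <- apply_somatic_filters(apply_site_filters(once))
  expect_equal(twice$site_pass, once$site_pass)
  expect_equal(twice$somatic_pass, once$somatic_pass)
  expect_equal(twice$filter, once$filter)
  # partition: all rows kept, pass and fail disjoint and exhaustive
  expect_equal(nrow(once), nrow(g))
  expect_equal(sum(once$site_pass) + sum(!once$site_pass), nrow(g))

  lm <- p$primary_calls$L
  kept <- post_caller_filters(lm)
  expect_equal(nrow(post_caller_filters(kept)), nrow(kept))
})
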