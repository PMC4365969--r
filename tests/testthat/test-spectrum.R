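test_that("canonical channel assignment is strand-symmetric", {
  expect_equal(canonical_channel("C", "T", "ACG"), "ACG>ATG")
  # purine encoding reverse-complements to the same channel
  expect_equal(canonical_channel("G", "A", "CGT"), "ACG>ATG")
  expect_error(canonical_channel("C", "T", "ANG"), "ambiguous")
  expect_error(canonical_channel("C", "T", "AAG"), "middle base")
})

test_that("both strand encodings of all 96 channels map canonically", {
  ch <- channels96()
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  for (i in seq_len(96)) {
    ref <- substr(ch$sub[i], 1, 1); alt <- substr(ch$sub[i], 3, 3)
    expect_equal(canonical_channel(ref, alt, ch$context[i]), ch$channel[i])
    expect_equal(canonical_channel(rc(ref), rc(alt), rc(ch$context[i])),
                 ch$channel[i])
  }
})

test_that("spectra conserve totals and fold strands", {
  empty <- build_spectrum(variant_tbl())
  expect_equal(sum(empty$count), 0)

  x <- variant_tbl(chrom = "1", pos = 1:3, ref = "C", alt = "T",
                   context = "ACG")
  sp <- build_spectrum(x)
  expect_equal(sum(sp$count), 3)
  expect_equal(sp$count[sp$channel == "ACG>ATG"], 3L)

  # full reverse-complement re-encoding leaves the spectrum unchanged
  set.seed(23)
  cfg <- sim_config(n_patients = 2, seed = 23)
  truth <- cohort_truth(simulate_cohort(cfg))
  calls <- validate_variant_tbl(truth[, c("chrom", "pos", "ref", "alt",
                                          "context")])
  rc3 <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  flipped <- calls
  flipped$ref <- rc3(flipped$ref)
  flipped$alt <- rc3(flipped$alt)
  flipped$context <- rc3(flipped$context)
  expect_equal(build_spectrum(flipped)$count, build_spectrum(calls)$count)
})

test_that("channel-class fractions match exhaustive enumeration", {
  ch <- channels96()
  # enumerate: a CpG>TpG channel is C>T with 3' G, leaving the 5' base free,
  # so exactly 4 of the 96 channels (ACG, CCG, GCG, TCG)
  expect_equal(sum(ch$sub == "C>T" & ch$threep == "G"), 4)
  expect_equal(sort(ch$context[ch$sub == "C>T" & ch$threep == "G"]),
               c("ACG", "CCG", "GCG", "TCG"))
  uniform <- ch
  uniform$count <- 1L
  expect_equal(cpg_tpg_fraction(uniform), 4 / 96)
  expect_equal(pole_fraction(uniform), 2 / 96)

  one <- ch; one$count <- ifelse(ch$channel == "ACG>ATG", 5L, 0L)
  expect_equal(cpg_tpg_fraction(one), 1)
  pol <- ch; pol$count <- ifelse(ch$channel == "TCT>TAT", 7L, 0L)
  expect_equal(pole_fraction(pol), 1)
  expect_equal(cpg_tpg_fraction(pol), 0)
  expect_error(cpg_tpg_fraction(dplyr::mutate(ch, count = 0L)), "empty")
})

test_that("spectrum comparison: identical, disjoint and simulated separation", {
  ch <- channels96()
  a <- ch; a$count <- rep(c(3L, 0L), 48)
  expect_equal(compare_spectra(a, a)$cosine, 1)

  b <- ch; b$count <- rep(c(0L, 3L), 48)
  expect_equal(compare_spectra(a, b)$cosine, 0)
  expect_equal(sum(compare_spectra(a, b)$difference$difference), 0,
               tolerance = 1e-12)

  # default truncal and private signature configurations separate clearly
  cfg <- sim_config()
  set.seed(29)
  shared <- draw_context_channel("truncal", 400, cfg)
  private <- draw_context_channel("private", 400, cfg)
  as_calls <- function(d) validate_variant_tbl(
    tibble::tibble(chrom = "1", pos = seq_len(nrow(d)), ref = d$ref,
                   alt = d$alt, context = d$context))
  cmp <- compare_spectra(build_spectrum(as_calls(shared)),
                         build_spectrum(as_calls(private)))
  expect_lt(cmp$cosine, 0.5)
})
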