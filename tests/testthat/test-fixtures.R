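test_that("the per-patient fixture satisfies its count identities", {
  fx <- table2_fixture()
  expect_equal(nrow(fx), 18)
  expect_equal(fx$n_shared + fx$n_private_primary + fx$n_private_met,
               fx$n_distinct)
  # the ultramutant row: 608 + 133 = 741 in the primary, 608 + 264 = 872
  p16 <- fx[fx$patient_id == "P16", ]
  expect_equal(p16$n_shared + p16$n_private_primary, 741)
  expect_equal(p16$n_shared + p16$n_private_met, 872)
  expect_equal(p16$n_distinct, 1005)
  expect_error(expand_fixture(dplyr::mutate(fx, n_distinct = n_distinct + 1)),
               "P01")
})

test_that("expanding and classifying reproduces the printed per-patient rows", {
  rows <- fixture_concordance_rows()
  fx <- table2_fixture()
  expect_equal(rows$n_shared, fx$n_shared)
  expect_equal(rows$n_private_primary, fx$n_private_primary)
  expect_equal(rows$n_private_met, fx$n_private_met)
  expect_equal(rows$n_distinct, fx$n_distinct)

  # spot checks against printed percentages
  p1 <- rows[rows$patient_id == "P01", ]
  expect_equal(round(p1$pct_primary_in_met, 1), 53.8)
  expect_equal(round(p1$pct_met_in_primary, 1), 77.8)
  p8 <- rows[rows$patient_id == "P08", ]
  expect_equal(p8$pct_primary_in_met, 100)
  expect_equal(round(p8$pct_met_in_primary, 1), 83.3)
  expect_true(is.na(p8$mean_vaf_private_primary))
  p15 <- rows[rows$patient_id == "P15", ]
  expect_equal(round(p15$pct_primary_in_met, 2), 17.65)
  expect_equal(p15$pct_met_in_primary, 100)
})

test_that("the validation fixture reproduces the printed marginals", {
  vf <- validation_fixture()
  expect_equal(nrow(vf$presence), 186)
  expect_equal(sum(vf$presence$in_g), 136)
  expect_equal(sum(vf$presence$in_l), 156)
  expect_equal(sum(vf$presence$in_m), 109)
  vp <- venn_partition(vf$presence)
  expect_equal(vp$count[vp$region == "GLM"], 72)
  expect_equal(sum(vp$count[vp$region %in% c("G", "L", "M")]), 43)

  conf <- vf$presence[vf$presence$validation == "confirmed_present", ]
  expect_equal(nrow(conf), 170)
  expect_equal(c(sum(conf$in_g), sum(conf$in_l), sum(conf$in_m)),
               c(129, 149, 96))
  expect_equal(nrow(vf$absence), 35)
  expect_equal(sum(vf$absence$validation == "confirmed_absent"), 34)
})

test_that("union of per-caller fixture slices rebuilds the discovery set", {
  vf <- validation_fixture()
  slice <- function(bit) {
    x <- vf$presence[vf$presence[[bit]], c("chrom", "pos", "ref", "alt")]
    x$tumor_depth <- 100L; x$tumor_alt <- 30L
    validate_variant_tbl(x)
  }
  ic <- union_callsets(slice("in_g"), slice("in_l"), slice("in_m"))
  expect_equal(nrow(ic), 186)
  expect_equal(sum(ic$in_g), 136)
  vp <- venn_partition(ic)
  expect_equal(vp$count[vp$region == "GLM"], 72)
})

test_that("the rendered report matches the published table dialect", {
  rows <- fixture_concordance_rows()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table2_report(rows, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 18 + 1 + 1)  # header, patients, Total, footnote
  expect_match(lines[length(lines)], "79.3")
  expect_match(lines[length(lines)], "81.7")
  # patient 2's empty private-metastasis group renders as NA
  expect_match(lines[3], "0 (NA)", fixed = TRUE)
  # patient 1 row carries the printed cells
  expect_match(lines[2], "7 (31%)", fixed = TRUE)
  expect_match(lines[2], "53.8")
  total <- lines[20]
  expect_match(total, "^Total")
  expect_match(total, "740")
  expect_match(total, "1236")
  expect_error(write_table2_report(rows[0, ], path), "no rows")
})
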