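test_that("delimited parsing masks blank/NA/NaN cells and nothing else", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tfa\tfb",
    "s1\t1.5\t",
    "s2\tNA\t2.5",
    "s3\tnan\t3.5"
  ), f)
  got <- read_metabolite_matrix(f)
  expect_equal(dim(got$matrix), c(3L, 2L))
  expect_equal(sum(missing_mask(got$matrix)), 3L)
  expect_equal(got$matrix$values["s1", "fa"], 1.5)
  expect_identical(got$matrix$scale_tag, "raw")
})

test_that("write/read round-trip is the identity on values, mask and ids", {
  mat <- small_cohort()$matrix
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metabolite_matrix(mat, f)
  back <- read_metabolite_matrix(f)$matrix
  expect_identical(sample_ids(back), sample_ids(mat))
  expect_identical(feature_ids(back), feature_ids(mat))
  expect_identical(missing_mask(back), missing_mask(mat))
  expect_equal(back$values, mat$values, tolerance = 1e-9)
})

test_that("parse errors are informative: duplicates, non-numeric, negative", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfa", "s1\t1", "s1\t2"), f)
  expect_error(read_metabolite_matrix(f), "duplicate")
  writeLines(c("id\tfa", "s1\t1", "s2\tbogus"), f)
  expect_error(read_metabolite_matrix(f), "s2.*fa")
  writeLines(c("id\tfa", "s1\t-3", "s2\t2"), f)
  expect_error(read_metabolite_matrix(f), "negative")
})

test_that("features-in-rows orientation transposes and splits annotations", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "feature_id\tsuper_pathway\tnamed_flag\ts1\ts2",
    "fa\tLipid\ttrue\t1\t2",
    "fb\tAmino Acid\tfalse\t3\t4"
  ), f)
  got <- read_metabolite_matrix(f, orientation = "features_in_rows")
  expect_identical(sample_ids(got$matrix), c("s1", "s2"))
  expect_identical(feature_ids(got$matrix), c("fa", "fb"))
  expect_identical(got$annotations$named_flag, c(TRUE, FALSE))
  expect_identical(got$annotations$super_pathway, c("Lipid", "Amino Acid"))
})

test_that("taxa rows renormalize and the load joins by sample id", {
  m <- matrix(c(2, 2, 0, 1, 1, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  tt <- taxa_table(m, total_load = c(s1 = 1000))
  expect_equal(unname(tt$rel_abundance["s1", ]), c(0.5, 0.5, 0))
  expect_equal(unname(tt$total_load), c(1000, NA))
  expect_error(taxa_table(rbind(m, s3 = c(0, 0, 0))), "all-zero")
  expect_warning(taxa_table(m, total_load = c(s1 = 10, zz = 5)), "not in table")
})

test_that("taxa table write/read round-trips", {
  taxa <- small_cohort()$taxa
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_taxa_table(taxa, f1, f2)
  back <- read_taxa_table(f1, f2)
  expect_equal(back$rel_abundance, taxa$rel_abundance, tolerance = 1e-9)
  expect_equal(back$total_load, taxa$total_load, tolerance = 1e-9)
})

test_that("metadata validation enforces the outcome/GAB contract", {
  md <- toy_metadata(10)
  expect_s3_class(cohort_metadata(md), "tbl_df")
  bad <- md
  bad$gab_weeks[1] <- 39 # sPTB at term
  expect_error(cohort_metadata(bad), "mismatch")
  dup <- md
  dup$sample_id[2] <- dup$sample_id[1]
  expect_error(cohort_metadata(dup), "duplicate")
})

test_that("write_report: schema, empty input, JSON round-trip, bad format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- tibble::tibble(feature_id = character(), p = numeric())
  write_report(empty, f, "tsv")
  expect_identical(readLines(f), "feature_id\tp")

  ch <- small_cohort()
  assoc <- association_scan(ch$matrix, ch$metadata, strata = "all")
  write_report(assoc, f, "tsv")
  back <- read_report(f)
  expect_identical(names(back), names(assoc))
  expect_equal(back$p, assoc$p, tolerance = 1e-8)

  fj <- withr::local_tempfile(fileext = ".json")
  rep <- list(auroc = 0.8123456789, n = 10L, outcome = "sPTB")
  write_report(rep, fj, "json")
  expect_equal(jsonlite::read_json(fj, simplifyVector = TRUE), rep,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(write_report(empty, f, "xml"), "unknown report format")
})
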