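test_that("count_table enforces its invariants", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ct <- count_table(m)
  expect_identical(ct$total_reads, rowSums(m))
  expect_error(count_table(matrix(c(-5L, 1L, 1L, 1L), 2, 2,
                                  dimnames = list(c("s1", "s2"), c("a", "b")))),
               "negative count")
  expect_error(count_table(matrix(1L, 2, 2,
                                  dimnames = list(c("s1", "s1"), c("a", "b")))),
               "duplicate sample")
  expect_error(count_table(matrix(c(0L, 0L, 1L, 0L), 2, 2, byrow = TRUE,
                                  dimnames = list(c("s1", "s2"), c("a", "b")))),
               "zero total reads")
})

test_that("Bracken reports merge over the species union", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_bracken_fixture(f1, "speciesA", 100L)
  write_bracken_fixture(f2, c("speciesA", "speciesB"), c(50L, 10L))
  ct <- read_bracken_reports(c(f1, f2), c("s1", "s2"))
  expect_equal(unname(ct$counts),
               matrix(c(100, 0, 50, 10), 2, 2, byrow = TRUE))
  expect_identical(ct$species_names, c("speciesA", "speciesB"))
})

test_that("non-species rows are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bracken_fixture(f, c("speciesA", "Genus1"), c(100L, 30L),
                        lvl = c("S", "G"))
  expect_warning(ct <- read_bracken_reports(f, "s1"), "non-species")
  expect_identical(ct$species_names, "speciesA")
  expect_equal(unname(ct$counts[1, 1]), 100)
})

test_that("a missing Bracken column is a format error naming file and column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bracken_fixture(f, "speciesA", 100L, drop_col = "new_est_reads")
  expect_error(read_bracken_reports(f, "s1"), "new_est_reads")
})

test_that("merging is order-independent up to sample order", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_bracken_fixture(f1, c("a", "b"), c(5L, 7L))
  write_bracken_fixture(f2, c("b", "c"), c(2L, 9L))
  ct12 <- read_bracken_reports(c(f1, f2), c("s1", "s2"))
  ct21 <- read_bracken_reports(c(f2, f1), c("s2", "s1"))
  expect_equal(ct12$counts, ct21$counts[c("s1", "s2"), ])
})

test_that("count matrix TSV round-trips bit-exactly and respects orientation", {
  m <- matrix(sample.int(1000, 12), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("sp", 1:4)))
  ct <- count_table(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(ct, f, seed = 42)
  back <- read_count_matrix(f, "samples_in_rows")
  expect_identical(back$counts, ct$counts)
  expect_match(readLines(f, n = 1), "^# gmci .*seed=42")

  ft <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(species = colnames(m), t(m), check.names = FALSE)
  write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_count_matrix(ft, "species_in_rows")$counts, ct$counts)
})

test_that("bad cells are validation errors with coordinates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ta\tb", "s1\t-5\t2", "s2\t1\t1"), f)
  expect_error(read_count_matrix(f), "s1.*'a'")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ta\tb", "s1\tx\t2", "s2\t1\t1"), f2)
  expect_error(read_count_matrix(f2), "non-numeric")
})

test_that("metadata validation enforces the closed enums and matching", {
  ok <- data.frame(sample_id = c("p1", "h1"), group = c("breast", "HC"),
                   cohort = "breast", sex = "F", age = c(50, 54))
  expect_s3_class(sample_metadata(ok), "sample_metadata")
  bad <- ok; bad$group[1] <- "kidney"
  expect_error(sample_metadata(bad), "kidney")
  orphan <- ok[1, ]
  expect_error(sample_metadata(orphan), "no healthy-control")
  bad_sex <- ok; bad_sex$sex[1] <- "X"
  expect_error(sample_metadata(bad_sex), "sex")
})

test_that("samples missing from metadata are a reconciliation error", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("p1", "p2"), c("a", "b")))
  meta <- sample_metadata(data.frame(sample_id = c("p1", "h1"),
                                     group = c("CRC", "HC"), cohort = "CRC",
                                     sex = "M", age = 60))
  expect_error(reconcile_samples(count_table(m), meta), "p2")
})

test_that("metabolite tables require the full 16-metabolite panel", {
  ids <- c("s1", "s2")
  m <- make_metab_fixture(ids)
  mt <- metabolite_table(m)
  expect_identical(mt$metabolite_names, metabolite_names())
  expect_error(metabolite_table(m[, -match("formic", colnames(m))]), "formic")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metabolites(mt, f)
  expect_equal(read_metabolites(f)$concentrations, mt$concentrations)
})
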