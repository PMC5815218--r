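write_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

fixture_header <- paste(
  "study_accession", "pubmed_id", "publication_date", "stage",
  "number_of_individuals", "broad_ancestral_category",
  "detailed_ancestry_description", "country_of_recruitment",
  "country_of_origin", "additional_ancestry_description",
  sep = "\t"
)

test_that("the reader parses stages, sizes, dates and multi-valued cells", {
  path <- write_fixture(c(
    fixture_header,
    paste("GCST000001", "11111111", "2010-05-01", "initial", "2000",
      "East Asian", "Han Chinese", "China", "", "self-reported",
      sep = "\t"
    ),
    paste("GCST000001", "11111111", "2010-05-01", "Replication", "800",
      "East Asian", "Han Chinese", "China", "", "",
      sep = "\t"
    ),
    paste("GCST000002", "22222222", "2012-11-30", "initial", "1500",
      "European, East Asian", "Dutch and Japanese individuals",
      "Netherlands, Japan", "", "",
      sep = "\t"
    )
  ))
  rec <- read_ancestry_tsv(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$stage, c("initial", "replication", "initial"))
  expect_equal(rec$n_individuals, c(2000L, 800L, 1500L))
  expect_equal(rec$publication_date[3], as.Date("2012-11-30"))
  expect_equal(rec$categories[[3]], c("European", "East Asian"))
  expect_equal(rec$country_of_recruitment[[3]], c("Netherlands", "Japan"))
})

test_that("a category name containing commas survives the cell dialect", {
  gme <- "Greater Middle Eastern (Middle Eastern, North African, or Persian)"
  path <- write_fixture(c(
    fixture_header,
    paste("GCST000009", "33333333", "2014-01-01", "initial", "500",
      paste(gme, "European", sep = ", "), "Iranian and Swedish", "Iran, Sweden",
      "", "",
      sep = "\t"
    )
  ))
  rec <- read_ancestry_tsv(path)
  expect_equal(rec$categories[[1]], c(gme, "European"))
})

test_that("rows without a category cell go through the classification cascade", {
  path <- write_fixture(c(
    fixture_header,
    paste("GCST000003", "33333333", "2013-01-01", "initial", "100",
      "", "Han Chinese", "", "", "",
      sep = "\t"
    ),
    paste("GCST000004", "44444444", "2013-01-01", "initial", "100",
      "", "", "Japan", "", "",
      sep = "\t"
    ),
    paste("GCST000005", "55555555", "2013-01-01", "initial", "100",
      "", "", "", "", "",
      sep = "\t"
    )
  ))
  rec <- read_ancestry_tsv(path)
  expect_equal(rec$categories[[1]], "East Asian")
  expect_equal(rec$categories[[2]], "East Asian")
  expect_equal(rec$categories[[3]], "Not reported")
})

test_that("reader errors name the offending rows and columns", {
  bad_int <- write_fixture(c(
    fixture_header,
    paste("GCST000001", "1", "2010-01-01", "initial", "12x4", "European",
      "", "", "", "",
      sep = "\t"
    )
  ))
  err <- expect_error(read_ancestry_tsv(bad_int),
    class = "ancestrycat_malformed_integer"
  )
  expect_match(conditionMessage(err), "row\\(s\\) 1")
  expect_match(conditionMessage(err), "12x4")

  bad_cat <- write_fixture(c(
    fixture_header,
    paste("GCST000001", "1", "2010-01-01", "initial", "10", "Vulcan",
      "", "", "", "",
      sep = "\t"
    )
  ))
  err <- expect_error(read_ancestry_tsv(bad_cat),
    class = "ancestrycat_unknown_category"
  )
  expect_match(conditionMessage(err), "row 1")

  no_col <- write_fixture(c(
    "study_accession\tpubmed_id",
    "GCST000001\t1"
  ))
  expect_error(read_ancestry_tsv(no_col), class = "ancestrycat_missing_column")
})

test_that("write/read round trip preserves every field, including commas in text", {
  rec <- random_samples(100, seed = 7)
  path <- tempfile(fileext = ".tsv")
  write_ancestry_tsv(rec, path)
  back <- read_ancestry_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec))

  # commas in descriptions are preserved verbatim (TSV, not CSV)
  keep <- grepl(",", rec$detailed_description)
  expect_true(any(keep))
  expect_identical(back$detailed_description[keep], rec$detailed_description[keep])

  # empty record list yields a header-only file
  empty_path <- tempfile(fileext = ".tsv")
  write_ancestry_tsv(rec[0, ], empty_path)
  expect_length(readLines(empty_path), 1L)
  expect_equal(nrow(read_ancestry_tsv(empty_path)), 0L)
})

test_that("association files round trip with optional annotations", {
  assoc <- tibble::tibble(
    association_id = c("A1", "A2", "A3"),
    study_accession = c("GCST000001", "GCST000001", "GCST000002"),
    trait = c("type 2 diabetes", "type 2 diabetes", "height"),
    ancestry_annotation = list("European", character(0), c("European", "East Asian"))
  )
  path <- tempfile(fileext = ".tsv")
  write_associations_tsv(assoc, path)
  back <- read_associations_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(assoc))
})

test_that("the display form renders size, categories and recruitment countries", {
  expect_equal(
    format_category_string(2000, "East Asian", "China"),
    "2,000 East Asian (China)"
  )
  expect_equal(format_category_string(0, "Not reported"), "0 Not reported")
  expect_equal(
    format_category_string(1500, c("European", "East Asian"), c("UK", "Japan")),
    "1,500 European, East Asian (UK, Japan)"
  )
})
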