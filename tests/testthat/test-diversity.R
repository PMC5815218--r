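toy_catalog <- function() {
  # 5 studies: 3 European-only, 1 East-Asian-only, 1 spanning two categories
  mk <- function(acc, cats, n = 100L, year = 2012) {
    sample_row(
      description = "", categories = list(cats), n_individuals = n,
      accession = acc
    ) |>
      dplyr::mutate(publication_date = as.Date(sprintf("%d-06-01", year)))
  }
  dplyr::bind_rows(
    mk("GCST000001", "European"),
    mk("GCST000002", "European"),
    mk("GCST000003", "European"),
    mk("GCST000004", "East Asian"),
    mk("GCST000005", c("European", "East Asian"))
  )
}

test_that("a single-category study gives a 100% single-label distribution", {
  s <- sample_row(description = "", categories = list("European"), n_individuals = 100L)
  rep <- distribution_by_category(s, level = "individuals")
  expect_equal(rep$label, "European")
  expect_equal(rep$percentage, 100)
  expect_equal(attr(rep, "n_total"), 100)
})

test_that("the toy catalog splits 60/20/20 at the study level", {
  rep <- distribution_by_category(toy_catalog(), level = "studies")
  shares <- stats::setNames(rep$percentage, rep$label)
  expect_equal(shares[["European"]], 60)
  expect_equal(shares[["East Asian"]], 20)
  expect_equal(shares[["multiple"]], 20)
})

test_that("counts sum to N and percentages to 100 at every level", {
  cat <- generate_catalog(sim_config(n_studies = 300, seed = 5))
  for (lv in c("individuals", "studies", "associations")) {
    rep <- distribution_by_category(cat$samples, cat$associations, level = lv)
    expect_equal(sum(rep$count), attr(rep, "n_total"))
    expect_equal(sum(rep$percentage), 100, tolerance = 1e-9)
  }
  n_studies <- length(unique(cat$samples$study_accession))
  rep_s <- distribution_by_category(cat$samples, level = "studies")
  expect_equal(sum(rep_s$count), n_studies)
})

test_that("small catalogs agree exactly with brute-force enumeration", {
  for (seed in 1:50) {
    n <- 1 + (seed %% 10)
    cat <- generate_catalog(sim_config(n_studies = n, seed = seed))
    for (lv in c("individuals", "studies", "associations")) {
      both <- compare_to_naive(cat$samples, cat$associations, lv)
      expect_equal(both$got, both$want, label = sprintf("seed %d level %s", seed, lv))
    }
  }
})

test_that("adding a European-only study never decreases the European study count", {
  base <- toy_catalog()
  before <- distribution_by_category(base, level = "studies")
  extra <- sample_row(
    description = "", categories = list("European"), accession = "GCST000099"
  )
  after <- distribution_by_category(dplyr::bind_rows(base, extra), level = "studies")
  cnt <- function(r) sum(r$count[r$label == "European"])
  expect_gte(cnt(after), cnt(before))
  expect_equal(cnt(after), cnt(before) + 1)
})

test_that("supergroup maps collapse labels before percentaging", {
  cat <- generate_catalog(sim_config(n_studies = 200, seed = 9))
  plain <- distribution_by_category(cat$samples, level = "individuals")
  grouped <- distribution_by_category(cat$samples,
    level = "individuals",
    supergroup_map = default_supergroup_map()
  )
  asian_members <- default_supergroup_map()$Asian
  expect_equal(
    sum(grouped$count[grouped$label == "Asian"]),
    sum(plain$count[plain$label %in% asian_members])
  )
  expect_false(any(asian_members %in% grouped$label))
  expect_equal(sum(grouped$percentage), 100, tolerance = 1e-9)
})

test_that("windows filter on publication year inclusively", {
  cat <- generate_catalog(sim_config(n_studies = 200, seed = 13))
  yr <- as.integer(format(cat$samples$publication_date, "%Y"))
  early <- unique(cat$samples$study_accession[yr <= 2010])
  rep <- distribution_by_category(cat$samples,
    level = "studies",
    window = window_spec(2005, 2010)
  )
  expect_equal(sum(rep$count), length(early))
  expect_error(window_spec(2012, 2005), class = "ancestrycat_invalid_window")
})

test_that("identical windows give fold 1 for every represented label", {
  cat <- generate_catalog(sim_config(n_studies = 150, seed = 21))
  cw <- compare_windows(cat$samples,
    level = "studies",
    window_a = c(2005, 2016), window_b = c(2005, 2016)
  )
  nonzero <- cw$pct_a > 0
  expect_true(all(cw$fold[nonzero] == 1))
  # labels absent from window A report an undefined fold, not infinity
  expect_true(all(is.na(cw$fold[!nonzero])))
})

test_that("associations inherit study labels unless annotated, and dangling ids error", {
  samples <- toy_catalog()
  assoc <- tibble::tibble(
    association_id = c("A1", "A2", "A3"),
    study_accession = c("GCST000005", "GCST000005", "GCST000001"),
    trait = "height",
    ancestry_annotation = list("East Asian", character(0), character(0))
  )
  rep <- distribution_by_category(samples, assoc, level = "associations")
  shares <- stats::setNames(rep$count, rep$label)
  expect_equal(shares[["East Asian"]], 1) # annotated association
  expect_equal(shares[["multiple"]], 1) # inherited from two-category study
  expect_equal(shares[["European"]], 1)

  bad <- assoc
  bad$study_accession[1] <- "GCST999999"
  expect_error(
    distribution_by_category(samples, bad, level = "associations"),
    class = "ancestrycat_dangling_accession"
  )
  expect_error(distribution_by_category(samples, NULL, level = "associations"))
})

test_that("trait breadth counts descriptions, categories, studies and associations", {
  samples <- dplyr::bind_rows(
    sample_row(description = "Han Chinese", categories = list("East Asian"), accession = "GCST000001"),
    sample_row(description = "Japanese", categories = list("East Asian"), accession = "GCST000002"),
    sample_row(description = "Yoruban", categories = list("Sub-Saharan African"), accession = "GCST000003")
  )
  assoc <- tibble::tibble(
    association_id = sprintf("A%d", 1:5),
    study_accession = c(
      "GCST000001", "GCST000001", "GCST000002", "GCST000003", "GCST000003"
    ),
    trait = c(rep("type 2 diabetes", 4), "height"),
    ancestry_annotation = replicate(5, character(0), simplify = FALSE)
  )
  tb <- trait_breadth(samples, assoc, "Type 2 Diabetes")
  expect_equal(tb$n_detailed_descriptions, 3L)
  expect_equal(tb$n_categories, 2L)
  expect_equal(tb$n_studies, 3L)
  expect_equal(tb$n_associations, 4L)

  single <- trait_breadth(samples, assoc, "height")
  expect_equal(single$n_studies, 1L)
  expect_equal(single$n_associations, 1L)
  expect_equal(single$n_categories, 1L)

  expect_error(trait_breadth(samples, assoc, "unicorn allergy"),
    class = "ancestrycat_unknown_trait"
  )

  # synthetic bookkeeping: association totals per trait match the generator
  cat <- generate_catalog(sim_config(n_studies = 100, seed = 31))
  for (tr in unique(cat$associations$trait)[1:3]) {
    tb <- trait_breadth(cat$samples, cat$associations, tr)
    expect_equal(tb$n_associations, sum(cat$associations$trait == tr))
    expect_equal(
      tb$n_studies,
      length(unique(cat$associations$study_accession[cat$associations$trait == tr]))
    )
  }
})
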