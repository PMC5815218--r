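test_that("descriptor normalization folds case, punctuation and whitespace", {
  expect_equal(normalize_descriptor("  Han  Chinese. "), "han chinese")
  expect_equal(normalize_descriptor(""), "")
  expect_equal(normalize_descriptor("African-American"), "african american")
  expect_equal(normalize_descriptor(NA), "")
})

test_that("descriptors classify through lexicon, labels, and codes", {
  expect_equal(classify_descriptor("Han Chinese")$categories, "East Asian")
  expect_equal(classify_descriptor("Yoruban")$categories, "Sub-Saharan African")
  expect_equal(classify_descriptor("Surinamese")$categories, "Other")
  expect_equal(classify_descriptor("CEU")$categories, "European")

  sikh <- classify_descriptor("Punjabi Sikh")
  expect_equal(sikh$categories, "South Asian")
  expect_equal(sikh$tier, "lexicon")
  expect_true(any(sikh$matched_terms$ethnocultural))

  expect_error(classify_descriptor("Klingon warriors"),
    class = "ancestrycat_unclassified"
  )
  expect_equal(classify_descriptor("")$tier, "not-reported")
  expect_equal(classify_descriptor("   .  ")$tier, "not-reported")
})

test_that("multi-term descriptors match the exhaustive n-gram oracle", {
  cases <- c(
    "European and Japanese",
    "Chinese and Yoruban samples",
    "Caucasian plus Korean individuals",
    "Brazilian, Thai"
  )
  for (txt in cases) {
    expect_setequal(classify_descriptor(txt)$categories, all_ngram_categories(txt))
  }
  expect_setequal(
    classify_descriptor("European and Japanese")$categories,
    c("European", "East Asian")
  )
})

test_that("longest match wins over embedded shorter terms", {
  # "African American" must not decompose into "African" + "American"
  expect_equal(
    classify_descriptor("African American")$categories,
    "African American or Afro-Caribbean"
  )
  expect_equal(classify_descriptor("African")$categories, "African unspecified")
  expect_equal(classify_descriptor("Pima Indian")$categories, "Native American")
  expect_equal(classify_descriptor("Indian")$categories, "South Asian")
})

test_that("the whole shipped lexicon is self-consistent", {
  lex <- ancestry_lexicon()
  for (i in seq_len(nrow(lex))) {
    expect_equal(
      classify_descriptor(lex$descriptor[i])$categories,
      lex$category[i],
      label = sprintf("classify('%s')", lex$descriptor[i])
    )
  }
  # example descriptors from the category table behave the same way
  cats <- ancestry_categories()
  for (i in seq_len(nrow(cats))) {
    for (ex in cats$example_descriptors[[i]]) {
      expect_equal(
        classify_descriptor(ex)$categories, cats$name[i],
        label = sprintf("classify('%s')", ex)
      )
    }
  }
})

test_that("country inference follows the shipped country table exactly", {
  expect_equal(infer_from_country("Japan")$categories, "East Asian")
  expect_equal(infer_from_country("Japan")$tier, "country-inferred")
  us <- infer_from_country("United States")
  expect_equal(us$categories, "Not reported")
  expect_equal(us$tier, "not-reported")
  expect_error(infer_from_country("Narnia"), class = "ancestrycat_unknown_country")

  # oracle: direct table lookup for every shipped country
  tbl <- ancestry_countries()
  for (i in seq_len(nrow(tbl))) {
    expect_equal(
      infer_from_country(tbl$country[i])$categories[1],
      tbl$inferred_category[i],
      label = tbl$country[i]
    )
  }
  # ISO codes resolve too
  expect_equal(infer_from_country("JP")$categories, "East Asian")
})

test_that("the classification cascade honors its precedence order", {
  # (1) reference population beats everything
  r <- classify_sample(
    author_category = "East Asian", description = "Yoruban",
    population_codes = "CEU", country_of_recruitment = "Japan"
  )
  expect_equal(r$categories, "European")
  expect_equal(r$tier, "reference-population")

  # (2) author-stated beats descriptor and country
  r <- classify_sample(
    author_category = "South Asian", description = "Han Chinese",
    country_of_recruitment = "Japan"
  )
  expect_equal(r$categories, "South Asian")
  expect_equal(r$tier, "author-stated")

  # (3) descriptor beats country
  r <- classify_sample(description = "Han Chinese", country_of_recruitment = "Nigeria")
  expect_equal(r$categories, "East Asian")
  expect_equal(r$tier, "lexicon")

  # (4) country fallback
  r <- classify_sample(country_of_recruitment = "Japan")
  expect_equal(r$categories, "East Asian")
  expect_equal(r$tier, "country-inferred")

  # (5) nothing at all
  r <- classify_sample()
  expect_equal(r$categories, "Not reported")
  expect_equal(r$tier, "not-reported")

  # unresolvable rungs fall through instead of erroring
  r <- classify_sample(
    author_category = "Klingon", description = "mystery cohort zzz",
    country_of_recruitment = "Narnia"
  )
  expect_equal(r$categories, "Not reported")
})

test_that("worked cascade examples behave as published", {
  expect_equal(classify_sample(population_codes = "CEU")$categories, "European")
  expect_equal(classify_sample()$categories, "Not reported")

  adm <- classify_sample(
    description = "admixed individuals of European and East Asian descent"
  )
  expect_equal(adm$categories, "Other admixed ancestry")
  expect_setequal(adm$admixture_components, c("European", "East Asian"))

  amish <- classify_sample(description = "Old Order Amish")
  expect_equal(amish$categories, "European")
  expect_true(any(amish$matched_terms$isolate))
})

test_that("admixture keywords respect defined admixed categories and genomic evidence", {
  # an already-admixed category is kept, components recorded
  r <- classify_sample(description = "admixed African American with European ancestry")
  expect_equal(r$categories, "African American or Afro-Caribbean")
  expect_true("European" %in% r$admixture_components)

  # genomic evidence is never overridden by the keyword
  r <- classify_sample(description = "admixed sample", population_codes = "CEU")
  expect_equal(r$categories, "European")
  expect_equal(r$tier, "reference-population")

  # a bare admixture statement is still information
  r <- classify_sample(description = "admixed individuals")
  expect_equal(r$categories, "Other admixed ancestry")
})

test_that("classification is deterministic and a population code never lowers the tier", {
  tier_rank <- function(t) {
    match(t, c(
      "not-reported", "country-inferred", "lexicon", "author-stated",
      "reference-population"
    ))
  }
  grid <- expand.grid(
    author = c(NA, "European"),
    desc = c("", "Han Chinese", "mystery zzz"),
    country = c(NA, "Japan", "United States"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    base_args <- list(
      author_category = if (is.na(g$author)) NULL else g$author,
      description = g$desc,
      country_of_recruitment = if (is.na(g$country)) NULL else g$country
    )
    r1 <- do.call(classify_sample, base_args)
    r2 <- do.call(classify_sample, base_args)
    expect_identical(r1, r2)
    r3 <- do.call(classify_sample, c(base_args, list(population_codes = "JPT")))
    expect_gte(tier_rank(r3$tier), tier_rank(r1$tier))
  }
})
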