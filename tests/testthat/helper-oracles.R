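# Independent oracles and fixture builders. These deliberately re-derive
# results with plain loops over the exported seed tables, so they share no
# code path with the implementation they check.

# every n-gram (any position, n <= max_n) of the text that matches a seed
# term, with the category it maps to
all_ngram_categories <- function(text, max_n = 4) {
  cats <- ancestry_categories()
  lex <- ancestry_lexicon()
  term_map <- c(
    stats::setNames(lex$category, normalize_descriptor(lex$descriptor)),
    stats::setNames(
      rep(cats$name, lengths(cats$example_descriptors)),
      normalize_descriptor(unlist(cats$example_descriptors))
    ),
    stats::setNames(cats$name, normalize_descriptor(cats$name)),
    stats::setNames(
      rep(cats$name, lengths(cats$synonyms)),
      normalize_descriptor(unlist(cats$synonyms))
    ),
    stats::setNames(
      rep(cats$name, lengths(cats$reference_populations)),
      tolower(unlist(cats$reference_populations))
    )
  )
  toks <- strsplit(normalize_descriptor(text), " ", fixed = TRUE)[[1]]
  found <- character(0)
  for (i in seq_along(toks)) {
    for (j in i:min(i + max_n - 1, length(toks))) {
      frag <- paste(toks[i:j], collapse = " ")
      if (frag %in% names(term_map)) found <- c(found, term_map[[frag]])
    }
  }
  unique(found)
}

naive_label <- function(cats) {
  core <- unique(cats[cats != "Not reported"])
  if (length(core) == 0) {
    "Not reported"
  } else if (length(core) == 1) {
    core
  } else {
    "multiple"
  }
}

# brute-force enumeration of the category distribution, plain loops
naive_distribution <- function(samples, associations = NULL, level) {
  counts <- c()
  add <- function(lbl, w) {
    if (is.null(counts[lbl]) || is.na(counts[lbl])) counts[lbl] <<- 0
    counts[lbl] <<- counts[lbl] + w
  }
  if (level == "individuals") {
    for (i in seq_len(nrow(samples))) {
      w <- samples$n_individuals[i]
      add(naive_label(samples$categories[[i]]), ifelse(is.na(w), 0, w))
    }
  } else if (level == "studies") {
    for (acc in unique(samples$study_accession)) {
      cc <- unlist(samples$categories[samples$study_accession == acc])
      add(naive_label(cc), 1)
    }
  } else {
    study_lab <- list()
    for (acc in unique(samples$study_accession)) {
      cc <- unlist(samples$categories[samples$study_accession == acc])
      study_lab[[acc]] <- naive_label(cc)
    }
    for (i in seq_len(nrow(associations))) {
      ann <- associations$ancestry_annotation[[i]]
      lbl <- if (length(ann) > 0) {
        naive_label(ann)
      } else {
        study_lab[[associations$study_accession[i]]]
      }
      add(lbl, 1)
    }
  }
  out <- data.frame(label = names(counts), count = as.numeric(counts))
  out$percentage <- 100 * out$count / sum(out$count)
  out[order(out$label), ]
}

compare_to_naive <- function(samples, associations, level) {
  got <- distribution_by_category(samples, associations, level = level)
  got <- as.data.frame(got)[, c("label", "count", "percentage")]
  got <- got[order(got$label), ]
  want <- naive_distribution(samples, associations, level)
  rownames(got) <- rownames(want) <- NULL
  list(got = got, want = want)
}

# random sample records exercising the full TSV dialect (multi-category
# cells, commas in free text, missing sizes, confidentiality flags)
random_samples <- function(n, seed) {
  set.seed(seed)
  cats <- setdiff(ancestry_categories()$name, "Not reported")
  ctry <- ancestry_countries()$country
  descs <- c(
    "Han Chinese",
    "cohort of adults, recruited 1998-2004",
    "",
    "Old Order Amish individuals of European descent",
    "population-based sample; urban, semi-rural"
  )
  tibble::tibble(
    study_accession = sprintf("GCST%06d", sample(1:500, n, replace = TRUE)),
    pubmed_id = as.character(sample(10000000:20000000, n, replace = TRUE)),
    publication_date = as.Date("2005-01-01") + sample(0:4000, n, replace = TRUE),
    stage = sample(c("initial", "replication"), n, replace = TRUE),
    n_individuals = ifelse(stats::runif(n) < 0.05, NA_integer_,
      sample(10:50000, n, replace = TRUE)
    ),
    categories = replicate(n, {
      if (stats::runif(1) < 0.05) "Not reported" else sample(cats, sample(1:2, 1))
    }, simplify = FALSE),
    detailed_description = sample(descs, n, replace = TRUE),
    country_of_recruitment = replicate(n, sample(ctry, sample(0:2, 1)),
      simplify = FALSE
    ),
    country_of_origin = replicate(n, character(0), simplify = FALSE),
    additional_description = sample(c("", "self-reported", "inferred, PCA"),
      n,
      replace = TRUE
    ),
    confidential = stats::runif(n) < 0.02
  )
}

# a fully specified, recommendation-clean sample row
clean_sample <- function(accession = "GCST000001") {
  tibble::tibble(
    study_accession = accession,
    pubmed_id = "12345678",
    publication_date = as.Date("2015-06-01"),
    stage = "initial",
    n_individuals = 2500L,
    categories = list("Sub-Saharan African"),
    detailed_description = "Yoruban",
    country_of_recruitment = list("Nigeria"),
    country_of_origin = list("Nigeria"),
    additional_description = "self-reported and confirmed by principal component analysis",
    confidential = FALSE
  )
}

sample_row <- function(description = "", categories = list("Not reported"),
                       n_individuals = 1000L, country = character(0),
                       additional = "self-reported", confidential = FALSE,
                       accession = "GCST000001") {
  tibble::tibble(
    study_accession = accession,
    pubmed_id = "11111111",
    publication_date = as.Date("2012-01-15"),
    stage = "initial",
    n_individuals = n_individuals,
    categories = categories,
    detailed_description = description,
    country_of_recruitment = list(country),
    country_of_origin = list(character(0)),
    additional_description = additional,
    confidential = confidential
  )
}
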