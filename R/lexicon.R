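# Descriptor lexicon, country table, and the deterministic classification
# cascade turning free-text sample metadata into ancestry categories.

#' The descriptor lexicon
#'
#' Seed table of detailed ancestry descriptors with their category
#' assignments, plus flags marking socio-cultural (ethnocultural) terms such
#' as "Punjabi Sikh" and founder/isolate populations such as "Old Order
#' Amish". The shipped file is a curated seed subset covering common
#' descriptors; it is a plain TSV and can be extended or replaced via
#' `config`. Example descriptors from the category table are merged in at
#' classification time, so the lexicon file only needs descriptors that are
#' not already listed there.
#'
#' @param config Optional path to an alternative lexicon TSV with columns
#'   `descriptor`, `category`, `ethnocultural`, `isolate`,
#'   `admixture_components` (the last `|`-separated).
#' @param categories Category table used to validate assignments.
#' @return A tibble with columns `descriptor`, `category`, `ethnocultural`,
#'   `isolate` (logicals) and list-column `admixture_components`.
#' @export
ancestry_lexicon <- function(config = NULL, categories = ancestry_categories()) {
  if (is.null(config) && !is.null(the$lexicon)) {
    return(the$lexicon)
  }
  path <- config %||% anc_file("ancestry_lexicon.tsv")
  raw <- read_seed_tsv(path, c(
    "descriptor", "category", "ethnocultural", "isolate", "admixture_components"
  ))
  lex <- tibble(
    descriptor = raw$descriptor,
    category = raw$category,
    ethnocultural = as_flag(raw$ethnocultural),
    isolate = as_flag(raw$isolate),
    admixture_components = split_multi(raw$admixture_components)
  )
  bad <- setdiff(lex$category, categories$name)
  if (length(bad) > 0) {
    abort(sprintf(
      "Lexicon '%s' assigns unknown categories: %s",
      path, paste(unique(bad), collapse = ", ")
    ))
  }
  norm <- normalize_descriptor(lex$descriptor)
  if (anyDuplicated(norm)) {
    abort(sprintf(
      "Lexicon descriptors must be unique after normalization; duplicated: %s",
      paste(unique(lex$descriptor[duplicated(norm)]), collapse = ", ")
    ))
  }
  if (is.null(config)) the$lexicon <- lex
  lex
}

#' The recruitment-country table
#'
#' Seed table mapping countries of recruitment to UN M49 regions and to the
#' ancestry category inferred when a publication reports only the location
#' of recruitment. Countries whose resident population is demographically
#' heterogeneous (e.g. the United States) deliberately map to
#' `"Not reported"` rather than to any single category. The shipped file is
#' a curated seed subset (about 95 common recruitment countries) built from
#' demographic-majority reasoning; extend or replace it via `config`.
#'
#' @param config Optional path to an alternative TSV with columns `country`,
#'   `iso2`, `un_region`, `inferred_category`.
#' @param categories Category table used to validate assignments.
#' @return A tibble with those four character columns.
#' @export
ancestry_countries <- function(config = NULL, categories = ancestry_categories()) {
  if (is.null(config) && !is.null(the$countries)) {
    return(the$countries)
  }
  path <- config %||% anc_file("recruitment_countries.tsv")
  tbl <- read_seed_tsv(path, c("country", "iso2", "un_region", "inferred_category"))
  if (anyDuplicated(normalize_descriptor(tbl$country))) {
    abort(sprintf("Duplicate countries in '%s'", path))
  }
  bad <- setdiff(tbl$inferred_category, categories$name)
  if (length(bad) > 0) {
    abort(sprintf(
      "Country table '%s' assigns unknown categories: %s",
      path, paste(unique(bad), collapse = ", ")
    ))
  }
  if (is.null(config)) the$countries <- tbl
  tbl
}

#' Cohort names that must not be read as ancestry descriptors
#'
#' Seed list of study-cohort names (e.g. "TwinsUK") whose geographic flavour
#' must not be used as a substitute for ancestry. Used by the linter.
#'
#' @param config Optional path to an alternative single-column TSV (`cohort`).
#' @return Character vector of cohort names.
#' @export
cohort_names <- function(config = NULL) {
  if (is.null(config) && !is.null(the$cohorts)) {
    return(the$cohorts)
  }
  path <- config %||% anc_file("cohort_names.tsv")
  out <- read_seed_tsv(path, "cohort")$cohort
  if (is.null(config)) the$cohorts <- out
  out
}

# ---------------------------------------------------------------------------
# term matching

# Unified match table. priority 1 = lexicon (incl. example descriptors),
# 2 = category names/synonyms, 3 = reference-population codes. Lower wins
# among equal-length fragments.
match_table <- function(categories = ancestry_categories(),
                        lexicon = ancestry_lexicon(categories = categories)) {
  default <- identical(categories, the$categories) &&
    identical(lexicon, the$lexicon)
  if (default && !is.null(the$match_table)) {
    return(the$match_table)
  }
  lex_part <- tibble(
    term = normalize_descriptor(lexicon$descriptor),
    category = lexicon$category,
    priority = 1L,
    ethnocultural = lexicon$ethnocultural,
    isolate = lexicon$isolate,
    components = lexicon$admixture_components
  )
  ex_part <- tibble(
    term = normalize_descriptor(unlist(categories$example_descriptors)),
    category = rep(categories$name, lengths(categories$example_descriptors)),
    priority = 1L,
    ethnocultural = FALSE,
    isolate = FALSE,
    components = list(character(0))
  )
  name_part <- tibble(
    term = c(
      normalize_descriptor(categories$name),
      normalize_descriptor(unlist(categories$synonyms))
    ),
    category = c(categories$name, rep(categories$name, lengths(categories$synonyms))),
    priority = 2L,
    ethnocultural = FALSE,
    isolate = FALSE,
    components = list(character(0))
  )
  code_part <- tibble(
    term = tolower(unlist(categories$reference_populations)),
    category = rep(categories$name, lengths(categories$reference_populations)),
    priority = 3L,
    ethnocultural = FALSE,
    isolate = FALSE,
    components = list(character(0))
  )
  mt <- bind_rows(lex_part, ex_part, name_part, code_part)
  mt <- mt[nzchar(mt$term), ]
  mt <- mt[order(mt$priority), ]
  conflict <- mt |>
    dplyr::distinct(.data$term, .data$priority, .data$category) |>
    dplyr::count(.data$term, .data$priority) |>
    filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    abort(sprintf(
      "Ambiguous terms map to multiple categories at equal priority: %s",
      paste(conflict$term, collapse = ", ")
    ))
  }
  mt <- mt[!duplicated(mt$term), ]
  mt$n_tokens <- lengths(strsplit(mt$term, " ", fixed = TRUE))
  if (default) the$match_table <- mt
  mt
}

# Longest-match left-to-right scan of normalized n-grams (n <= max_n) against
# the match table. Ties on length break toward lower priority number.
scan_terms <- function(text, mt, max_n = 4L) {
  toks <- strsplit(normalize_descriptor(text), " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  hits <- list()
  i <- 1L
  while (i <= length(toks)) {
    found <- NULL
    for (n in seq(min(max_n, length(toks) - i + 1L), 1L)) {
      frag <- paste(toks[i:(i + n - 1L)], collapse = " ")
      row <- mt[mt$term == frag, ]
      if (nrow(row) > 0) {
        found <- row[1, ]
        found$fragment <- frag
        found$n_used <- n
        break
      }
    }
    if (is.null(found)) {
      i <- i + 1L
    } else {
      hits[[length(hits) + 1L]] <- found
      i <- i + found$n_used
    }
  }
  if (length(hits) == 0) {
    return(tibble(
      term = character(0), category = character(0), priority = integer(0),
      ethnocultural = logical(0), isolate = logical(0),
      components = list(), n_tokens = integer(0),
      fragment = character(0), n_used = integer(0)
    ))
  }
  bind_rows(hits)
}

# ---------------------------------------------------------------------------
# classification results

tier_levels <- c(
  "not-reported", "country-inferred", "lexicon", "author-stated",
  "reference-population"
)

new_classification <- function(categories, tier,
                               matched_terms = empty_matches(),
                               admixture_components = character(0)) {
  stopifnot(tier %in% tier_levels, length(categories) > 0)
  if ("Not reported" %in% categories && length(categories) > 1) {
    abort("'Not reported' cannot be combined with other categories")
  }
  structure(
    list(
      categories = unname(categories),
      tier = tier,
      matched_terms = matched_terms,
      admixture_components = unname(admixture_components)
    ),
    class = "ancestry_classification"
  )
}

empty_matches <- function() {
  tibble(
    fragment = character(0), matched = character(0), category = character(0),
    source = character(0), ethnocultural = logical(0), isolate = logical(0)
  )
}

#' @export
print.ancestry_classification <- function(x, ...) {
  cat(paste(x$categories, collapse = ", "), sprintf("[tier: %s]", x$tier), "\n")
  if (length(x$admixture_components) > 0) {
    cat("  admixture components:", paste(x$admixture_components, collapse = ", "), "\n")
  }
  if (nrow(x$matched_terms) > 0) {
    cat(
      "  matched:",
      paste(sprintf("'%s' -> %s", x$matched_terms$fragment, x$matched_terms$category),
        collapse = "; "
      ), "\n"
    )
  }
  invisible(x)
}

matches_from_scan <- function(scan) {
  tibble(
    fragment = scan$fragment,
    matched = scan$term,
    category = scan$category,
    source = c("lexicon", "category-label", "population-code")[scan$priority],
    ethnocultural = scan$ethnocultural,
    isolate = scan$isolate
  )
}

#' Classify a free-text ancestry descriptor
#'
#' Looks up normalized n-grams of the descriptor (longest match first,
#' left-to-right, up to four tokens) against, in order of precedence, the
#' descriptor lexicon, the category names and synonyms, and the
#' reference-population codes. Several disjoint matches yield a
#' multi-category result (e.g. `"European and Japanese"`). A descriptor in
#' which nothing matches raises an `ancestrycat_unclassified` error carrying
#' the input — never a silent assignment to `"Other"`, since `Other` means a
#' curator judged the descriptor known but unclassifiable. Empty input
#' yields a `Not reported` result instead.
#'
#' @param text The descriptor string.
#' @param categories,lexicon Seed tables (see [ancestry_categories()],
#'   [ancestry_lexicon()]).
#' @return An `ancestry_classification`: a list with `categories`, `tier`,
#'   `matched_terms`, `admixture_components`.
#' @examples
#' classify_descriptor("Han Chinese")$categories
#' classify_descriptor("European and Japanese")$categories
#' @export
classify_descriptor <- function(text,
                                categories = ancestry_categories(),
                                lexicon = ancestry_lexicon(categories = categories)) {
  norm <- normalize_descriptor(text)
  if (!nzchar(norm)) {
    return(new_classification("Not reported", "not-reported"))
  }
  mt <- match_table(categories, lexicon)
  scan <- scan_terms(text, mt)
  if (nrow(scan) == 0) {
    abort(
      sprintf("Unclassified descriptor: '%s' (no lexicon, category, or code match)", text),
      class = "ancestrycat_unclassified",
      descriptor = text
    )
  }
  cats <- unique(scan$category)
  components <- unique(unlist(scan$components))
  new_classification(
    cats, "lexicon",
    matched_terms = matches_from_scan(scan),
    admixture_components = components
  )
}

#' Infer an ancestry category from a country of recruitment
#'
#' Fallback used when the only available information is where participants
#' were recruited: the country's demographic-majority category is taken from
#' the recruitment-country table. Countries tabled as `"Not reported"`
#' (demographically heterogeneous) yield a not-reported result.
#'
#' @param country Country name (or ISO 3166-1 alpha-2 code).
#' @param countries Country table (see [ancestry_countries()]).
#' @param categories Category table.
#' @return An `ancestry_classification` with tier `"country-inferred"` (or
#'   `"not-reported"`).
#' @examples
#' infer_from_country("Japan")$categories
#' @export
infer_from_country <- function(country,
                               countries = ancestry_countries(),
                               categories = ancestry_categories()) {
  if (length(country) != 1 || is.na(country) || !nzchar(trimws(country))) {
    abort("`country` must be a single non-empty string",
      class = "ancestrycat_unknown_country"
    )
  }
  key <- normalize_descriptor(country)
  idx <- normalize_descriptor(countries$country)
  hit <- which(idx == key | tolower(countries$iso2) == key)
  if (length(hit) == 0) {
    abort(
      sprintf(
        "Unknown country '%s'. Nearest candidates: %s",
        country, paste(nearest_terms(key, countries$country), collapse = ", ")
      ),
      class = "ancestrycat_unknown_country"
    )
  }
  entry <- countries[hit[1], ]
  matched <- tibble(
    fragment = country, matched = entry$country, category = entry$inferred_category,
    source = "country", ethnocultural = FALSE, isolate = FALSE
  )
  if (entry$inferred_category == "Not reported") {
    new_classification("Not reported", "not-reported", matched_terms = matched)
  } else {
    new_classification(entry$inferred_category, "country-inferred",
      matched_terms = matched
    )
  }
}

admixture_keyword <- function(text) {
  grepl("\\b(admixed|admixture|mixed ancestry)\\b", normalize_descriptor(text))
}

#' Classify one sample through the full curation precedence cascade
#'
#' Evidence is used in decreasing order of trust: (1) reference-population
#' codes, the genomic evidence, outrank everything; (2) an author-stated
#' category label; (3) lexicon classification of the detailed description;
#' (4) category inference from the country of recruitment; (5) otherwise
#' `Not reported`. The tier of the winning rung is recorded in the result so
#' downstream users can see how much to trust each assignment. The cascade
#' is total: unresolvable descriptors or countries fall through to the next
#' rung rather than erroring.
#'
#' If the description signals admixture ("admixed", "admixture", "mixed
#' ancestry") and the current result is not already one of the defined
#' admixed categories, the sample is assigned `Other admixed ancestry` and
#' the categories matched in the description are kept as its admixture
#' components. Reference-population evidence is never overridden by the
#' keyword.
#'
#' @param author_category Optional author-stated category label(s).
#' @param description Free-text detailed ancestry description.
#' @param population_codes Character vector of reference-population codes
#'   the sample genetically clusters with.
#' @param country_of_recruitment Optional country name(s); several countries
#'   with conflicting inferred categories fall through to `Not reported`.
#' @param categories,lexicon,countries Seed tables.
#' @return An `ancestry_classification`.
#' @examples
#' classify_sample(population_codes = "CEU")$categories
#' classify_sample(description = "admixed individuals of European and East Asian descent")
#' @export
classify_sample <- function(author_category = NULL,
                            description = "",
                            population_codes = character(0),
                            country_of_recruitment = NULL,
                            categories = ancestry_categories(),
                            lexicon = ancestry_lexicon(categories = categories),
                            countries = ancestry_countries(categories = categories)) {
  description <- if (is.null(description) || is.na(description[1])) "" else description[1]
  res <- NULL

  codes <- population_codes[!is.na(population_codes) & nzchar(population_codes)]
  if (length(codes) > 0) {
    rows <- lapply(codes, function(cd) {
      tryCatch(category_for_population_code(cd, categories),
        ancestrycat_unknown_code = function(e) NULL
      )
    })
    hit <- !vapply(rows, is.null, logical(1))
    if (any(hit)) {
      catnames <- vapply(rows[hit], function(r) r$name, character(1))
      res <- new_classification(
        unique(catnames), "reference-population",
        matched_terms = tibble(
          fragment = codes[hit], matched = toupper(codes[hit]),
          category = catnames, source = "population-code",
          ethnocultural = FALSE, isolate = FALSE
        )
      )
    }
  }

  if (is.null(res) && !is.null(author_category)) {
    labels <- author_category[!is.na(author_category) & nzchar(trimws(author_category))]
    if (length(labels) > 0) {
      rows <- lapply(labels, function(lb) {
        tryCatch(resolve_category_label(lb, categories),
          ancestrycat_unknown_label = function(e) NULL
        )
      })
      if (!any(vapply(rows, is.null, logical(1)))) {
        cats <- unique(vapply(rows, function(r) r$name, character(1)))
        core <- setdiff(cats, "Not reported")
        if (length(core) > 0) cats <- core
        res <- new_classification(cats, if (identical(cats, "Not reported")) {
          "not-reported"
        } else {
          "author-stated"
        })
      }
    }
  }

  if (is.null(res) && nzchar(normalize_descriptor(description))) {
    res <- tryCatch(
      classify_descriptor(description, categories, lexicon),
      ancestrycat_unclassified = function(e) NULL
    )
  }

  if (is.null(res) && length(country_of_recruitment) > 0) {
    ctry <- country_of_recruitment[
      !is.na(country_of_recruitment) & nzchar(trimws(country_of_recruitment))
    ]
    if (length(ctry) > 0) {
      inferred <- lapply(ctry, function(cc) {
        tryCatch(infer_from_country(cc, countries, categories),
          ancestrycat_unknown_country = function(e) NULL
        )
      })
      inferred <- inferred[!vapply(inferred, is.null, logical(1))]
      if (length(inferred) > 0) {
        cats <- unique(unlist(lapply(inferred, function(r) r$categories)))
        if (length(cats) == 1 && cats != "Not reported") {
          res <- new_classification(cats, "country-inferred",
            matched_terms = bind_rows(lapply(inferred, function(r) r$matched_terms))
          )
        }
      }
    }
  }

  if (is.null(res)) {
    res <- new_classification("Not reported", "not-reported")
  }

  # admixture adjustment: genomic evidence wins, everything else can be
  # promoted into an admixed assignment when the text says so
  if (admixture_keyword(description) && res$tier != "reference-population") {
    admixed_names <- categories$name[categories$admixed]
    desc_scan <- tryCatch(
      classify_descriptor(description, categories, lexicon),
      ancestrycat_unclassified = function(e) NULL
    )
    matched_cats <- if (!is.null(desc_scan)) desc_scan$categories else character(0)
    components <- setdiff(matched_cats, c(admixed_names, "Not reported"))
    if (any(res$categories %in% admixed_names)) {
      keep <- intersect(res$categories, admixed_names)
      res <- new_classification(keep, res$tier,
        matched_terms = res$matched_terms,
        admixture_components = unique(c(res$admixture_components, components))
      )
    } else {
      if (length(components) == 0) {
        components <- setdiff(res$categories, "Not reported")
      }
      res <- new_classification(
        "Other admixed ancestry",
        if (res$tier == "not-reported") "lexicon" else res$tier,
        matched_terms = res$matched_terms,
        admixture_components = components
      )
    }
  }

  res
}
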