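# Controlled vocabulary of ancestry categories: loading, lookup, OBO export.

#' The controlled vocabulary of ancestry categories
#'
#' Returns the 17 ancestry categories of the framework, in their canonical
#' order, as one row per category. Each category is a distinct regional
#' population grouping with characteristic patterns of genetic variation;
#' three of them (`African American or Afro-Caribbean`,
#' `Hispanic or Latin American`, `Other admixed ancestry`) describe admixed
#' populations, and `Not reported` records the absence of any ancestry or
#' recruitment information. Categories are anchored, where possible, to
#' 1000 Genomes / HapMap reference populations (e.g. CEU for European,
#' YRI for Sub-Saharan African).
#'
#' The vocabulary ships with the package as a human-editable TSV
#' (`system.file("extdata", "ancestry_categories.tsv", package = "ancestrycat")`);
#' pass `config` to load a customized copy (synonyms are extensible, and the
#' same structural checks are applied).
#'
#' @param config Optional path to an alternative category seed TSV with
#'   columns `name`, `parent`, `admixed`, `synonyms`, `reference_populations`,
#'   `example_descriptors`, `definition` (multi-valued cells separated by
#'   `|`).
#' @return A tibble with columns `name`, `definition`, `admixed` (logical),
#'   `parent` (supergroup label or `NA`), and list-columns `synonyms`,
#'   `reference_populations`, `example_descriptors`.
#' @examples
#' cats <- ancestry_categories()
#' cats$name
#' @export
ancestry_categories <- function(config = NULL) {
  if (is.null(config) && !is.null(the$categories)) {
    return(the$categories)
  }
  path <- config %||% anc_file("ancestry_categories.tsv")
  raw <- read_seed_tsv(path, c(
    "name", "parent", "admixed", "synonyms", "reference_populations",
    "example_descriptors", "definition"
  ))
  cats <- tibble(
    name = raw$name,
    definition = raw$definition,
    synonyms = split_multi(raw$synonyms),
    reference_populations = split_multi(raw$reference_populations),
    example_descriptors = split_multi(raw$example_descriptors),
    admixed = as_flag(raw$admixed),
    parent = ifelse(nzchar(raw$parent), raw$parent, NA_character_)
  )
  validate_categories(cats, path)
  if (is.null(config)) the$categories <- cats
  cats
}

validate_categories <- function(cats, path) {
  if (anyDuplicated(cats$name)) {
    abort(sprintf("Duplicate category names in '%s'", path))
  }
  codes <- unlist(cats$reference_populations)
  if (anyDuplicated(toupper(codes))) {
    dup <- codes[duplicated(toupper(codes))]
    abort(sprintf(
      "Reference-population codes must be disjoint across categories; duplicated: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  invisible(cats)
}

# normalized label -> category name index (names + synonyms)
label_index <- function(categories) {
  if (identical(categories, the$categories) && !is.null(the$label_index)) {
    return(the$label_index)
  }
  idx <- tibble(
    term = c(
      normalize_descriptor(categories$name),
      normalize_descriptor(unlist(categories$synonyms))
    ),
    name = c(
      categories$name,
      rep(categories$name, lengths(categories$synonyms))
    )
  )
  idx <- idx[!duplicated(idx$term), ]
  if (identical(categories, the$categories)) the$label_index <- idx
  idx
}

#' Resolve a category label or synonym to its category definition
#'
#' Matching is case- and whitespace-insensitive and covers both canonical
#' category names and their synonyms (e.g. `"Caucasian"` and `"white"`
#' resolve to `European`; `"latino"` resolves to
#' `Hispanic or Latin American`).
#'
#' @param label A single label string.
#' @param categories Category table, as from [ancestry_categories()].
#' @return The one-row tibble for the matching category.
#' @examples
#' resolve_category_label("Caucasian")$name
#' @export
resolve_category_label <- function(label, categories = ancestry_categories()) {
  if (length(label) != 1 || is.na(label) || !nzchar(trimws(label))) {
    abort("`label` must be a single non-empty string",
      class = "ancestrycat_unknown_label"
    )
  }
  key <- normalize_descriptor(label)
  idx <- label_index(categories)
  hit <- idx$name[idx$term == key]
  if (length(hit) == 0) {
    near <- nearest_terms(key, idx$term)
    abort(
      sprintf(
        "Unknown ancestry category label '%s'. Nearest candidates: %s",
        label, paste(near, collapse = ", ")
      ),
      class = "ancestrycat_unknown_label"
    )
  }
  categories[categories$name == hit[[1]], ]
}

#' Look up the ancestry category of a reference-population code
#'
#' Maps a 1000 Genomes / HapMap population code (e.g. `"CEU"`, `"YRI"`,
#' `"JPT"`) to the unique category whose reference populations contain it.
#' Matching is case-insensitive.
#'
#' @param code A single three-letter population code.
#' @inheritParams resolve_category_label
#' @return The one-row tibble for the matching category.
#' @examples
#' category_for_population_code("YRI")$name
#' @export
category_for_population_code <- function(code, categories = ancestry_categories()) {
  if (length(code) != 1 || is.na(code) || !nzchar(trimws(code))) {
    abort("`code` must be a single non-empty string",
      class = "ancestrycat_unknown_code"
    )
  }
  key <- toupper(trimws(code))
  hits <- vapply(
    categories$reference_populations,
    function(v) key %in% toupper(v), logical(1)
  )
  if (!any(hits)) {
    all_codes <- toupper(unlist(categories$reference_populations))
    abort(
      sprintf(
        "Unknown reference-population code '%s'. Known codes: %s",
        code, paste(sort(all_codes), collapse = ", ")
      ),
      class = "ancestrycat_unknown_code"
    )
  }
  categories[hits, ][1, ]
}

#' Default supergroup map for display-level aggregation
#'
#' Supergroups are analysis-time label groupings used for display (for
#' example aggregating East Asian, South Asian, South East Asian, Central
#' Asian and Asian unspecified into "Asian"); they are not categories
#' themselves. The default map is derived from the `parent` column of the
#' category table; pass your own named list of category-name vectors to
#' [distribution_by_category()] to aggregate differently.
#'
#' @inheritParams resolve_category_label
#' @return Named list: supergroup label -> character vector of category names.
#' @examples
#' default_supergroup_map()
#' @export
default_supergroup_map <- function(categories = ancestry_categories()) {
  keep <- !is.na(categories$parent)
  split(categories$name[keep], categories$parent[keep])
}

#' Export the category hierarchy as an OBO 1.4 document
#'
#' Writes one `[Term]` stanza per ancestry category, plus one per supergroup
#' and a single root term. Every non-root term carries exactly one `is_a`
#' edge (category -> its supergroup, or the root when it has none;
#' supergroup -> root), and synonyms are emitted as EXACT synonyms. Term ids
#' are stable: the root takes the first id and the remaining terms are
#' numbered in alphabetical order within a fixed namespace prefix.
#'
#' @inheritParams resolve_category_label
#' @param file Optional path; when given the document is also written there.
#' @param prefix Id namespace prefix (default `"ANC"`).
#' @return The OBO document as a single string (invisibly when `file` is
#'   given).
#' @examples
#' obo <- export_obo()
#' cat(substr(obo, 1, 120))
#' @export
export_obo <- function(categories = ancestry_categories(), file = NULL,
                       prefix = "ANC") {
  root_name <- "ancestry category"
  supers <- sort(unique(categories$parent[!is.na(categories$parent)]))
  others <- sort(c(supers, categories$name))
  ids <- setNames(
    sprintf("%s:%07d", prefix, seq_len(length(others) + 1)),
    c(root_name, others)
  )
  esc <- function(x) gsub("\"", "\\\\\"", x)
  stanza <- function(name, def = NULL, synonyms = character(0), parent = NULL) {
    lines <- c("[Term]", paste0("id: ", ids[[name]]), paste0("name: ", name))
    if (!is.null(def) && nzchar(def)) {
      lines <- c(lines, sprintf("def: \"%s\" []", esc(def)))
    }
    for (s in sort(synonyms)) {
      lines <- c(lines, sprintf("synonym: \"%s\" EXACT []", esc(s)))
    }
    if (!is.null(parent)) {
      lines <- c(lines, sprintf("is_a: %s ! %s", ids[[parent]], parent))
    }
    paste(lines, collapse = "\n")
  }
  stanzas <- c(
    stanza(root_name, def = "A grouping of samples by ancestral background."),
    vapply(supers, function(s) stanza(s, parent = root_name), character(1)),
    vapply(sort(categories$name), function(nm) {
      row <- categories[categories$name == nm, ]
      stanza(
        nm,
        def = row$definition,
        synonyms = row$synonyms[[1]],
        parent = if (is.na(row$parent)) root_name else row$parent
      )
    }, character(1))
  )
  header <- paste0("format-version: 1.4\nontology: ", tolower(prefix))
  doc <- paste0(paste(c(header, stanzas), collapse = "\n\n"), "\n")
  if (!is.null(file)) {
    writeLines(doc, file, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Parse an OBO document produced by [export_obo()]
#'
#' A minimal reader for the subset of OBO 1.4 that [export_obo()] emits,
#' provided so the export can be round-trip checked and re-imported.
#'
#' @param text OBO document as a single string or character vector of lines.
#' @return A tibble with columns `id`, `name`, `synonyms` (list), `is_a`
#'   (parent id or `NA`).
#' @export
parse_obo <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  starts <- which(lines == "[Term]")
  ends <- c(starts[-1] - 1L, length(lines))
  terms <- lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    field <- function(key) {
      sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), block, value = TRUE))
    }
    syn <- field("synonym")
    tibble(
      id = field("id")[1],
      name = field("name")[1],
      synonyms = list(sub("^\"(.*)\" EXACT.*$", "\\1", syn)),
      is_a = if (length(field("is_a")) > 0) {
        sub(" !.*$", "", field("is_a")[1])
      } else {
        NA_character_
      }
    )
  })
  bind_rows(terms)
}
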