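# Readers/writers for the catalog-style ancestry and association TSV
# dialects, and the two-form display rendering.

# pinned column order of the ancestry file dialect
ancestry_tsv_columns <- c(
  "study_accession", "pubmed_id", "publication_date", "stage",
  "number_of_individuals", "broad_ancestral_category",
  "detailed_ancestry_description", "country_of_recruitment",
  "country_of_origin", "additional_ancestry_description", "confidential"
)

association_tsv_columns <- c(
  "association_id", "study_accession", "trait", "ancestry_annotation"
)

empty_samples <- function() {
  tibble(
    study_accession = character(0), pubmed_id = character(0),
    publication_date = as.Date(character(0)), stage = character(0),
    n_individuals = integer(0), categories = list(),
    detailed_description = character(0), country_of_recruitment = list(),
    country_of_origin = list(), additional_description = character(0),
    confidential = logical(0)
  )
}

# Resolve a multi-valued category cell. The delimiter is the comma, but one
# category name legitimately contains commas ("Greater Middle Eastern
# (Middle Eastern, North African, or Persian)"), so segments are consumed
# greedily: at each position the longest run of segments that resolves as a
# single label wins. Returns resolved names, or the offending fragments as
# an "unresolved" attribute.
resolve_label_cell <- function(cell, categories) {
  segs <- split_cell(cell)[[1]]
  out <- character(0)
  unresolved <- character(0)
  i <- 1L
  while (i <= length(segs)) {
    hit <- NULL
    for (j in seq(length(segs), i)) {
      candidate <- paste(segs[i:j], collapse = ", ")
      hit <- tryCatch(resolve_category_label(candidate, categories)$name,
        ancestrycat_unknown_label = function(e) NULL
      )
      if (!is.null(hit)) {
        out <- c(out, hit)
        i <- j + 1L
        break
      }
    }
    if (is.null(hit)) {
      unresolved <- c(unresolved, segs[i])
      i <- i + 1L
    }
  }
  structure(unique(out), unresolved = unresolved)
}

# multi-valued cells: comma separated; " and " accepted on read
split_cell <- function(x) {
  parts <- strsplit(gsub(" and ", ",", ifelse(is.na(x), "", x), fixed = TRUE),
    ",",
    fixed = TRUE
  )
  lapply(parts, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

parse_date_cell <- function(x, rows, path) {
  out <- as.Date(rep(NA, length(x)))
  nz <- nzchar(x)
  for (fmt in c("%Y-%m-%d", "%d-%m-%Y", "%d/%m/%Y")) {
    todo <- nz & is.na(out)
    if (!any(todo)) break
    out[todo] <- as.Date(x[todo], format = fmt)
  }
  bad <- nz & is.na(out)
  if (any(bad)) {
    abort(
      sprintf(
        "Malformed publication_date in '%s' at row(s) %s: %s",
        path, paste(rows[bad], collapse = ", "),
        paste(unique(x[bad]), collapse = ", ")
      ),
      class = "ancestrycat_malformed_date"
    )
  }
  out
}

#' Read a catalog-style ancestry TSV
#'
#' Reads per-sample ancestry records in the download dialect: one row per
#' analyzed sample with study accession, PubMed id, publication date, stage
#' (`initial` / `replication`), number of individuals, broad ancestral
#' category, detailed description, countries of recruitment and origin, and
#' free-text additional description. The pinned column order is the one
#' [write_ancestry_tsv()] emits; see that help page. Files are plain TSV
#' (no quoting), so commas inside descriptions are preserved verbatim;
#' multi-valued category and country cells are comma-separated (`" and "`
#' is also accepted on read).
#'
#' Category cells are resolved through the controlled vocabulary; an
#' unresolvable label is an error naming the offending rows. A row with an
#' empty category cell is classified through the [classify_sample()] cascade
#' from its description and recruitment country, so a row with no ancestry
#' information at all comes back as `Not reported`.
#'
#' @param path Path to the TSV file.
#' @param categories,lexicon,countries Seed tables used for resolution.
#' @return A tibble with columns `study_accession`, `pubmed_id`,
#'   `publication_date` (Date), `stage`, `n_individuals` (integer, `NA` when
#'   missing), `categories` (list of character), `detailed_description`,
#'   `country_of_recruitment` (list), `country_of_origin` (list),
#'   `additional_description`, `confidential` (logical).
#' @export
read_ancestry_tsv <- function(path,
                              categories = ancestry_categories(),
                              lexicon = ancestry_lexicon(categories = categories),
                              countries = ancestry_countries(categories = categories)) {
  raw <- read_seed_tsv(path, setdiff(ancestry_tsv_columns, "confidential"))
  if (nrow(raw) == 0) {
    return(empty_samples())
  }
  rows <- seq_len(nrow(raw))

  nx <- trimws(raw$number_of_individuals)
  bad_n <- nzchar(nx) & !grepl("^[0-9]+$", nx)
  if (any(bad_n)) {
    abort(
      sprintf(
        "Malformed number_of_individuals in '%s' at row(s) %s: %s",
        path, paste(rows[bad_n], collapse = ", "),
        paste(unique(nx[bad_n]), collapse = ", ")
      ),
      class = "ancestrycat_malformed_integer"
    )
  }
  n_individuals <- ifelse(nzchar(nx), suppressWarnings(as.integer(nx)), NA_integer_)

  stage <- tolower(trimws(raw$stage))
  bad_stage <- !stage %in% c("initial", "replication")
  if (any(bad_stage)) {
    abort(
      sprintf(
        "Invalid stage in '%s' at row(s) %s (must be 'initial' or 'replication'): %s",
        path, paste(rows[bad_stage], collapse = ", "),
        paste(unique(raw$stage[bad_stage]), collapse = ", ")
      ),
      class = "ancestrycat_invalid_stage"
    )
  }

  dates <- parse_date_cell(trimws(raw$publication_date), rows, path)

  recr <- split_cell(raw$country_of_recruitment)
  orig <- split_cell(raw$country_of_origin)

  failures <- character(0)
  cats <- vector("list", nrow(raw))
  for (i in rows) {
    cell <- raw$broad_ancestral_category[i]
    if (!nzchar(trimws(ifelse(is.na(cell), "", cell)))) {
      res <- classify_sample(
        description = raw$detailed_ancestry_description[i],
        country_of_recruitment = recr[[i]],
        categories = categories, lexicon = lexicon, countries = countries
      )
      cats[[i]] <- res$categories
    } else {
      resolved <- resolve_label_cell(cell, categories)
      unres <- attr(resolved, "unresolved")
      if (length(unres) > 0) {
        failures <- c(failures, sprintf(
          "row %d: %s", i, paste(unres, collapse = ", ")
        ))
      } else {
        core <- setdiff(as.character(resolved), "Not reported")
        cats[[i]] <- if (length(core) > 0) core else "Not reported"
      }
    }
  }
  if (length(failures) > 0) {
    abort(
      sprintf(
        "Unknown ancestry categories in '%s' (column broad_ancestral_category): %s",
        path, paste(failures, collapse = "; ")
      ),
      class = "ancestrycat_unknown_category"
    )
  }

  confidential <- if ("confidential" %in% names(raw)) {
    as_flag(raw$confidential)
  } else {
    rep(FALSE, nrow(raw))
  }

  tibble(
    study_accession = raw$study_accession,
    pubmed_id = raw$pubmed_id,
    publication_date = dates,
    stage = stage,
    n_individuals = n_individuals,
    categories = cats,
    detailed_description = ifelse(is.na(raw$detailed_ancestry_description), "",
      raw$detailed_ancestry_description
    ),
    country_of_recruitment = recr,
    country_of_origin = orig,
    additional_description = ifelse(is.na(raw$additional_ancestry_description), "",
      raw$additional_ancestry_description
    ),
    confidential = confidential
  )
}

assert_no_tabs <- function(x, what) {
  bad <- grepl("[\t\n]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s must not contain tab or newline characters (rows %s)",
      what, paste(which(bad), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Write a catalog-style ancestry TSV
#'
#' Bit-exact inverse of [read_ancestry_tsv()]: writing a sample table and
#' reading it back reproduces every field. Output is UTF-8 with Unix
#' newlines, unquoted TSV, columns in the pinned order `study_accession`,
#' `pubmed_id`, `publication_date`, `stage`, `number_of_individuals`,
#' `broad_ancestral_category`, `detailed_ancestry_description`,
#' `country_of_recruitment`, `country_of_origin`,
#' `additional_ancestry_description`, `confidential`. Multi-valued cells are
#' joined with `", "`; dates are ISO-8601.
#'
#' @param records Sample tibble as returned by [read_ancestry_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestry_tsv <- function(records, path) {
  assert_no_tabs(records$detailed_description, "detailed_description")
  assert_no_tabs(records$additional_description, "additional_description")
  out <- tibble(
    study_accession = records$study_accession,
    pubmed_id = records$pubmed_id,
    publication_date = ifelse(is.na(records$publication_date), "",
      format(records$publication_date, "%Y-%m-%d")
    ),
    stage = records$stage,
    number_of_individuals = ifelse(is.na(records$n_individuals), "",
      as.character(records$n_individuals)
    ),
    broad_ancestral_category = join_multi(records$categories, ", "),
    detailed_ancestry_description = records$detailed_description,
    country_of_recruitment = join_multi(records$country_of_recruitment, ", "),
    country_of_origin = join_multi(records$country_of_origin, ", "),
    additional_ancestry_description = records$additional_description,
    confidential = ifelse(records$confidential, "TRUE", "FALSE")
  )
  readr::write_tsv(out, path, quote = "none", escape = "none", eol = "\n",
    progress = FALSE
  )
  invisible(path)
}

#' Read an associations TSV
#'
#' One row per variant-trait association: `association_id`,
#' `study_accession`, `trait`, and an optional `ancestry_annotation` holding
#' the category label(s) attached to the association itself (present in
#' multi-ancestry studies, where a single study-level category cannot
#' describe every association). Annotation labels are resolved through the
#' controlled vocabulary.
#'
#' @param path Path to the TSV file.
#' @param categories Category table used to resolve annotations.
#' @return A tibble with columns `association_id`, `study_accession`,
#'   `trait`, `ancestry_annotation` (list of character, `character(0)` when
#'   absent).
#' @export
read_associations_tsv <- function(path, categories = ancestry_categories()) {
  raw <- read_seed_tsv(path, association_tsv_columns)
  failures <- character(0)
  ann <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    cell <- raw$ancestry_annotation[i]
    if (!nzchar(trimws(ifelse(is.na(cell), "", cell)))) {
      ann[[i]] <- character(0)
      next
    }
    resolved <- resolve_label_cell(cell, categories)
    unres <- attr(resolved, "unresolved")
    if (length(unres) > 0) {
      failures <- c(failures, sprintf(
        "row %d: %s", i, paste(unres, collapse = ", ")
      ))
    } else {
      ann[[i]] <- as.character(resolved)
    }
  }
  if (length(failures) > 0) {
    abort(
      sprintf(
        "Unknown ancestry annotations in '%s': %s",
        path, paste(failures, collapse = "; ")
      ),
      class = "ancestrycat_unknown_category"
    )
  }
  tibble(
    association_id = raw$association_id,
    study_accession = raw$study_accession,
    trait = raw$trait,
    ancestry_annotation = ann
  )
}

#' Write an associations TSV
#'
#' Inverse of [read_associations_tsv()]; columns `association_id`,
#' `study_accession`, `trait`, `ancestry_annotation`.
#'
#' @param associations Association tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations_tsv <- function(associations, path) {
  out <- tibble(
    association_id = associations$association_id,
    study_accession = associations$study_accession,
    trait = associations$trait,
    ancestry_annotation = join_multi(associations$ancestry_annotation, ", ")
  )
  readr::write_tsv(out, path, quote = "none", escape = "none", eol = "\n",
    progress = FALSE
  )
  invisible(path)
}

#' Render the display form "sample size, category, (country of recruitment)"
#'
#' Produces the compact string used to display a sample's ancestry next to
#' its study: thousands-separated sample size, the comma-joined categories,
#' and the parenthesized comma-joined countries of recruitment (omitted when
#' none are recorded).
#'
#' @param n_individuals Sample size (single non-negative integer).
#' @param categories Character vector of category names.
#' @param country_of_recruitment Character vector of countries (may be
#'   empty).
#' @return A single string, e.g. `"2,000 East Asian (China)"`.
#' @examples
#' format_category_string(2000, "East Asian", "China")
#' @export
format_category_string <- function(n_individuals, categories,
                                   country_of_recruitment = character(0)) {
  size <- format(as.integer(n_individuals), big.mark = ",", scientific = FALSE)
  out <- paste0(size, " ", paste(categories, collapse = ", "))
  if (length(country_of_recruitment) > 0) {
    out <- paste0(out, " (", paste(country_of_recruitment, collapse = ", "), ")")
  }
  out
}
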