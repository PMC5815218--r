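# Lint rules for ancestry metadata quality, mirroring the reporting
# recommendations for authors, plus catalog-level completeness summaries.

#' The lint rule registry
#'
#' Ten rules, each mapped to one of the reporting recommendations:
#' \describe{
#'   \item{R1 (info)}{Descriptor is a bare broad category label; descriptors
#'     should be as granular as possible (Yoruban rather than Sub-Saharan
#'     African).}
#'   \item{R2 (warning)}{A country name is used as the ancestry descriptor;
#'     country or citizenship is not a substitute for ancestry.}
#'   \item{R3 (warning)}{A cohort name is used as the ancestry descriptor;
#'     geographic flavour in a cohort name (e.g. TwinsUK) cannot be assumed
#'     to imply ancestry.}
#'   \item{R4 (warning)}{Socio-cultural (ethnocultural) descriptor without a
#'     genetic/genealogical qualifier (e.g. "Punjabi Sikh" without "South
#'     Asian").}
#'   \item{R5 (warning)}{Founder/isolate population named without its
#'     broader ancestral background (e.g. "Old Order Amish" without
#'     "European").}
#'   \item{R6 (warning)}{Sample flagged as admixed without naming the
#'     contributing ancestral backgrounds.}
#'   \item{R7 (info)}{No ascertainment method (self-reported / genomically
#'     inferred) recorded.}
#'   \item{R8 (error)}{No ancestry category assigned.}
#'   \item{R9 (error)}{Sample size missing.}
#'   \item{R10 (info)}{Country of recruitment missing.}
#' }
#' R8-R10 are suppressed for records whose `confidential` flag is set, which
#' models an explicit statement that ancestry cannot be disclosed.
#'
#' @return A tibble with columns `rule_id`, `severity`, `summary`.
#' @export
lint_rules <- function() {
  tibble(
    rule_id = paste0("R", 1:10),
    severity = c(
      "info", "warning", "warning", "warning", "warning", "warning",
      "info", "error", "error", "info"
    ),
    summary = c(
      "descriptor no more granular than a broad category label",
      "country name used as ancestry descriptor",
      "cohort name used as ancestry descriptor",
      "ethnocultural descriptor lacks genetic ancestry qualifier",
      "founder/isolate population lacks broader ancestry",
      "admixed sample lacks contributing ancestral backgrounds",
      "ascertainment method not recorded",
      "ancestry category missing",
      "sample size missing",
      "country of recruitment missing"
    )
  )
}

empty_findings <- function() {
  tibble(
    rule_id = character(0), severity = character(0), message = character(0),
    study_accession = character(0), row = integer(0)
  )
}

finding <- function(rule_id, message, accession, row) {
  reg <- lint_rules()
  tibble(
    rule_id = rule_id,
    severity = reg$severity[reg$rule_id == rule_id],
    message = message,
    study_accession = accession,
    row = as.integer(row)
  )
}

ascertainment_pattern <-
  "self report|self identified|pca|principal component|genomic|genotype|inferred|ancestry informative"

#' Lint one sample record against the reporting recommendations
#'
#' Applies the rule registry (see [lint_rules()]) to a single sample row and
#' returns the findings, ordered by rule id. Linting is pure: the same input
#' always produces identical findings.
#'
#' @param sample A one-row sample tibble in the shape produced by
#'   [read_ancestry_tsv()].
#' @param row Row index recorded in the findings (for catalog-level
#'   pointers).
#' @param categories,lexicon,countries,cohorts Seed tables.
#' @return A tibble of findings with columns `rule_id`, `severity`,
#'   `message`, `study_accession`, `row`.
#' @export
lint_sample <- function(sample, row = 1L,
                        categories = ancestry_categories(),
                        lexicon = ancestry_lexicon(categories = categories),
                        countries = ancestry_countries(categories = categories),
                        cohorts = cohort_names()) {
  stopifnot(nrow(sample) == 1)
  acc <- sample$study_accession
  desc <- sample$detailed_description
  desc_norm <- normalize_descriptor(desc)
  extra_norm <- normalize_descriptor(sample$additional_description)
  cats <- sample$categories[[1]]
  out <- list()

  mt <- match_table(categories, lexicon)
  scan <- if (nzchar(desc_norm)) scan_terms(desc, mt) else scan_terms("", mt)

  # R1: the whole descriptor is nothing more than a category name/synonym
  if (nzchar(desc_norm) &&
    desc_norm %in% mt$term[mt$priority == 2L]) {
    out <- c(out, list(finding(
      "R1",
      sprintf("descriptor '%s' is a broad category label; report the most granular descriptor available", desc),
      acc, row
    )))
  }

  # R2: descriptor is a country name
  if (nzchar(desc_norm) &&
    desc_norm %in% normalize_descriptor(countries$country)) {
    out <- c(out, list(finding(
      "R2",
      sprintf("descriptor '%s' is a country; country or citizenship is not a substitute for ancestry", desc),
      acc, row
    )))
  }

  # R3: descriptor contains a known cohort name
  cohort_hit <- vapply(normalize_descriptor(cohorts), function(cn) {
    grepl(paste0("\\b", cn, "\\b"), desc_norm)
  }, logical(1))
  if (any(cohort_hit)) {
    out <- c(out, list(finding(
      "R3",
      sprintf(
        "descriptor '%s' names cohort '%s'; a cohort name cannot be assumed to imply ancestry",
        desc, cohorts[cohort_hit][1]
      ),
      acc, row
    )))
  }

  # R4/R5: ethnocultural or isolate terms need a plain ancestry qualifier
  plain_match <- any(!scan$ethnocultural & !scan$isolate)
  if (any(scan$ethnocultural) && !plain_match) {
    out <- c(out, list(finding(
      "R4",
      sprintf("descriptor '%s' is ethnocultural; also state the underlying genetic ancestry", desc),
      acc, row
    )))
  }
  if (any(scan$isolate) && !plain_match) {
    out <- c(out, list(finding(
      "R5",
      sprintf("descriptor '%s' names a founder/isolate population; also state its broader ancestry", desc),
      acc, row
    )))
  }

  # R6: admixture signalled but components not stated
  admixed_names <- categories$name[categories$admixed]
  admix_signal <- admixture_keyword(desc) || "Other admixed ancestry" %in% cats
  if (admix_signal) {
    comp_scan <- scan_terms(paste(desc, sample$additional_description), mt)
    components <- setdiff(unique(comp_scan$category), c(admixed_names, "Not reported"))
    if (length(components) < 2) {
      out <- c(out, list(finding(
        "R6",
        "admixed sample: name the ancestral backgrounds contributing to the admixture",
        acc, row
      )))
    }
  }

  # R7: ascertainment method
  if (!grepl(ascertainment_pattern, paste(extra_norm, desc_norm))) {
    out <- c(out, list(finding(
      "R7",
      "no ascertainment method recorded (e.g. self-reported, genomically inferred)",
      acc, row
    )))
  }

  if (!isTRUE(sample$confidential)) {
    # R8: category missing
    if (length(cats) == 0 || identical(cats, "Not reported")) {
      out <- c(out, list(finding(
        "R8", "no ancestry category could be assigned", acc, row
      )))
    }
    # R9: sample size missing
    if (is.na(sample$n_individuals)) {
      out <- c(out, list(finding("R9", "sample size missing", acc, row)))
    }
    # R10: country of recruitment missing
    if (length(sample$country_of_recruitment[[1]]) == 0) {
      out <- c(out, list(finding("R10", "country of recruitment missing", acc, row)))
    }
  }

  res <- if (length(out) == 0) empty_findings() else bind_rows(out)
  res[order(match(res$rule_id, lint_rules()$rule_id)), ]
}

#' Lint a whole catalog of sample records
#'
#' Aggregates [lint_sample()] over every row and summarises completeness,
#' including the fraction of studies that report no ancestry information at
#' all (every sample `Not reported`). Findings are ordered by rule id, then
#' row.
#'
#' @param samples Sample tibble (all studies), as from
#'   [read_ancestry_tsv()].
#' @inheritParams lint_sample
#' @return A `lint_report`: list with `findings` (tibble), `rule_counts`
#'   (tibble of per-rule totals), `fraction_no_ancestry`, `n_studies`,
#'   `n_samples`.
#' @export
lint_catalog <- function(samples,
                         categories = ancestry_categories(),
                         lexicon = ancestry_lexicon(categories = categories),
                         countries = ancestry_countries(categories = categories),
                         cohorts = cohort_names()) {
  if (is.null(samples) || nrow(samples) == 0) {
    abort("Cannot lint an empty catalog", class = "ancestrycat_empty_input")
  }
  findings <- bind_rows(lapply(seq_len(nrow(samples)), function(i) {
    lint_sample(samples[i, ], row = i,
      categories = categories, lexicon = lexicon,
      countries = countries, cohorts = cohorts
    )
  }))
  findings <- findings[order(match(findings$rule_id, lint_rules()$rule_id), findings$row), ]
  reg <- lint_rules()
  rule_counts <- tibble(
    rule_id = reg$rule_id,
    severity = reg$severity,
    n = vapply(reg$rule_id, function(r) sum(findings$rule_id == r), integer(1))
  )
  no_anc <- vapply(
    split(samples$categories, samples$study_accession),
    function(cat_list) all(vapply(cat_list, identical, logical(1), y = "Not reported")),
    logical(1)
  )
  structure(
    list(
      findings = findings,
      rule_counts = rule_counts,
      fraction_no_ancestry = mean(no_anc),
      n_studies = length(no_anc),
      n_samples = nrow(samples)
    ),
    class = "lint_report"
  )
}

#' @export
print.lint_report <- function(x, ...) {
  cat(sprintf(
    "Lint report: %d samples in %d studies, %d finding(s)\n",
    x$n_samples, x$n_studies, nrow(x$findings)
  ))
  shown <- x$rule_counts[x$rule_counts$n > 0, ]
  for (i in seq_len(nrow(shown))) {
    cat(sprintf(
      "  %-4s %-8s %d\n", shown$rule_id[i], shown$severity[i], shown$n[i]
    ))
  }
  cat(sprintf(
    "  studies with no ancestry information: %.1f%%\n",
    100 * x$fraction_no_ancestry
  ))
  invisible(x)
}
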