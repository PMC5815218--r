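# Category-level diversity statistics: distributions over individuals,
# studies and associations, time-window comparisons, and trait breadth.

#' Specify an inclusive publication-year window
#'
#' @param start_year,end_year Inclusive publication-year bounds.
#' @return A `window_spec` list.
#' @examples
#' window_spec(2005, 2010)
#' @export
window_spec <- function(start_year, end_year) {
  start_year <- as.integer(start_year)
  end_year <- as.integer(end_year)
  if (is.na(start_year) || is.na(end_year) || start_year > end_year) {
    abort("`start_year` must be <= `end_year`", class = "ancestrycat_invalid_window")
  }
  structure(list(start_year = start_year, end_year = end_year),
    class = "window_spec"
  )
}

as_window <- function(window) {
  if (is.null(window)) {
    return(NULL)
  }
  if (inherits(window, "window_spec")) {
    return(window)
  }
  if (is.numeric(window) && length(window) == 2) {
    return(window_spec(window[1], window[2]))
  }
  abort("`window` must be a window_spec or a length-2 numeric vector")
}

# label of a unit given its category set: distinct categories other than
# "Not reported" decide; two or more make the unit "multiple"
unit_label <- function(cats) {
  core <- setdiff(unique(cats), "Not reported")
  if (length(core) == 0) {
    "Not reported"
  } else if (length(core) == 1) {
    core
  } else {
    "multiple"
  }
}

apply_supergroups <- function(labels, supergroup_map) {
  if (is.null(supergroup_map)) {
    return(labels)
  }
  lut <- stats::setNames(
    rep(names(supergroup_map), lengths(supergroup_map)),
    unlist(supergroup_map)
  )
  ifelse(labels %in% names(lut), lut[labels], labels)
}

filter_window <- function(samples, window) {
  if (is.null(window)) {
    return(samples)
  }
  yr <- as.integer(format(samples$publication_date, "%Y"))
  samples[!is.na(yr) & yr >= window$start_year & yr <= window$end_year, ]
}

study_labels <- function(samples) {
  vapply(
    split(samples$categories, samples$study_accession),
    function(cat_list) unit_label(unlist(cat_list)),
    character(1)
  )
}

#' Distribution of ancestry categories across a catalog
#'
#' Summarises a catalog at one of three levels:
#' \describe{
#'   \item{individuals}{Every sample contributes its number of individuals
#'     to its category, or to `"multiple"` when the sample itself is
#'     annotated with more than one category. Initial and replication
#'     samples both count, without deduplication across studies.}
#'   \item{studies}{A study analysing exactly one distinct category (after
#'     setting aside `Not reported`) counts toward that category; more than
#'     one makes it `"multiple"`; none makes it `Not reported`.}
#'   \item{associations}{An association carrying its own ancestry
#'     annotation uses it; otherwise it inherits its study's label.}
#' }
#' An optional inclusive publication-year window restricts the catalog
#' first, and an optional supergroup map (see [default_supergroup_map()])
#' collapses labels before percentages are taken.
#'
#' @param samples Sample tibble, as from [read_ancestry_tsv()].
#' @param associations Association tibble (required when
#'   `level = "associations"`).
#' @param level `"individuals"`, `"studies"` or `"associations"`.
#' @param window Optional [window_spec()] or length-2 numeric vector of
#'   years.
#' @param supergroup_map Optional named list collapsing categories into
#'   display supergroups.
#' @return A `diversity_report` tibble with columns `label`, `count`,
#'   `percentage`, carrying attributes `level` and `n_total`.
#' @examples
#' cat <- generate_catalog(sim_config(n_studies = 50, seed = 7))
#' distribution_by_category(cat$samples, level = "studies")
#' @export
distribution_by_category <- function(samples, associations = NULL,
                                     level = c("individuals", "studies", "associations"),
                                     window = NULL, supergroup_map = NULL) {
  level <- match.arg(level)
  window <- as_window(window)
  samples <- filter_window(samples, window)

  if (level == "individuals") {
    labels <- vapply(samples$categories, function(cats) {
      core <- setdiff(unique(cats), "Not reported")
      if (length(core) == 0) "Not reported" else if (length(core) == 1) core else "multiple"
    }, character(1))
    weights <- ifelse(is.na(samples$n_individuals), 0, samples$n_individuals)
  } else if (level == "studies") {
    labels <- study_labels(samples)
    weights <- rep(1, length(labels))
  } else {
    if (is.null(associations)) {
      abort("`associations` is required at the associations level")
    }
    dangling <- setdiff(
      unique(associations$study_accession), unique(samples$study_accession)
    )
    if (is.null(window) && length(dangling) > 0) {
      abort(
        sprintf(
          "Associations reference unknown study accession(s): %s",
          paste(dangling, collapse = ", ")
        ),
        class = "ancestrycat_dangling_accession"
      )
    }
    slab <- study_labels(samples)
    keep <- associations$study_accession %in% names(slab)
    assoc <- associations[keep, ]
    labels <- vapply(seq_len(nrow(assoc)), function(i) {
      ann <- assoc$ancestry_annotation[[i]]
      if (length(ann) > 0) unit_label(ann) else slab[[assoc$study_accession[i]]]
    }, character(1))
    weights <- rep(1, length(labels))
  }

  labels <- apply_supergroups(labels, supergroup_map)
  agg <- tibble(label = labels, weight = weights) |>
    group_by(.data$label) |>
    summarise(count = sum(.data$weight), .groups = "drop")
  total <- sum(agg$count)
  agg$percentage <- if (total > 0) 100 * agg$count / total else rep(0, nrow(agg))
  agg <- agg[order(-agg$count, agg$label), ]
  structure(
    as_tibble(agg),
    level = level, n_total = total, window = window,
    class = c("diversity_report", class(as_tibble(agg)))
  )
}

#' Compare category shares between two publication-year windows
#'
#' Computes the distribution in each window at the requested level and the
#' fold change of each label's share (`pct_b / pct_a`). Labels absent from
#' window A report `NA` for the fold (undefined, rather than infinite).
#'
#' @inheritParams distribution_by_category
#' @param window_a,window_b The two windows (see [window_spec()]).
#' @return A tibble with columns `label`, `pct_a`, `pct_b`, `fold`.
#' @export
compare_windows <- function(samples, associations = NULL,
                            level = c("individuals", "studies", "associations"),
                            window_a, window_b, supergroup_map = NULL) {
  level <- match.arg(level)
  rep_a <- distribution_by_category(samples, associations, level,
    window = window_a, supergroup_map = supergroup_map
  )
  rep_b <- distribution_by_category(samples, associations, level,
    window = window_b, supergroup_map = supergroup_map
  )
  merged <- dplyr::full_join(
    tibble(label = rep_a$label, pct_a = rep_a$percentage),
    tibble(label = rep_b$label, pct_b = rep_b$percentage),
    by = "label"
  )
  merged$pct_a[is.na(merged$pct_a)] <- 0
  merged$pct_b[is.na(merged$pct_b)] <- 0
  merged$fold <- ifelse(merged$pct_a > 0, merged$pct_b / merged$pct_a, NA_real_)
  merged[order(-merged$pct_b), ]
}

#' Ancestry breadth of a trait
#'
#' How widely a trait has been analysed across ancestral backgrounds:
#' distinct normalized detailed descriptions, distinct categories (setting
#' aside `Not reported`), and the numbers of studies and associations
#' reporting the trait. Trait matching is case-insensitive.
#'
#' @inheritParams distribution_by_category
#' @param trait Trait label.
#' @return A one-row tibble with columns `trait`,
#'   `n_detailed_descriptions`, `n_categories`, `n_studies`,
#'   `n_associations`.
#' @export
trait_breadth <- function(samples, associations, trait) {
  hit <- tolower(trimws(associations$trait)) == tolower(trimws(trait))
  if (!any(hit)) {
    abort(sprintf("Unknown trait '%s'", trait), class = "ancestrycat_unknown_trait")
  }
  assoc <- associations[hit, ]
  accs <- unique(assoc$study_accession)
  ss <- samples[samples$study_accession %in% accs, ]
  descs <- normalize_descriptor(ss$detailed_description)
  cats <- setdiff(unique(unlist(ss$categories)), "Not reported")
  tibble(
    trait = trait,
    n_detailed_descriptions = length(unique(descs[nzchar(descs)])),
    n_categories = length(cats),
    n_studies = length(accs),
    n_associations = nrow(assoc)
  )
}
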