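# Synthetic study/sample/association generator with exact ground truth, so
# the I/O, lint and diversity modules are testable without any download.

default_category_weights <- function() {
  c(
    "European" = 0.62,
    "East Asian" = 0.15,
    "South Asian" = 0.05,
    "African American or Afro-Caribbean" = 0.04,
    "Hispanic or Latin American" = 0.03,
    "Sub-Saharan African" = 0.02,
    "Greater Middle Eastern (Middle Eastern, North African, or Persian)" = 0.02,
    "Asian unspecified" = 0.02,
    "African unspecified" = 0.01,
    "South East Asian" = 0.01,
    "Oceanian" = 0.005,
    "Native American" = 0.005,
    "Other" = 0.02
  )
}

default_trait_pool <- function() {
  c(
    "type 2 diabetes", "body mass index", "coronary artery disease", "height",
    "rheumatoid arthritis", "schizophrenia", "asthma", "breast cancer",
    "systolic blood pressure", "LDL cholesterol"
  )
}

#' Configure a synthetic catalog simulation
#'
#' The defaults emulate a European-dominant GWAS corpus: about 4% of
#' studies report no ancestry information, about a quarter analyze more
#' than one ancestral background, the rest draw a single category from a
#' European-heavy weight vector, publication years span 2005-2016, and
#' sample sizes follow a heavy-tailed shifted negative-binomial
#' distribution.
#'
#' @param n_studies Number of studies to simulate.
#' @param category_weights Named probability vector over (non-`Not
#'   reported`) category names for single-category draws; must sum to 1.
#' @param multi_ancestry_fraction Probability that a study (with reported
#'   ancestry) analyzes two distinct categories. Such a study gets one
#'   initial sample per category plus one jointly annotated replication
#'   sample.
#' @param not_reported_fraction Probability that a study reports no
#'   ancestry information at all.
#' @param mean_sample_size Mean individuals per sample (>= 1).
#' @param size_dispersion Negative-binomial dispersion (`size` parameter) of
#'   sample sizes; smaller is heavier-tailed.
#' @param replication_prob Probability that a single-category study also
#'   has a replication sample.
#' @param associations_mean Mean associations per study (>= 1; shifted
#'   Poisson, so every study has at least one).
#' @param annotation_fraction Probability that an association in a
#'   multi-ancestry study carries its own single-category annotation.
#' @param year_range Inclusive publication-year range (length 2).
#' @param trait_pool Trait labels sampled uniformly per study.
#' @param seed Integer seed; the same configuration always generates
#'   byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_studies = 1000,
                       category_weights = default_category_weights(),
                       multi_ancestry_fraction = 0.25,
                       not_reported_fraction = 0.04,
                       mean_sample_size = 2000,
                       size_dispersion = 0.8,
                       replication_prob = 0.5,
                       associations_mean = 5,
                       annotation_fraction = 0.5,
                       year_range = c(2005, 2016),
                       trait_pool = default_trait_pool(),
                       seed = 1L) {
  cfg <- list(
    n_studies = as.integer(n_studies),
    category_weights = category_weights,
    multi_ancestry_fraction = multi_ancestry_fraction,
    not_reported_fraction = not_reported_fraction,
    mean_sample_size = mean_sample_size,
    size_dispersion = size_dispersion,
    replication_prob = replication_prob,
    associations_mean = associations_mean,
    annotation_fraction = annotation_fraction,
    year_range = as.integer(year_range),
    trait_pool = trait_pool,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  w <- cfg$category_weights
  cats <- ancestry_categories()
  if (is.null(names(w)) || any(!nzchar(names(w)))) {
    abort("`category_weights` must be named", class = "ancestrycat_invalid_config")
  }
  bad <- setdiff(names(w), setdiff(cats$name, "Not reported"))
  if (length(bad) > 0) {
    abort(
      sprintf("Unknown categories in `category_weights`: %s", paste(bad, collapse = ", ")),
      class = "ancestrycat_invalid_config"
    )
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    abort("`category_weights` must be non-negative and sum to 1",
      class = "ancestrycat_invalid_config"
    )
  }
  fr <- c(
    cfg$multi_ancestry_fraction, cfg$not_reported_fraction,
    cfg$replication_prob, cfg$annotation_fraction
  )
  if (any(fr < 0 | fr > 1)) {
    abort("Fractions must lie in [0, 1]", class = "ancestrycat_invalid_config")
  }
  if (cfg$n_studies < 0 || cfg$mean_sample_size < 1 || cfg$size_dispersion <= 0 ||
    cfg$associations_mean < 1 || cfg$year_range[1] > cfg$year_range[2]) {
    abort("Invalid simulation configuration", class = "ancestrycat_invalid_config")
  }
  invisible(cfg)
}

# representative recruitment country per category (seed-table consistent)
category_country <- function() {
  c(
    "European" = "United Kingdom",
    "East Asian" = "China",
    "South Asian" = "India",
    "South East Asian" = "Thailand",
    "Central Asian" = "Kazakhstan",
    "Asian unspecified" = "United States",
    "African unspecified" = "South Africa",
    "Sub-Saharan African" = "Nigeria",
    "African American or Afro-Caribbean" = "United States",
    "Hispanic or Latin American" = "Mexico",
    "Greater Middle Eastern (Middle Eastern, North African, or Persian)" = "Iran",
    "Native American" = "United States",
    "Oceanian" = "Fiji",
    "Aboriginal Australian" = "Australia",
    "Other" = "Russia",
    "Other admixed ancestry" = "United States"
  )
}

# a descriptor for each category that classifies back to it
category_descriptor <- function(categories) {
  vapply(categories$name, function(nm) {
    ex <- categories$example_descriptors[[match(nm, categories$name)]]
    if (length(ex) > 0) ex[1] else nm
  }, character(1))
}

#' Generate a synthetic catalog with known ground truth
#'
#' Draws studies of three kinds — not-reported, single-category, and
#' two-category ("multi-ancestry") — according to the configuration, builds
#' the per-sample and per-association tables in the catalog dialect, and
#' tallies the exact per-label counts at each analysis level while
#' generating. The ground truth is bookkept directly from the generation
#' process, independently of the analysis code, so pipeline tests can
#' require exact agreement.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_catalog` list: `samples` (tibble), `associations`
#'   (tibble), `ground_truth` (tibble: `level`, `label`, `count`), `config`.
#' @examples
#' cat <- generate_catalog(sim_config(n_studies = 20, seed = 42))
#' cat$ground_truth
#' @export
generate_catalog <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config", class = "ancestrycat_invalid_config")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_studies
  cats_tbl <- ancestry_categories()
  desc_of <- category_descriptor(cats_tbl)
  ctry_of <- category_country()
  w <- config$category_weights
  wn <- names(w)

  if (n == 0) {
    return(structure(
      list(
        samples = empty_samples(),
        associations = tibble(
          association_id = character(0), study_accession = character(0),
          trait = character(0), ancestry_annotation = list()
        ),
        ground_truth = tibble(
          level = character(0), label = character(0), count = numeric(0)
        ),
        config = config
      ),
      class = "synthetic_catalog"
    ))
  }

  fnr <- config$not_reported_fraction
  fm <- config$multi_ancestry_fraction
  type <- sample(c("nr", "multi", "single"), n,
    replace = TRUE,
    prob = c(fnr, (1 - fnr) * fm, (1 - fnr) * (1 - fm))
  )
  c1 <- sample(wn, n, replace = TRUE, prob = w)
  c2 <- sample(wn, n, replace = TRUE, prob = w)
  while (any(clash <- c2 == c1)) {
    c2[clash] <- sample(wn, sum(clash), replace = TRUE, prob = w)
  }
  has_rep <- rbinom(n, 1, config$replication_prob)

  accession <- sprintf("GCST%06d", seq_len(n))
  pubmed <- as.character(sample(10000000:39999999, n))
  years <- sample(config$year_range[1]:config$year_range[2], n, replace = TRUE)
  dates <- as.Date(sprintf(
    "%d-%02d-%02d", years, sample(1:12, n, replace = TRUE),
    sample(1:28, n, replace = TRUE)
  ))
  trait <- sample(config$trait_pool, n, replace = TRUE)

  rows_per <- ifelse(type == "nr", 1L, ifelse(type == "multi", 3L, 1L + has_rep))
  sidx <- rep(seq_len(n), rows_per)
  pos <- sequence(rows_per)
  n_samp <- length(sidx)

  stype <- type[sidx]
  stage <- ifelse(
    (stype == "multi" & pos == 3L) | (stype == "single" & pos == 2L),
    "replication", "initial"
  )
  sample_label <- character(n_samp) # exact label bookkeeping
  cats <- vector("list", n_samp)
  for (k in seq_len(n_samp)) {
    i <- sidx[k]
    if (stype[k] == "nr") {
      cats[[k]] <- "Not reported"
      sample_label[k] <- "Not reported"
    } else if (stype[k] == "single") {
      cats[[k]] <- c1[i]
      sample_label[k] <- c1[i]
    } else if (pos[k] == 1L) {
      cats[[k]] <- c1[i]
      sample_label[k] <- c1[i]
    } else if (pos[k] == 2L) {
      cats[[k]] <- c2[i]
      sample_label[k] <- c2[i]
    } else {
      cats[[k]] <- c(c1[i], c2[i])
      sample_label[k] <- "multiple"
    }
  }
  n_individuals <- 1L + rnbinom(n_samp,
    size = config$size_dispersion,
    mu = config$mean_sample_size - 1
  )
  descriptions <- vapply(cats, function(cc) {
    if (identical(cc, "Not reported")) "" else paste(desc_of[cc], collapse = " and ")
  }, character(1))
  recr <- lapply(cats, function(cc) {
    if (identical(cc, "Not reported")) character(0) else unique(unname(ctry_of[cc]))
  })
  method <- sample(
    c("self-reported", "inferred by principal component analysis"),
    n_samp,
    replace = TRUE
  )

  samples <- tibble(
    study_accession = accession[sidx],
    pubmed_id = pubmed[sidx],
    publication_date = dates[sidx],
    stage = stage,
    n_individuals = as.integer(n_individuals),
    categories = cats,
    detailed_description = descriptions,
    country_of_recruitment = recr,
    country_of_origin = lapply(seq_len(n_samp), function(i) character(0)),
    additional_description = ifelse(stype == "nr", "", method),
    confidential = rep(FALSE, n_samp)
  )

  k_assoc <- 1L + rpois(n, config$associations_mean - 1)
  aidx <- rep(seq_len(n), k_assoc)
  association_id <- sprintf("%s.%d", accession[aidx], sequence(k_assoc))
  annotate <- runif(length(aidx)) < config$annotation_fraction &
    type[aidx] == "multi"
  pick_first <- rbinom(length(aidx), 1, 0.5) == 1
  ann <- vector("list", length(aidx))
  assoc_label <- character(length(aidx))
  study_lab <- ifelse(type == "nr", "Not reported",
    ifelse(type == "multi", "multiple", c1)
  )
  for (k in seq_along(aidx)) {
    i <- aidx[k]
    if (annotate[k]) {
      ann[[k]] <- if (pick_first[k]) c1[i] else c2[i]
      assoc_label[k] <- ann[[k]]
    } else {
      ann[[k]] <- character(0)
      assoc_label[k] <- study_lab[i]
    }
  }
  associations <- tibble(
    association_id = association_id,
    study_accession = accession[aidx],
    trait = trait[aidx],
    ancestry_annotation = ann
  )

  gt <- bind_rows(
    tally_counts("studies", study_lab, rep(1, n)),
    tally_counts("individuals", sample_label, n_individuals),
    tally_counts("associations", assoc_label, rep(1, length(aidx)))
  )

  structure(
    list(
      samples = samples, associations = associations,
      ground_truth = gt, config = config
    ),
    class = "synthetic_catalog"
  )
}

tally_counts <- function(level, labels, weights) {
  agg <- tapply(weights, labels, sum)
  tibble(
    level = level,
    label = names(agg),
    count = as.numeric(agg)
  )
}

#' Write a synthetic catalog to disk
#'
#' Writes `ancestry.tsv`, `associations.tsv` and a `ground_truth.tsv`
#' sidecar into a directory. Output is byte-identical for the same
#' configuration (including seed).
#'
#' @param catalog A `synthetic_catalog` from [generate_catalog()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_catalog <- function(catalog, dir) {
  stopifnot(inherits(catalog, "synthetic_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ancestry_tsv(catalog$samples, file.path(dir, "ancestry.tsv"))
  write_associations_tsv(catalog$associations, file.path(dir, "associations.tsv"))
  readr::write_tsv(catalog$ground_truth, file.path(dir, "ground_truth.tsv"),
    quote = "none", escape = "none", eol = "\n", progress = FALSE
  )
  invisible(dir)
}

#' Closed-form expected category distribution of a configuration
#'
#' The percentage of each label that [distribution_by_category()] recovers
#' in expectation from catalogs generated under `config`, at each level.
#' Derived directly from the generative process: study-type probabilities,
#' the inclusion probability of each category in a two-category draw
#' (first category from the weights, second from the renormalized weights),
#' the per-study expected sample count, and the association annotation
#' fraction.
#'
#' @param config A [sim_config()].
#' @param level `"individuals"`, `"studies"` or `"associations"`.
#' @return A tibble with columns `label`, `percentage`, for every label
#'   with positive expected share.
#' @export
expected_distribution <- function(config,
                                  level = c("individuals", "studies", "associations")) {
  level <- match.arg(level)
  w <- config$category_weights
  fnr <- config$not_reported_fraction
  fm <- config$multi_ancestry_fraction
  # P(category in the unordered two-category draw)
  incl <- vapply(seq_along(w), function(i) {
    others <- w[-i]
    w[i] + sum(others * w[i] / (1 - others))
  }, numeric(1))
  names(incl) <- names(w)

  if (level == "studies") {
    mass <- c(
      (1 - fnr) * (1 - fm) * w,
      "multiple" = (1 - fnr) * fm,
      "Not reported" = fnr
    )
  } else if (level == "individuals") {
    m <- config$mean_sample_size
    single_mass <- (1 - fnr) * (1 - fm) * w * (1 + config$replication_prob) * m
    multi_mass <- (1 - fnr) * fm * incl * m
    mass <- c(
      single_mass + multi_mass,
      "multiple" = (1 - fnr) * fm * m,
      "Not reported" = fnr * m
    )
  } else {
    af <- config$annotation_fraction
    mass <- c(
      (1 - fnr) * ((1 - fm) * w + fm * af * incl / 2),
      "multiple" = (1 - fnr) * fm * (1 - af),
      "Not reported" = fnr
    )
  }
  mass <- mass[mass > 0]
  out <- tibble(
    label = names(mass),
    percentage = 100 * as.numeric(mass) / sum(mass)
  )
  out[order(-out$percentage, out$label), ]
}
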