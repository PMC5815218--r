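#!/usr/bin/env Rscript
# Integration check against the real GWAS Catalog ancestry download
# (release pinned to 2017-07-18). Requires network access; it is not part
# of the test suite because the corpus numbers cannot be reproduced without
# the release files.
#
#   Rscript scripts/external_reproduction.R [--ancestry PATH] [--associations PATH]
#
# When --ancestry is not given, the script downloads the current ancestry
# file from the Catalog FTP mirror; point it at a locally archived copy of
# the pinned release to reproduce the published percentages. Reference
# values printed alongside each computed quantity (individuals: European
# 78%, East Asian 9%, multiple 1.8%; studies: European-only ~50%;
# 2005-2010 vs 2011-2016 African individuals 0.8% -> 2.8%, 3.5-fold).
# Counting conventions (no deduplication across studies, both stages
# counted) are documented in the package vignette; expect agreement within
# about one percentage point.

suppressPackageStartupMessages(library(ancestrycat))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

url <- "https://ftp.ebi.ac.uk/pub/databases/gwas/releases/latest/gwas-catalog-ancestry.tsv"
path <- get_arg("--ancestry")
if (is.null(path)) {
  path <- tempfile(fileext = ".tsv")
  message("downloading ", url)
  utils::download.file(url, path, quiet = TRUE)
}

# The public download uses upper-case spaced headers; map them onto the
# package dialect before reading.
raw <- readr::read_tsv(path,
  col_types = readr::cols(.default = readr::col_character()),
  quote = "", na = character(), progress = FALSE
)
header_map <- c(
  "STUDY ACCESSION" = "study_accession",
  "PUBMEDID" = "pubmed_id",
  "DATE" = "publication_date",
  "STAGE" = "stage",
  "NUMBER OF INDIVDUALS" = "number_of_individuals",
  "NUMBER OF INDIVIDUALS" = "number_of_individuals",
  "BROAD ANCESTRAL CATEGORY" = "broad_ancestral_category",
  "ADDITIONAL ANCESTRY DESCRIPTION" = "detailed_ancestry_description",
  "COUNTRY OF RECRUITMENT" = "country_of_recruitment",
  "COUNTRY OF ORIGIN" = "country_of_origin"
)
keep <- names(raw) %in% names(header_map)
raw <- raw[keep]
names(raw) <- header_map[names(raw)]
raw$additional_ancestry_description <- ""
# the download writes "NR" for unreported cells
for (col in c("broad_ancestral_category", "country_of_recruitment", "country_of_origin")) {
  raw[[col]][toupper(trimws(raw[[col]])) == "NR"] <- ""
}
if (!"detailed_ancestry_description" %in% names(raw)) {
  raw$detailed_ancestry_description <- ""
}
tmp <- tempfile(fileext = ".tsv")
readr::write_tsv(raw, tmp, quote = "none", escape = "none", progress = FALSE)

samples <- read_ancestry_tsv(tmp)
message(sprintf("parsed %d sample rows", nrow(samples)))

show <- function(title, report, labels, reference) {
  cat("\n", title, "\n", sep = "")
  for (i in seq_along(labels)) {
    pct <- sum(report$percentage[report$label == labels[i]])
    cat(sprintf("  %-50s %6.2f%%   (published: %s)\n", labels[i], pct, reference[i]))
  }
}

ind <- distribution_by_category(samples, level = "individuals")
show("Individuals", ind,
  c("European", "East Asian", "multiple", "Not reported"),
  c("78%", "9%", "1.8%", "6%")
)

stu <- distribution_by_category(samples, level = "studies")
show("Studies", stu, c("European", "multiple"), c("~50%", "~25% (multi incl. European)"))

cw <- compare_windows(samples,
  level = "individuals",
  window_a = window_spec(2005, 2010), window_b = window_spec(2011, 2016),
  supergroup_map = default_supergroup_map()
)
eur <- cw[cw$label == "European", ]
afr <- cw[cw$label == "African", ]
cat(sprintf(
  "\nEuropean individuals 2005-2010 vs 2011-2016: %.1f%% -> %.1f%% (published: 86%% -> 76%%)\n",
  eur$pct_a, eur$pct_b
))
cat(sprintf(
  "African individuals 2005-2010 vs 2011-2016: %.2f%% -> %.2f%%, fold %.2f (published: 0.8%% -> 2.8%%, 3.5)\n",
  afr$pct_a, afr$pct_b, afr$fold
))
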