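# shared plumbing: seed-file resolution, multi-value cells, string normalization

anc_file <- function(name) {
  system.file("extdata", name, package = "ancestrycat", mustWork = TRUE)
}

read_seed_tsv <- function(path, required) {
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    quote = "", na = character(), progress = FALSE
  )
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "Seed table '%s' is missing column(s): %s", path,
        paste(missing, collapse = ", ")
      ),
      class = "ancestrycat_missing_column"
    )
  }
  tbl
}

# "a|b|c" -> c("a", "b", "c"); empty cells -> character(0)
split_multi <- function(x, sep = "|") {
  out <- strsplit(ifelse(is.na(x), "", x), sep, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_multi <- function(x, sep = "|") {
  vapply(x, paste, character(1), collapse = sep)
}

as_flag <- function(x) toupper(trimws(x)) %in% c("TRUE", "T", "1", "YES")

#' Normalize a free-text population descriptor
#'
#' Case-folds, replaces punctuation with spaces, and collapses runs of
#' whitespace, so that e.g. `"African-American"` and `" african  AMERICAN "`
#' normalize to the same key. All descriptor matching in the package operates
#' on normalized strings.
#'
#' @param text Character vector of descriptors.
#' @return Character vector of normalized descriptors (`""` for empty input).
#' @examples
#' normalize_descriptor("  Han  Chinese. ")
#' normalize_descriptor("African-American")
#' @export
normalize_descriptor <- function(text) {
  x <- tolower(ifelse(is.na(text), "", as.character(text)))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

# top candidates by edit distance, for "did you mean" error messages
nearest_terms <- function(key, candidates, k = 3) {
  if (length(candidates) == 0) return(character(0))
  d <- adist(key, candidates)[1, ]
  unique(candidates[order(d)])[seq_len(min(k, length(candidates)))]
}
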