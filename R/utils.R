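# Shared helpers: label normalisation and small assertions.

#' Normalise a label for comparison
#'
#' Lower-cases, trims, and collapses internal whitespace. All label-based
#' lookups in the package (reference-list hits, object resolution, voting
#' groups, matching name sets) compare labels in this normal form.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# Class labels additionally drop non-alphanumerics so that e.g.
# "Western Medicine", "western_medicine" and "WesternMedicine" coincide.
normalize_class_label <- function(x) {
  gsub("[^a-z0-9]", "", tolower(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# deterministic unlist-paste for provenance tags
collapse_sources <- function(x) {
  paste(sort(unique(unlist(strsplit(x[nzchar(x)], ",", fixed = TRUE)))),
        collapse = ",")
}
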