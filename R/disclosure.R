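#' Disclosure control settings
#'
#' Houses the DataSHIELD-style subset threshold: the minimum non-zero number
#' of unique individuals any exposed subset may represent. Data describing
#' fewer individuals (but more than zero) is considered disclosive and is
#' excluded from catalogs and outputs. A count of zero means absence, not
#' disclosure, and always passes. Sites configure the threshold; 5 is a
#' conservative default, not a constant.
#'
#' \code{glm_ratio} bounds the number of model parameters relative to the
#' number of observations a site may contribute to an aggregate request,
#' mirroring the safeguard family deployed DataSHIELD servers apply to
#' model-fitting calls.
#'
#' @param subset_threshold Positive integer, minimum non-zero unique-person
#'   count.
#' @param glm_ratio Maximum allowed parameters/observations ratio for
#'   aggregate model requests.
#' @return An object of class \code{disclosure_settings}.
#' @export
disclosure_settings <- function(subset_threshold = 5L, glm_ratio = 0.33) {
  subset_threshold <- as.integer(subset_threshold)
  stopifnot(length(subset_threshold) == 1L, subset_threshold >= 1L,
            glm_ratio > 0)
  structure(list(subset_threshold = subset_threshold, glm_ratio = glm_ratio),
            class = "disclosure_settings")
}

#' Does a unique-person count pass the subset threshold?
#'
#' Strict "falls below" semantics: a count equal to the threshold passes;
#' counts in \code{1..threshold-1} are blocked; zero passes (absence of data
#' discloses nothing).
#'
#' @param unique_person_count Non-negative integer.
#' @param settings A [disclosure_settings()].
#' @return TRUE or FALSE.
#' @export
passes_subset_threshold <- function(unique_person_count, settings) {
  stopifnot(unique_person_count >= 0)
  unique_person_count == 0 | unique_person_count >= settings$subset_threshold
}

#' Filter a concept catalog by the subset threshold
#'
#' Removes every entry whose unique-person count is non-zero but below the
#' threshold. Entries are only removed, never modified.
#'
#' @param counts Named vector as returned by [concept_person_counts()].
#' @param settings A [disclosure_settings()].
#' @return The surviving subset of \code{counts}.
#' @export
filter_concept_catalog <- function(counts, settings) {
  if (length(counts) == 0L) return(counts)
  counts[counts > 0 & passes_subset_threshold(counts, settings)]
}

#' Validate an output table against the subset threshold
#'
#' Called before any table is exposed beyond the server boundary. The table
#' passes iff it represents zero persons or at least \code{subset_threshold}
#' distinct persons. On failure a condition of class \code{disclosure_error}
#' is signalled naming only the offending table -- never identifiers or the
#' sub-threshold count itself.
#'
#' @param records An \code{event_records} or \code{wide_dataset} data frame,
#'   or any data frame with a \code{person_id} column.
#' @param settings A [disclosure_settings()].
#' @param table_name Name used in the error message; defaults to the records'
#'   own table attribute.
#' @return Invisibly TRUE on pass.
#' @export
validate_output_table <- function(records, settings,
                                  table_name = attr(records, "table_name")) {
  pcol <- attr(records, "person_column")
  if (is.null(pcol)) pcol <- "person_id"
  if (!pcol %in% names(records))
    stop("records carry no person column; cannot assess disclosure",
         call. = FALSE)
  n <- length(unique(records[[pcol]]))
  if (!passes_subset_threshold(n, settings)) {
    if (is.null(table_name)) table_name <- "<unnamed>"
    stop(disclosure_error(sprintf(
      "table '%s' is disclosive under the configured subset threshold",
      table_name)))
  }
  invisible(TRUE)
}

disclosure_error <- function(message) {
  structure(class = c("disclosure_error", "error", "condition"),
            list(message = message, call = NULL))
}
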