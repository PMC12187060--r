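#' List the tables of a site's database with their classified roles
#'
#' Names come from runtime introspection. A table is flagged as a domain
#' table when it carries both a person link and a concept link and its
#' primary key is not the person id itself -- i.e. it holds (possibly many)
#' clinical events per person, as opposed to the one-row-per-person
#' \code{person} table.
#'
#' @param site An [create_site()] server.
#' @return Data frame with columns \code{table}, \code{n_rows},
#'   \code{n_columns}, \code{is_domain}.
#' @export
list_tables <- function(site) {
  schema <- site_schema(site)
  out <- do.call(rbind, lapply(schema$tables, function(td) {
    data.frame(table = td$name, n_rows = td$row_count,
               n_columns = length(td$columns),
               is_domain = is_domain_table(td),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

is_domain_table <- function(td) {
  pcol <- person_column_of(td)
  !is.null(main_concept_column(td)) && !is.null(pcol) &&
    !identical(primary_key_of(td), pcol)
}

#' Disclosure-filtered concept inventory of a domain table
#'
#' Counts unique persons per concept, removes every concept below the site's
#' subset threshold, translates the survivors against the site's own
#' vocabulary and sorts by concept name (concept id breaking ties). A
#' concept visible here is exactly a concept retrievable through
#' [site_assign_dataset()]; sub-threshold concepts appear in neither place.
#'
#' @param site An \code{omop_site}.
#' @param table Name of a domain table at the site.
#' @return Data frame with columns \code{table}, \code{concept_id},
#'   \code{concept_name}, \code{unique_person_count}.
#' @export
list_concepts <- function(site, table) {
  schema <- site_schema(site)
  td <- schema$tables[[tolower(table)]]
  if (is.null(td))
    stop(sprintf("unknown table '%s'", table), call. = FALSE)
  if (!is_domain_table(td))
    stop(sprintf("'%s' is not a domain table", table), call. = FALSE)
  counts <- concept_person_counts(site$connection, td)
  counts <- filter_concept_catalog(counts, site$settings)
  voc <- site_vocabulary(site)
  ids <- as.integer(names(counts))
  nm <- unname(voc[names(counts)])
  nm[is.na(nm)] <- paste0("concept_", ids[is.na(nm)])
  out <- data.frame(table = rep(td$name, length(ids)), concept_id = ids,
                    concept_name = nm,
                    unique_person_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(out$concept_name, out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
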