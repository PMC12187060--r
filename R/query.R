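#' Construct a query filter
#'
#' A filter restricts extraction by person, by concept, and/or by column.
#' An \emph{absent} component (\code{NULL}) leaves that dimension
#' unrestricted; an \emph{empty} set is a real restriction that matches zero
#' rows. The distinction matters for cohort workflows, where an empty cohort
#' must yield an empty (not full) extraction.
#'
#' Printing a filter never reveals the person identifiers it carries -- only
#' their count -- so filters can appear in client-visible transcripts without
#' leaking cohort membership.
#'
#' @param person_ids Optional integer vector of person ids.
#' @param concept_ids Optional integer vector of concept ids.
#' @param columns Optional character vector of columns to retrieve.
#' @return An object of class \code{query_filter}.
#' @export
query_filter <- function(person_ids = NULL, concept_ids = NULL,
                         columns = NULL) {
  if (!is.null(person_ids)) person_ids <- unique(as.integer(person_ids))
  if (!is.null(concept_ids)) concept_ids <- unique(as.integer(concept_ids))
  if (!is.null(columns)) stopifnot(is.character(columns))
  structure(list(person_ids = person_ids, concept_ids = concept_ids,
                 columns = columns), class = "query_filter")
}

#' @export
print.query_filter <- function(x, ...) {
  part <- function(v, what)
    if (is.null(v)) paste0(what, ": unrestricted")
    else sprintf("%s: %d", what, length(v))
  cat("<query_filter ", part(x$person_ids, "persons"), ", ",
      part(x$concept_ids, "concepts"), ", ",
      if (is.null(x$columns)) "all columns" else
        paste(x$columns, collapse = ","), ">\n", sep = "")
  invisible(x)
}

#' Build a parameterized SELECT for a filtered table extraction
#'
#' Emits one read-only SELECT with all filter predicates pushed into the WHERE
#' clause. Every literal value is bound as a \code{?} parameter -- never
#' interpolated into the SQL text -- so the statement text depends only on the
#' schema and on the \emph{sizes} of the filter sets. Empty-set filters
#' compile to a contradiction (\code{1 = 0}), preserving empty-means-zero-rows
#' semantics.
#'
#' @param table A table descriptor (element of \code{cdm_schema$tables}).
#' @param filter A [query_filter()].
#' @param concept_column Column to apply the concept filter to; required when
#'   \code{filter$concept_ids} is non-NULL.
#' @param connection Optional connection used for identifier quoting.
#' @return List with \code{sql} (character) and \code{params} (unnamed list).
#' @export
build_select <- function(table, filter = query_filter(),
                         concept_column = NULL, connection = NULL) {
  q <- if (is.null(connection)) function(x) paste0('"', x, '"')
       else function(x) dialect_quote(connection, x)
  cols <- filter$columns
  if (is.null(cols)) cols <- table$columns
  bad <- setdiff(tolower(cols), tolower(table$columns))
  if (length(bad))
    stop(sprintf("unknown column(s) in table '%s': %s", table$name,
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (!is.null(filter$concept_ids) && is.null(concept_column))
    stop("a concept filter requires a concept_column", call. = FALSE)
  person_col <- person_column_of(table)
  where <- character(); params <- list()
  add_in <- function(colname, vals) {
    if (length(vals) == 0L) return(list(clause = "1 = 0", params = list()))
    list(clause = paste0(q(colname), " IN (",
                         paste(rep("?", length(vals)), collapse = ","), ")"),
         params = as.list(vals))
  }
  if (!is.null(filter$person_ids)) {
    if (is.null(person_col))
      stop(sprintf("table '%s' has no person_id column", table$name),
           call. = FALSE)
    p <- add_in(person_col, filter$person_ids)
    where <- c(where, p$clause); params <- c(params, p$params)
  }
  if (!is.null(filter$concept_ids)) {
    if (!tolower(concept_column) %in% tolower(table$columns))
      stop(sprintf("unknown concept column '%s'", concept_column),
           call. = FALSE)
    p <- add_in(concept_column, filter$concept_ids)
    where <- c(where, p$clause); params <- c(params, p$params)
  }
  sql <- paste0("SELECT ", paste(vapply(cols, q, character(1)),
                                 collapse = ", "),
                " FROM ", q(table$name))
  if (length(where)) sql <- paste0(sql, " WHERE ",
                                   paste(where, collapse = " AND "))
  list(sql = sql, params = unname(params))
}

#' Fetch a filtered table with predicate pushdown
#'
#' Executes [build_select()] against the database so filtering happens at the
#' database level and only matching rows cross into the R session. The result
#' is contractually identical (as a row multiset) to fetching the whole table
#' and filtering in memory. Large id sets are split into IN-list batches
#' (default 999 placeholders, a common DBMS limit) whose results are
#' concatenated and ordered by the table's primary key, so batch size never
#' affects the result.
#'
#' @param connection Open DBI connection.
#' @param table Table descriptor from the schema.
#' @param filter A [query_filter()].
#' @param batch_size Maximum ids per IN list.
#' @return An \code{event_records} data frame carrying \code{table_name} and
#'   \code{person_column} attributes.
#' @export
fetch_filtered <- function(connection, table, filter = query_filter(),
                           batch_size = 999L) {
  stopifnot(batch_size >= 1L)
  split_ids <- function(ids) {
    if (is.null(ids)) return(list(NULL))
    if (length(ids) == 0L) return(list(integer(0)))
    split(ids, ceiling(seq_along(ids) / batch_size))
  }
  chunks <- list()
  for (pids in split_ids(filter$person_ids)) {
    for (cids in split_ids(filter$concept_ids)) {
      f <- query_filter(person_ids = pids, concept_ids = cids,
                        columns = filter$columns)
      f$person_ids <- pids; f$concept_ids <- cids  # keep NULL vs empty intact
      qry <- build_select(table, f,
                          concept_column = if (is.null(cids)) NULL else
                            main_concept_column(table),
                          connection = connection)
      res <- tryCatch(
        if (length(qry$params))
          DBI::dbGetQuery(connection, qry$sql, params = qry$params)
        else DBI::dbGetQuery(connection, qry$sql),
        error = function(e) stop(sprintf(
          "retrieval failed for table '%s': %s", table$name,
          conditionMessage(e)), call. = FALSE))
      chunks[[length(chunks) + 1L]] <- res
    }
  }
  out <- do.call(rbind, chunks)
  pk <- primary_key_of(table)
  if (!is.null(pk) && pk %in% names(out))
    out <- out[order(out[[pk]]), , drop = FALSE]
  rownames(out) <- NULL
  event_records(out, table_name = table$name,
                person_column = person_column_of(table))
}

#' Per-concept unique-person counts for a domain table
#'
#' For each concept present in the table, counts the number of distinct
#' persons with at least one event of that concept
#' (\code{COUNT(DISTINCT person_id) GROUP BY concept}). This catalog of
#' unique-individual counts is the quantity disclosure control thresholds.
#'
#' @param connection Open DBI connection.
#' @param table Table descriptor; must carry both a person link and a concept
#'   link column.
#' @return Named integer vector, names = concept ids as characters; concepts
#'   absent from the table are absent from the result.
#' @export
concept_person_counts <- function(connection, table) {
  pcol <- person_column_of(table)
  ccol <- main_concept_column(table)
  if (is.null(pcol) || is.null(ccol))
    stop(sprintf("'%s' is not a domain table (needs person and concept columns)",
                 table$name), call. = FALSE)
  q <- function(x) dialect_quote(connection, x)
  res <- DBI::dbGetQuery(connection, paste0(
    "SELECT ", q(ccol), " AS concept_id, COUNT(DISTINCT ", q(pcol),
    ") AS n FROM ", q(table$name), " GROUP BY ", q(ccol)))
  stats::setNames(as.integer(res$n), as.character(res$concept_id))
}

# ---- internal helpers -------------------------------------------------------

person_column_of <- function(table) {
  i <- which(table$kinds == "person_link")
  if (length(i)) tolower(table$columns[i[1]]) else NULL
}

# The table's identifying concept column: first concept_link in schema order,
# skipping qualifier links (type/source/unit/value_as) that describe the event
# rather than naming it. Matches OMOP DDL column ordering for all domain tables.
main_concept_column <- function(table) {
  cand <- tolower(table$columns[table$kinds == "concept_link"])
  cand <- cand[!grepl("(_type_concept_id|_source_concept_id)$", cand)]
  cand <- setdiff(cand, c("unit_concept_id", "value_as_concept_id",
                          "qualifier_concept_id", "operator_concept_id"))
  if (length(cand)) cand[1] else NULL
}

primary_key_of <- function(table) {
  pk <- paste0(tolower(table$name), "_id")
  if (pk %in% tolower(table$columns)) return(pk)
  fk <- tolower(table$columns)[tolower(table$columns) ==
                                 paste0(tolower(table$name), "_id")]
  if (length(fk)) fk[1] else NULL
}

event_records <- function(df, table_name, person_column = NULL) {
  if (is.null(df)) df <- data.frame()
  attr(df, "table_name") <- table_name
  attr(df, "person_column") <- person_column
  class(df) <- c("event_records", "data.frame")
  df
}
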