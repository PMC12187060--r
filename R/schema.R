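#' Classify an OMOP CDM column by name pattern
#'
#' OMOP CDM tables follow strict naming conventions. Rather than hard-coding a
#' particular CDM version's layout, columns are classified at runtime from
#' their names alone, in strict precedence order:
#'
#' \enumerate{
#'   \item \code{person_link}: the name is exactly \code{person_id}
#'     (case-insensitive) -- the column anchoring a row to an individual.
#'   \item \code{concept_link}: the name ends in \code{_concept_id} -- a
#'     reference into the vocabulary.
#'   \item \code{foreign_key}: the name ends in \code{_id} and its stem (the
#'     name minus the trailing \code{_id}) matches, case-insensitively, a table
#'     present in the schema. A table's own primary key (e.g. \code{note_id}
#'     inside \code{note}) still classifies as \code{foreign_key} but produces
#'     no graph edge.
#'   \item \code{date}: the name ends in \code{_date} or \code{_datetime}.
#'   \item \code{value}: the name contains \code{value} (e.g.
#'     \code{value_as_number}, \code{value_source_value}).
#'   \item \code{other}: anything else, including \code{_id} columns whose stem
#'     matches no table; these are preserved untouched.
#' }
#'
#' @param column_name Column name (non-empty character scalar).
#' @param known_tables Character vector of table names present in the schema.
#' @return One of \code{"person_link"}, \code{"concept_link"},
#'   \code{"foreign_key"}, \code{"date"}, \code{"value"}, \code{"other"}.
#' @examples
#' classify_column("person_id", "person")
#' classify_column("condition_concept_id", character())
#' classify_column("visit_occurrence_id", c("person", "visit_occurrence"))
#' classify_column("value_as_number", character())
#' @export
classify_column <- function(column_name, known_tables = character()) {
  stopifnot(is.character(column_name), length(column_name) == 1L,
            nzchar(column_name))
  nm <- tolower(column_name)
  if (nm == "person_id") return("person_link")
  if (grepl("_concept_id$", nm)) return("concept_link")
  if (grepl("_id$", nm)) {
    stem <- sub("_id$", "", nm)
    if (stem %in% tolower(known_tables)) return("foreign_key")
    # fall through: an _id column with no matching table is kept as-is
  }
  if (grepl("_(date|datetime)$", nm)) return("date")
  if (grepl("value", nm)) return("value")
  "other"
}

#' Introspect an OMOP CDM database into a schema graph
#'
#' Scans the connected database at runtime: lists its tables and columns,
#' classifies every column with [classify_column()], and derives the
#' inter-table link structure solely from those classifications. No fixed CDM
#' version layout is assumed; renaming or adding a domain table changes only
#' the edges incident to it.
#'
#' Edges are created for \code{person_link} columns (to the \code{person}
#' table, when present) and for \code{foreign_key} columns (to the table the
#' stem names, excluding a table's own primary key). \code{concept_link}
#' columns are vocabulary references handled by translation, not joins, and
#' contribute no edges.
#'
#' @param connection An open [DBI::DBIConnection] to the database.
#' @return An object of class \code{cdm_schema}: a list with \code{tables}
#'   (named list; each element has \code{name}, \code{columns},
#'   \code{kinds}, \code{row_count}) and \code{edges} (data frame with columns
#'   \code{from}, \code{column}, \code{to}).
#' @export
introspect_schema <- function(connection) {
  tabs <- sort(tolower(dialect_list_tables(connection)))
  if (length(tabs) == 0L)
    stop("empty schema: the database exposes no tables", call. = FALSE)
  tables <- list()
  for (tb in tabs) {
    cols <- dialect_list_columns(connection, tb)
    if (anyDuplicated(tolower(cols)))
      stop(sprintf("table '%s' has duplicate column names", tb), call. = FALSE)
    kinds <- vapply(cols, classify_column, character(1), known_tables = tabs)
    n <- DBI::dbGetQuery(connection, paste0(
      "SELECT COUNT(*) AS n FROM ", dialect_quote(connection, tb)))$n[1]
    tables[[tb]] <- list(name = tb, columns = cols, kinds = unname(kinds),
                         row_count = as.integer(n))
  }
  edges <- do.call(rbind, lapply(tables, function(td) {
    from <- character(); col <- character(); to <- character()
    for (i in seq_along(td$columns)) {
      k <- td$kinds[i]; cn <- tolower(td$columns[i])
      if (k == "person_link" && "person" %in% tabs && td$name != "person") {
        from <- c(from, td$name); col <- c(col, cn); to <- c(to, "person")
      } else if (k == "foreign_key") {
        stem <- sub("_id$", "", cn)
        if (stem != td$name) {
          from <- c(from, td$name); col <- c(col, cn); to <- c(to, stem)
        }
      }
    }
    data.frame(from = from, column = col, to = to, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), column = character(),
                        to = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  edges <- edges[order(edges$from, edges$column, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(tables = tables, edges = edges), class = "cdm_schema")
}

#' @export
print.cdm_schema <- function(x, ...) {
  cat(sprintf("<cdm_schema: %d tables, %d edges>\n",
              length(x$tables), nrow(x$edges)))
  for (td in x$tables)
    cat(sprintf("  %s (%d rows, %d cols)\n", td$name, td$row_count,
                length(td$columns)))
  invisible(x)
}

#' Shortest join path between two tables
#'
#' Breadth-first search over the undirected edge set of a schema graph.
#' Ties between equally short paths are broken lexicographically by the
#' sequence of intermediate table names, so the result is deterministic for a
#' fixed schema.
#'
#' @param schema A \code{cdm_schema} from [introspect_schema()].
#' @param from_table,to_table Table names present in the schema.
#' @return A data frame of edges (\code{from}, \code{column}, \code{to}) in
#'   traversal order; zero rows iff \code{from_table == to_table}.
#' @export
resolve_join_path <- function(schema, from_table, to_table) {
  from_table <- tolower(from_table); to_table <- tolower(to_table)
  if (!from_table %in% names(schema$tables))
    stop(sprintf("unknown table '%s'", from_table), call. = FALSE)
  if (!to_table %in% names(schema$tables))
    stop(sprintf("unknown table '%s'", to_table), call. = FALSE)
  empty <- schema$edges[0, , drop = FALSE]
  if (from_table == to_table) return(empty)
  # undirected adjacency; neighbours visited in lexicographic (table, column)
  # order so the BFS tree (hence the tie-break) is deterministic
  e <- schema$edges
  und <- rbind(
    data.frame(a = e$from, column = e$column, b = e$to,
               stringsAsFactors = FALSE),
    data.frame(a = e$to, column = e$column, b = e$from,
               stringsAsFactors = FALSE))
  und <- und[order(und$a, und$b, und$column), , drop = FALSE]
  parent <- list()  # node -> list(prev node, edge row index into `e`)
  visited <- from_table
  frontier <- from_table
  found <- FALSE
  while (length(frontier) > 0L && !found) {
    nxt <- character()
    for (node in frontier) {
      nb <- und[und$a == node, , drop = FALSE]
      for (i in seq_len(nrow(nb))) {
        tgt <- nb$b[i]
        if (tgt %in% visited) next
        visited <- c(visited, tgt)
        parent[[tgt]] <- list(prev = node, column = nb$column[i])
        nxt <- c(nxt, tgt)
        if (tgt == to_table) { found <- TRUE; break }
      }
      if (found) break
    }
    frontier <- sort(nxt)
  }
  if (!found)
    stop(sprintf("no join path from '%s' to '%s'", from_table, to_table),
         call. = FALSE)
  # walk back from target
  path <- empty
  node <- to_table
  while (node != from_table) {
    p <- parent[[node]]
    step <- data.frame(from = p$prev, column = p$column, to = node,
                       stringsAsFactors = FALSE)
    path <- rbind(step, path)
    node <- p$prev
  }
  rownames(path) <- NULL
  path
}

# ---- dialect seam -----------------------------------------------------------
# Two queries (list tables, list columns) plus identifier quoting are the only
# DBMS-specific pieces; other engines register by S4-dispatching on the
# connection class through DBI's own generics.

dialect_list_tables <- function(connection) {
  DBI::dbListTables(connection)
}

dialect_list_columns <- function(connection, table) {
  DBI::dbListFields(connection, table)
}

dialect_quote <- function(connection, identifier) {
  as.character(DBI::dbQuoteIdentifier(connection, identifier))
}
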