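#' Load the vocabulary from a database's own concept table
#'
#' Concept translation relies on each site's locally defined vocabulary
#' version, read directly from that database's \code{concept} table rather
#' than from any external reference.
#'
#' @param connection Open DBI connection to a CDM database.
#' @return Named character vector mapping concept id (as character) to
#'   concept name.
#' @export
load_vocabulary <- function(connection) {
  if (!"concept" %in% tolower(dialect_list_tables(connection)))
    stop("database has no concept table", call. = FALSE)
  v <- DBI::dbGetQuery(connection,
                       "SELECT concept_id, concept_name FROM concept")
  if (anyDuplicated(v$concept_id))
    stop("duplicate concept_id in vocabulary", call. = FALSE)
  stats::setNames(as.character(v$concept_name), as.character(v$concept_id))
}

#' Translate concept ids to vocabulary names
#'
#' Replaces the values of every concept-link column of an event record set by
#' the corresponding textual concept names. Ids missing from the vocabulary
#' degrade to \code{concept_<id>} rather than failing, so an incomplete local
#' vocabulary never blocks extraction. Translation is a pure relabeling: row
#' count and all non-concept columns are unchanged.
#'
#' @param records An \code{event_records} data frame (from [fetch_filtered()]).
#' @param vocabulary Named vector from [load_vocabulary()].
#' @param columns Concept columns to translate; defaults to every column whose
#'   name ends in \code{_concept_id}.
#' @return The records with concept columns translated to character.
#' @export
translate_concepts <- function(records, vocabulary, columns = NULL) {
  if (is.null(columns))
    columns <- grep("_concept_id$", names(records), value = TRUE)
  for (cl in columns) {
    ids <- as.character(records[[cl]])
    nm <- unname(vocabulary[ids])
    miss <- is.na(nm) & !is.na(ids)
    nm[miss] <- paste0("concept_", ids[miss])
    nm[is.na(ids)] <- NA_character_
    records[[cl]] <- nm
  }
  records
}

#' Sanitize a concept name into a syntactic column identifier
#'
#' Lowercases, collapses every run of non-alphanumeric characters to a single
#' underscore, strips leading/trailing underscores and prefixes an underscore
#' when the result would start with a digit. Deterministic; errors on input
#' with no alphanumeric content.
#'
#' @param concept_name Non-empty character scalar.
#' @return A lowercase identifier.
#' @examples
#' sanitize_identifier("Vitamin D deficiency")
#' sanitize_identifier("SARS-COV2 (antigen)")
#' sanitize_identifier("2,4-D exposure")
#' @export
sanitize_identifier <- function(concept_name) {
  stopifnot(is.character(concept_name), length(concept_name) == 1L,
            nzchar(concept_name))
  x <- tolower(concept_name)
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  if (!nzchar(x))
    stop(sprintf("'%s' contains no alphanumeric characters", concept_name),
         call. = FALSE)
  if (grepl("^[0-9]", x)) x <- paste0("_", x)
  x
}

#' Pivot long-format events into a one-row-per-person wide table
#'
#' Reformats a table holding multiple events per person into wide format: one
#' row per distinct person, one column per concept x attribute combination.
#' Repeated events of the same concept are spread over occurrence-indexed
#' columns named \code{<concept>.<attribute>.<k>}, with occurrences ordered
#' chronologically by \code{options$date_column} (ties broken by the source
#' table's primary key); concepts occurring at most once per person omit the
#' index. Distinct concept ids whose sanitized names collide are
#' disambiguated by appending \code{_<concept_id>}.
#'
#' Every non-NA cell is traceable through the \code{provenance} attribute
#' (column name -> concept id, source attribute, occurrence index) back to
#' exactly one source event; no event is silently duplicated or dropped.
#'
#' @param records \code{event_records} containing person and concept columns;
#'   the concept column must hold integer concept ids.
#' @param concept_column Name of the concept id column.
#' @param attribute_columns Event attribute columns to spread.
#' @param options A [longitudinal_options()].
#' @param vocabulary Optional vocabulary for concept naming; ids missing from
#'   it (or when NULL) are named \code{concept_<id>}.
#' @return A \code{wide_dataset}: data frame with \code{person_id} first and a
#'   \code{provenance} attribute.
#' @export
pivot_events_wide <- function(records, concept_column, attribute_columns,
                              options = longitudinal_options(),
                              vocabulary = NULL) {
  pcol <- attr(records, "person_column")
  if (is.null(pcol)) pcol <- "person_id"
  if (!pcol %in% names(records))
    stop("records lack a person column; cannot pivot", call. = FALSE)
  stopifnot(concept_column %in% names(records),
            all(attribute_columns %in% names(records)))
  df <- as.data.frame(records)
  persons <- sort(unique(df[[pcol]]))

  # chronological order within person x concept; primary key breaks ties
  dcol <- options$date_column
  if (!is.null(dcol) && dcol %in% names(df)) {
    dts <- as.Date(df[[dcol]])
    ord <- order(df[[pcol]], df[[concept_column]], dts,
                 seq_len(nrow(df)))
  } else {
    ord <- order(df[[pcol]], df[[concept_column]], seq_len(nrow(df)))
  }
  pk <- grep(paste0("^", tolower(attr(records, "table_name") %||% ""), "_id$"),
             tolower(names(df)), value = TRUE)
  if (length(pk) == 1L) {
    if (!is.null(dcol) && dcol %in% names(df)) {
      ord <- order(df[[pcol]], df[[concept_column]], as.Date(df[[dcol]]),
                   df[[pk]])
    } else {
      ord <- order(df[[pcol]], df[[concept_column]], df[[pk]])
    }
  }
  df <- df[ord, , drop = FALSE]

  key <- paste(df[[pcol]], df[[concept_column]])
  occ <- stats::ave(seq_len(nrow(df)), key, FUN = seq_along)

  cids <- sort(unique(df[[concept_column]]))
  base_name <- vapply(cids, function(cid) {
    nm <- if (!is.null(vocabulary)) unname(vocabulary[as.character(cid)])
          else NA_character_
    if (is.na(nm)) paste0("concept_", cid) else sanitize_identifier(nm)
  }, character(1))
  dup <- base_name %in% base_name[duplicated(base_name)]
  base_name[dup] <- paste0(base_name[dup], "_", cids[dup])
  names(base_name) <- as.character(cids)

  max_occ <- tapply(occ, df[[concept_column]], max)

  out <- data.frame(person_id = persons)
  names(out)[1] <- "person_id"
  prov <- data.frame(column = character(), concept_id = numeric(),
                     attribute = character(), occurrence = integer(),
                     stringsAsFactors = FALSE)
  pidx <- match(df[[pcol]], persons)
  for (cid in cids) {
    cn <- base_name[[as.character(cid)]]
    mo <- max_occ[[as.character(cid)]]
    sel0 <- df[[concept_column]] == cid
    for (k in seq_len(mo)) {
      sel <- sel0 & occ == k
      for (a in attribute_columns) {
        col <- if (mo == 1L) paste(cn, a, sep = ".")
               else paste(cn, a, k, sep = ".")
        v <- rep(NA, length(persons))
        v <- as.vector(v, mode = if (is.numeric(df[[a]])) "numeric"
                                 else "character")
        v[pidx[sel]] <- df[[a]][sel]
        out[[col]] <- v
        prov <- rbind(prov, data.frame(
          column = col, concept_id = cid, attribute = a, occurrence = k,
          stringsAsFactors = FALSE))
      }
    }
  }
  wide_dataset(out, provenance = prov)
}

#' Longitudinal handling options
#'
#' @param mode \code{"long"} (one row per event, the default) or
#'   \code{"wide"} (one row per person with occurrence-indexed columns).
#' @param complete_time_points If TRUE, pad each person's series so all
#'   persons share the union of observed time points (see
#'   [complete_time_points()]).
#' @param date_column Column used for chronological ordering / time indexing.
#' @return An object of class \code{longitudinal_options}.
#' @export
longitudinal_options <- function(mode = c("long", "wide"),
                                 complete_time_points = FALSE,
                                 date_column = NULL) {
  mode <- match.arg(mode)
  structure(list(mode = mode, complete_time_points = complete_time_points,
                 date_column = date_column), class = "longitudinal_options")
}

#' Pad per-person series to the union of observed time points
#'
#' Identifies the full set of time points observed across all persons for the
#' record set and inserts, for every person lacking a record at one of those
#' times, an entry carrying the correct time index and NA in every other
#' non-person column. Original entries are not modified; the operation is
#' idempotent, and afterwards every person has the same number of entries.
#'
#' @param records Long-format data frame with a person column and a date
#'   column.
#' @param date_column Name of the date column.
#' @param person_column Name of the person column.
#' @return The padded data frame, ordered by person then date.
#' @export
complete_time_points <- function(records, date_column,
                                 person_column = "person_id") {
  stopifnot(date_column %in% names(records),
            person_column %in% names(records))
  df <- as.data.frame(records)
  d <- tryCatch(as.Date(df[[date_column]]),
                error = function(e) NA)
  if (length(d) && anyNA(d) || (nrow(df) && all(is.na(d))))
    stop(sprintf("unparseable dates in %s.%s",
                 attr(records, "table_name") %||% "<records>", date_column),
         call. = FALSE)
  if (nrow(df) == 0L) return(records)
  df[[date_column]] <- as.character(d)
  all_t <- sort(unique(df[[date_column]]))
  persons <- unique(df[[person_column]])
  add <- list()
  for (p in persons) {
    have <- df[[date_column]][df[[person_column]] == p]
    need <- setdiff(all_t, have)
    if (length(need)) {
      pad <- df[rep(NA_integer_, length(need)), , drop = FALSE]
      pad[[person_column]] <- p
      pad[[date_column]] <- need
      add[[length(add) + 1L]] <- pad
    }
  }
  out <- rbind(df, do.call(rbind, add))
  out <- out[order(out[[person_column]], out[[date_column]]), , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("table_name", "person_column"))
    attr(out, a) <- attr(records, a)
  class(out) <- class(records)
  out
}

#' Left-join two person-level tables
#'
#' Merges on person id with the left table as the cohort anchor: persons
#' present only in the right table are dropped; left persons missing from the
#' right get NA in the new columns. Column name collisions are suffixed
#' \code{_x} (left) and \code{_y} (right). Either input having duplicated
#' person rows is a structural error.
#'
#' @param left,right \code{wide_dataset}s (or data frames with a
#'   \code{person_id} column).
#' @return A \code{wide_dataset} with left's persons, in left's order.
#' @export
merge_on_person <- function(left, right) {
  for (nm in list(list(left, "left"), list(right, "right"))) {
    if (!"person_id" %in% names(nm[[1]]))
      stop(sprintf("%s table lacks person_id", nm[[2]]), call. = FALSE)
    if (anyDuplicated(nm[[1]]$person_id))
      stop(sprintf("%s table has duplicate person rows", nm[[2]]),
           call. = FALSE)
  }
  l <- as.data.frame(left); r <- as.data.frame(right)
  m <- merge(l, r, by = "person_id", all.x = TRUE, sort = FALSE,
             suffixes = c("_x", "_y"))
  m <- m[match(l$person_id, m$person_id), , drop = FALSE]
  rownames(m) <- NULL
  prov <- rbind(attr(left, "provenance"), attr(right, "provenance"))
  wide_dataset(m, provenance = prov)
}

#' Derive a cohort filter from an existing person-level table
#'
#' Extracts the person identifiers of a server-side table into a
#' [query_filter()] so subsequent extractions are restricted to that cohort.
#' The id set lives only inside the filter object, which prints as a count --
#' cohort membership is never rendered into client-visible text.
#'
#' @param existing_table A \code{wide_dataset} (or data frame with
#'   \code{person_id}).
#' @return A [query_filter()] with \code{person_ids} set (possibly empty).
#' @export
build_cohort_filter <- function(existing_table) {
  if (!"person_id" %in% names(existing_table))
    stop("table lacks person_id", call. = FALSE)
  query_filter(person_ids = unique(existing_table$person_id))
}

#' @export
print.wide_dataset <- function(x, ...) {
  cat(sprintf("<wide_dataset: %d persons x %d columns>\n", nrow(x),
              ncol(x) - 1L))
  NextMethod()
}

#' Write / read a wide dataset as CSV
#'
#' RFC-4180 CSV with a header row; NA serialized as an empty field.
#'
#' @param x A \code{wide_dataset}.
#' @param path File path.
#' @return \code{write_wide_csv} returns the path invisibly;
#'   \code{read_wide_csv} returns a \code{wide_dataset} (without provenance,
#'   which is not serialized).
#' @export
write_wide_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_wide_csv
#' @export
read_wide_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  wide_dataset(df, provenance = NULL)
}

wide_dataset <- function(df, provenance = NULL) {
  attr(df, "provenance") <- provenance
  attr(df, "person_column") <- "person_id"
  class(df) <- c("wide_dataset", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
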