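#' Create a site server over a CDM database
#'
#' A site simulates, in-process, one data-holding server of a federated
#' network: it owns a database connection, its own disclosure settings and a
#' private symbol table of assembled person-level datasets. Symbols are never
#' serialized back to the caller; the only outward messages are assignment
#' acknowledgements (column names that survived disclosure filtering) and
#' fixed-shape aggregate payloads. Two sites opened on the same database file
#' have fully independent sessions.
#'
#' @param database_path Path to an SQLite CDM database file.
#' @param settings A [disclosure_settings()].
#' @param site_id Identifier for the site (defaults to the file name).
#' @return An object of class \code{omop_site}.
#' @export
create_site <- function(database_path, settings = disclosure_settings(),
                        site_id = basename(database_path)) {
  if (!file.exists(database_path))
    stop(sprintf("cannot connect: database '%s' not readable", database_path),
         call. = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), database_path)
  site <- new.env(parent = emptyenv())
  site$site_id <- site_id
  site$connection <- con
  site$settings <- settings
  site$symbols <- new.env(parent = emptyenv())
  site$schema <- NULL        # introspected lazily
  site$vocabulary <- NULL
  class(site) <- "omop_site"
  site
}

#' @export
print.omop_site <- function(x, ...) {
  cat(sprintf("<omop_site '%s': %d symbol(s), subset threshold %d>\n",
              x$site_id, length(ls(x$symbols)), x$settings$subset_threshold))
  invisible(x)
}

site_schema <- function(site) {
  if (is.null(site$schema)) site$schema <- introspect_schema(site$connection)
  site$schema
}

site_vocabulary <- function(site) {
  if (is.null(site$vocabulary))
    site$vocabulary <- load_vocabulary(site$connection)
  site$vocabulary
}

#' Close a site's database connection
#' @param site An \code{omop_site}.
#' @export
close_site <- function(site) {
  DBI::dbDisconnect(site$connection)
  invisible(NULL)
}

#' Extraction specification for a site assignment
#'
#' @param table Domain table to extract.
#' @param filter A [query_filter()].
#' @param options A [longitudinal_options()].
#' @param wide If TRUE, pivot to one row per person ([pivot_events_wide()]);
#'   otherwise keep long format.
#' @param attribute_columns Attribute columns to spread when pivoting;
#'   defaults to the table's date and value columns.
#' @return An object of class \code{extraction_spec}.
#' @export
extraction_spec <- function(table, filter = query_filter(),
                            options = longitudinal_options(),
                            wide = TRUE, attribute_columns = NULL) {
  structure(list(table = table, filter = filter, options = options,
                 wide = wide, attribute_columns = attribute_columns),
            class = "extraction_spec")
}

#' Assign a filtered, transformed dataset to a server-side symbol
#'
#' Runs the extraction pipeline entirely on the site: fetch with pushdown
#' filters, drop concepts whose unique-person count falls below the site's
#' subset threshold, translate concepts against the site's own vocabulary,
#' optionally pivot to wide format (with time-point completion if requested),
#' validate the result against the disclosure threshold and bind it to a
#' symbol in the site's private session. Re-assigning a symbol replaces it.
#'
#' The return value acknowledges success and lists the surviving column
#' names; it carries no row data and no person identifiers.
#'
#' @param site An [create_site()] server.
#' @param symbol Name to bind the dataset to.
#' @param spec An [extraction_spec()].
#' @return Invisibly, a list with \code{symbol}, \code{columns} and
#'   \code{n_columns}.
#' @export
site_assign_dataset <- function(site, symbol, spec) {
  schema <- site_schema(site)
  tname <- tolower(spec$table)
  td <- schema$tables[[tname]]
  if (is.null(td))
    stop(sprintf("table '%s' does not exist at site '%s'", spec$table,
                 site$site_id), call. = FALSE)
  ccol <- main_concept_column(td)
  # per-concept disclosure screen: restrict the fetch itself to admissible
  # concepts so sub-threshold data never enters the session symbol
  filter <- spec$filter
  if (!is.null(ccol) && !is.null(person_column_of(td))) {
    counts <- concept_person_counts(site$connection, td)
    ok <- filter_concept_catalog(counts, site$settings)
    keep <- as.integer(names(ok))
    filter <- query_filter(person_ids = filter$person_ids,
                           concept_ids = if (is.null(filter$concept_ids))
                             keep else intersect(filter$concept_ids, keep),
                           columns = filter$columns)
    filter$person_ids <- spec$filter$person_ids  # preserve NULL vs empty
  }
  rec <- fetch_filtered(site$connection, td, filter)
  # re-screen after person filtering: the cohort restriction can push a
  # concept below threshold even if it passes on the full table
  pcol <- person_column_of(td)
  if (!is.null(ccol) && !is.null(pcol) && nrow(rec)) {
    nper <- tapply(rec[[pcol]], rec[[ccol]],
                   function(p) length(unique(p)))
    bad <- names(nper)[!passes_subset_threshold(as.integer(nper),
                                                site$settings)]
    if (length(bad)) {
      tn <- attr(rec, "table_name")
      rec <- rec[!(as.character(rec[[ccol]]) %in% bad), , drop = FALSE]
      rec <- event_records(rec, table_name = tn, person_column = pcol)
    }
  }
  opts <- spec$options
  if (is.null(opts$date_column))
    opts$date_column <- default_date_column(td)
  out <- rec
  if (isTRUE(spec$wide) && !is.null(ccol)) {
    attrs <- spec$attribute_columns
    if (is.null(attrs))
      attrs <- td$columns[td$kinds %in% c("date", "value")]
    attrs <- intersect(attrs, names(rec))
    r <- rec
    if (isTRUE(opts$complete_time_points) && !is.null(opts$date_column) &&
        nrow(r))
      r <- complete_time_points(r, opts$date_column, pcol)
    out <- pivot_events_wide(r, ccol, attrs, options = opts,
                             vocabulary = site_vocabulary(site))
  } else if (!isTRUE(spec$wide)) {
    if (isTRUE(opts$complete_time_points) && !is.null(opts$date_column) &&
        nrow(out))
      out <- complete_time_points(out, opts$date_column, pcol)
    out <- translate_concepts(out, site_vocabulary(site))
  }
  validate_output_table(out, site$settings, table_name = td$name)
  assign(symbol, out, envir = site$symbols)
  invisible(list(symbol = symbol, columns = names(out),
                 n_columns = length(names(out))))
}

#' Bind an arbitrary person-level table to a site symbol
#'
#' Server-side convenience for composing datasets (e.g. the result of
#' [merge_on_person()] across previously assigned symbols). The table is
#' disclosure-validated before binding.
#'
#' @param site An \code{omop_site}.
#' @param symbol Symbol name.
#' @param table A person-level data frame.
#' @return Invisibly, the acknowledgement list (symbol + column names).
#' @export
site_bind_table <- function(site, symbol, table) {
  validate_output_table(table, site$settings, table_name = symbol)
  assign(symbol, table, envir = site$symbols)
  invisible(list(symbol = symbol, columns = names(table),
                 n_columns = length(names(table))))
}

site_get_symbol <- function(site, symbol) {
  if (!exists(symbol, envir = site$symbols, inherits = FALSE))
    stop(sprintf("symbol '%s' not found at site '%s'", symbol, site$site_id),
         call. = FALSE)
  get(symbol, envir = site$symbols, inherits = FALSE)
}

#' Compute one model-iteration aggregate payload at a site
#'
#' The only analytic message a site ever returns: its IRLS sufficient
#' statistics (information matrix, score vector, deviance, row count) for the
#' requested symbol, model spec and coefficient vector. The request is
#' refused -- with an opaque disclosure error carrying no counts -- when the
#' site's complete-case sample is non-empty but smaller than the subset
#' threshold, or when the parameters/observations ratio exceeds the
#' configured limit.
#'
#' @param site An \code{omop_site}.
#' @param request List with \code{symbol}, \code{spec} (a [glm_spec()]) and
#'   \code{beta} (current coefficients).
#' @return List of class \code{aggregate_payload}: \code{site_id},
#'   \code{n_obs}, \code{info_matrix}, \code{score_vector}, \code{deviance}.
#' @export
site_aggregate <- function(site, request) {
  tab <- site_get_symbol(site, request$symbol)
  spec <- request$spec
  mm <- model_matrix_for(as.data.frame(tab), spec)
  n <- length(mm$y)
  p <- ncol(mm$X)
  if (n > 0 && n < site$settings$subset_threshold)
    stop(disclosure_error(sprintf(
      "aggregate request refused at site '%s'", site$site_id)))
  if (n == 0 || p / n > site$settings$glm_ratio)
    stop(disclosure_error(sprintf(
      "aggregate request refused at site '%s'", site$site_id)))
  contrib <- irls_local_contribution(mm$X, mm$y, request$beta, spec$family)
  structure(list(site_id = site$site_id, n_obs = contrib$n,
                 info_matrix = contrib$info, score_vector = contrib$score,
                 deviance = contrib$deviance),
            class = "aggregate_payload")
}

#' @export
print.aggregate_payload <- function(x, ...) {
  cat(sprintf("<aggregate_payload from '%s': n = %d, p = %d>\n",
              x$site_id, x$n_obs, nrow(x$info_matrix)))
  invisible(x)
}

#' Open a roster of sites from a JSON configuration
#'
#' The roster is a JSON array of objects with fields \code{site_id},
#' \code{database} (path) and optionally \code{subset_threshold}.
#'
#' @param path Path to the roster JSON file.
#' @return List of \code{omop_site} objects.
#' @export
open_site_roster <- function(path) {
  roster <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(roster)), function(i) {
    thr <- if ("subset_threshold" %in% names(roster) &&
               !is.na(roster$subset_threshold[i]))
      roster$subset_threshold[i] else 5L
    create_site(roster$database[i],
                disclosure_settings(subset_threshold = thr),
                site_id = roster$site_id[i])
  })
}

default_date_column <- function(td) {
  for (pat in c("_start_date$", "_date$", "_datetime$")) {
    hit <- td$columns[grepl(pat, tolower(td$columns))]
    if (length(hit)) return(tolower(hit[1]))
  }
  NULL
}
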