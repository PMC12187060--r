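# Shared fixtures: tiny CDM databases built in code, plus independent
# oracles (BFS over an adjacency list, nested-loop join, un-pivot).

new_sqlite <- function(path = tempfile(fileext = ".sqlite")) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  list(con = con, path = path)
}

# A hand-built v5.3-shaped database: person, two domain tables, a visit
# table carrying provider_id (so measurement -> provider takes two hops),
# a provider table, a concept vocabulary and one non-CDM extra table.
make_mini_cdm <- function(path = tempfile(fileext = ".sqlite"),
                          with_extra = FALSE) {
  db <- new_sqlite(path)
  con <- db$con
  DBI::dbWriteTable(con, "person", data.frame(
    person_id = 1:6, gender_concept_id = c(8507L, 8532L)[c(1, 2, 1, 2, 1, 2)],
    year_of_birth = c(1950L, 1960L, 1970L, 1980L, 1990L, 2000L)))
  DBI::dbWriteTable(con, "condition_occurrence", data.frame(
    condition_occurrence_id = 1:7,
    person_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L),
    condition_concept_id = c(317009L, 317009L, 317009L, 317009L, 317009L,
                             255573L, 255573L),
    condition_start_date = c("2020-01-01", "2020-06-01", "2019-03-02",
                             "2018-07-04", "2021-02-10", "2020-05-05",
                             "2017-11-30"),
    visit_occurrence_id = c(1L, 2L, 3L, 4L, 5L, 6L, 7L)))
  DBI::dbWriteTable(con, "measurement", data.frame(
    measurement_id = 1:5,
    person_id = c(1L, 1L, 2L, 3L, 3L),
    measurement_concept_id = c(3004249L, 3004249L, 3004249L, 9191L, 9191L),
    measurement_date = c("2020-02-01", "2020-01-01", "2020-03-01",
                         "2020-04-01", "2020-05-01"),
    value_as_number = c(13.5, 12.8, 14.1, 1, 0),
    visit_occurrence_id = c(1L, 2L, 3L, 4L, 5L)))
  DBI::dbWriteTable(con, "visit_occurrence", data.frame(
    visit_occurrence_id = 1:7, person_id = c(1L, 1L, 2L, 3L, 3L, 5L, 6L),
    provider_id = c(1L, 1L, 2L, 1L, 2L, 1L, 2L),
    visit_start_date = rep("2020-01-01", 7)))
  DBI::dbWriteTable(con, "provider", data.frame(
    provider_id = 1:2, provider_name = c("A", "B")))
  DBI::dbWriteTable(con, "concept", data.frame(
    concept_id = c(317009L, 255573L, 3004249L, 9191L, 8507L, 8532L),
    concept_name = c("Asthma", "Chronic obstructive pulmonary disease",
                     "Hemoglobin", "Positive", "MALE", "FEMALE"),
    domain_id = c("Condition", "Condition", "Measurement", "Meas Value",
                  "Gender", "Gender"),
    vocabulary_id = "SNOMED"))
  if (with_extra)
    DBI::dbWriteTable(con, "site_notes", data.frame(
      note_id = 1:2, person_id = c(1L, 2L), txt = c("a", "b")))
  db
}

# Random event table for property-style pushdown / pivot tests.
random_event_table <- function(con, n_rows = 200, n_persons = 30,
                               concepts = c(101L, 202L, 303L)) {
  df <- data.frame(
    measurement_id = seq_len(n_rows),
    person_id = sample.int(n_persons, n_rows, replace = TRUE),
    measurement_concept_id = sample(concepts, n_rows, replace = TRUE),
    measurement_date = as.character(as.Date("2018-01-01") +
                                      sample.int(1000, n_rows, TRUE)),
    value_as_number = round(stats::runif(n_rows, 1, 20), 2))
  DBI::dbWriteTable(con, "measurement", df, overwrite = TRUE)
  df
}

# Independent shortest-path oracle: plain BFS distance over an edge list.
bfs_distance <- function(edges, from, to) {
  if (from == to) return(0L)
  adj <- c(split(edges$to, edges$from),
           split(edges$from, edges$to))
  dist <- stats::setNames(0L, from)
  frontier <- from
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) for (w in unlist(adj[names(adj) == v])) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        if (w == to) return(dist[[w]])
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  NA_integer_
}

# Un-pivot a wide_dataset through its provenance back to the long table.
unpivot_via_provenance <- function(wide) {
  prov <- attr(wide, "provenance")
  out <- list()
  for (i in seq_len(nrow(prov))) {
    v <- wide[[prov$column[i]]]
    keep <- !is.na(v)
    if (!any(keep)) next
    out[[i]] <- data.frame(person_id = wide$person_id[keep],
                           concept_id = prov$concept_id[i],
                           attribute = prov$attribute[i],
                           occurrence = prov$occurrence[i],
                           value = as.character(v[keep]),
                           stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  d[order(d$person_id, d$concept_id, d$attribute, d$occurrence), ,
    drop = FALSE]
}

expect_same_multiset <- function(got, want) {
  norm <- function(d) {
    d <- as.data.frame(d)[, sort(names(as.data.frame(d))), drop = FALSE]
    d <- d[do.call(order, d), , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  expect_equal(norm(got), norm(want))
}
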