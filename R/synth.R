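#' Configuration for the synthetic CDM generator
#'
#' Describes a cohort with binary predictors, a logistic binary outcome and a
#' longitudinal measurement series, to be materialized as an OMOP-CDM-shaped
#' SQLite database with a known ground truth. Predictors are independent
#' Bernoulli indicators at the stated prevalences (a pairwise correlation
#' knob is available but off by default, so the generating logistic model is
#' exactly the marginal model and recovery checks are unambiguous). The
#' outcome indicator is drawn from
#' \eqn{logit\,P(y=1) = \alpha + \sum_j \beta_j x_j}.
#'
#' @param n_persons Number of persons.
#' @param seed Integer seed; identical config + seed reproduces the database
#'   exactly.
#' @param predictors Data frame with columns \code{concept_id}, \code{name},
#'   \code{domain} (\code{"condition_occurrence"} or \code{"observation"}),
#'   \code{prevalence} (in (0,1)).
#' @param outcome List with \code{concept_id}, \code{name}, \code{intercept}
#'   (log-odds), \code{log_or} (numeric vector, one per predictor).
#' @param longitudinal List with \code{concept_id}, \code{name},
#'   \code{n_time_points}, \code{missing_rate} (per-entry
#'   missing-at-random probability).
#' @param n_sites Number of sites the cohort may be partitioned into.
#' @param correlation Optional shared-latent correlation in [0,1) between
#'   predictor indicators; 0 keeps them independent.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_persons, seed = 1L,
                         predictors,
                         outcome,
                         longitudinal = list(concept_id = 2000000010,
                                             name = "Hemoglobin",
                                             n_time_points = 4L,
                                             missing_rate = 0.2),
                         n_sites = 1L, correlation = 0) {
  stopifnot(n_persons >= 1, n_sites >= 1,
            is.data.frame(predictors),
            all(c("concept_id", "name", "domain", "prevalence") %in%
                  names(predictors)),
            all(predictors$prevalence > 0 & predictors$prevalence < 1),
            length(outcome$log_or) == nrow(predictors),
            correlation >= 0, correlation < 1)
  if (n_sites > n_persons)
    stop("n_sites must not exceed n_persons", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons), seed = as.integer(seed),
                 predictors = predictors, outcome = outcome,
                 longitudinal = longitudinal,
                 n_sites = as.integer(n_sites), correlation = correlation),
            class = "synth_config")
}

#' The default calibration scenario: COPD and four binary predictors
#'
#' A chronic-obstructive-pulmonary-disease cohort with the four predictors
#' whose associations with COPD are well established in the clinical
#' literature -- tobacco use, vitamin D deficiency, history of asthma and
#' history of rheumatoid arthritis -- with generating odds ratios 6.43, 6.14,
#' 20.02 and 8.22 as calibration defaults. Prevalences (0.25, 0.10, 0.12,
#' 0.03) and baseline log-odds (-4) are the package's own epidemiologically
#' plausible choices.
#'
#' @param n_persons,seed,n_sites Passed to [synth_config()].
#' @return A \code{synth_config}.
#' @export
copd_demo_config <- function(n_persons = 20000L, seed = 1L, n_sites = 3L) {
  predictors <- data.frame(
    concept_id = c(2000000001, 2000000002, 317009, 2000000004),
    name = c("Tobacco use", "Vitamin D deficiency", "Asthma",
             "Rheumatoid arthritis"),
    domain = c("observation", "condition_occurrence",
               "condition_occurrence", "condition_occurrence"),
    prevalence = c(0.25, 0.10, 0.12, 0.03),
    stringsAsFactors = FALSE)
  outcome <- list(concept_id = 2000000005,
                  name = "Chronic obstructive pulmonary disease",
                  intercept = -4,
                  log_or = log(c(6.43, 6.14, 20.02, 8.22)))
  synth_config(n_persons = n_persons, seed = seed, predictors = predictors,
               outcome = outcome, n_sites = n_sites)
}

#' Simulate the person-level cohort of a synthetic configuration
#'
#' Draws the demographic attributes, predictor indicators and logistic
#' outcome for each person. This is the sampling step [generate_cdm()]
#' materializes into a relational database; it is exposed directly so
#' statistical studies (e.g. coverage of confidence intervals over many
#' replicates) can run on the exact generating model without touching disk.
#'
#' @param config A [synth_config()].
#' @return Data frame with \code{person_id}, \code{gender_concept_id},
#'   \code{year_of_birth}, one 0/1 column per predictor (sanitized name) and
#'   the outcome column (sanitized name).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_persons
  pr <- config$predictors
  df <- data.frame(
    person_id = seq_len(n),
    gender_concept_id = sample(c(8507L, 8532L), n, replace = TRUE),
    year_of_birth = sample(1930:2000, n, replace = TRUE))
  if (config$correlation > 0) {
    # shared standard-normal latent induces exchangeable positive correlation
    shared <- stats::rnorm(n)
    r <- config$correlation
    for (j in seq_len(nrow(pr))) {
      zj <- sqrt(r) * shared + sqrt(1 - r) * stats::rnorm(n)
      df[[sanitize_identifier(pr$name[j])]] <-
        as.integer(zj < stats::qnorm(pr$prevalence[j]))
    }
  } else {
    for (j in seq_len(nrow(pr)))
      df[[sanitize_identifier(pr$name[j])]] <-
        stats::rbinom(n, 1L, pr$prevalence[j])
  }
  xb <- config$outcome$intercept
  for (j in seq_len(nrow(pr)))
    xb <- xb + config$outcome$log_or[j] *
      df[[sanitize_identifier(pr$name[j])]]
  df[[sanitize_identifier(config$outcome$name)]] <-
    stats::rbinom(n, 1L, stats::plogis(xb))
  df
}

#' Materialize a synthetic OMOP CDM database
#'
#' Writes an SQLite database shaped like an OMOP CDM v5.3 instance: a
#' \code{person} table with demographics; \code{condition_occurrence} and
#' \code{observation} rows for each person's positive predictor indicators
#' and for the outcome; a longitudinal \code{measurement} series on a shared
#' time grid with missing-at-random gaps; and a \code{concept} vocabulary
#' table covering every concept id used. Event dates are uniform over
#' 2015--2020 (the measurement series sits on a fixed quarterly grid).
#' Synthetic concepts use ids at or above 2,000,000,000, OMOP's conventional
#' local-concept range; well-known standard ids (e.g. 8507/8532 gender,
#' 317009 asthma, 9191 "Positive") are kept.
#'
#' @param config A [synth_config()].
#' @param destination Path of the SQLite file to create (overwritten).
#' @return The destination path, invisibly.
#' @export
generate_cdm <- function(config, destination) {
  stopifnot(inherits(config, "synth_config"))
  cohort <- simulate_cohort(config)   # seeds the RNG from config$seed
  n <- config$n_persons
  pr <- config$predictors

  if (file.exists(destination)) file.remove(destination)
  con <- DBI::dbConnect(RSQLite::SQLite(), destination)
  on.exit(DBI::dbDisconnect(con))

  person <- cohort[, c("person_id", "gender_concept_id", "year_of_birth")]
  DBI::dbWriteTable(con, "person", person)

  rdate <- function(k)
    as.character(as.Date("2015-01-01") +
                   sample.int(as.integer(as.Date("2020-12-31") -
                                           as.Date("2015-01-01")) + 1L, k,
                              replace = TRUE) - 1L)
  cond <- list(); obs <- list()
  add_events <- function(domain, persons, concept_id) {
    k <- length(persons)
    if (k == 0L) return()
    if (domain == "condition_occurrence") {
      cond[[length(cond) + 1L]] <<- data.frame(
        person_id = persons, condition_concept_id = concept_id,
        condition_start_date = rdate(k),
        condition_type_concept_id = 32020L)
    } else {
      obs[[length(obs) + 1L]] <<- data.frame(
        person_id = persons, observation_concept_id = concept_id,
        observation_date = rdate(k), value_as_concept_id = 9191L)
    }
  }
  for (j in seq_len(nrow(pr))) {
    who <- cohort$person_id[cohort[[sanitize_identifier(pr$name[j])]] == 1L]
    add_events(pr$domain[j], who, pr$concept_id[j])
  }
  add_events("condition_occurrence",
             cohort$person_id[
               cohort[[sanitize_identifier(config$outcome$name)]] == 1L],
             config$outcome$concept_id)

  bind_events <- function(lst, id_col) {
    if (length(lst) == 0L) return(NULL)
    d <- do.call(rbind, lst)
    d <- d[order(d$person_id, d[[2]]), , drop = FALSE]
    d <- cbind(stats::setNames(data.frame(seq_len(nrow(d))), id_col), d)
    rownames(d) <- NULL
    d
  }
  cond_df <- bind_events(cond, "condition_occurrence_id")
  obs_df <- bind_events(obs, "observation_id")
  empty_cond <- data.frame(condition_occurrence_id = integer(),
                           person_id = integer(),
                           condition_concept_id = integer(),
                           condition_start_date = character(),
                           condition_type_concept_id = integer())
  empty_obs <- data.frame(observation_id = integer(), person_id = integer(),
                          observation_concept_id = integer(),
                          observation_date = character(),
                          value_as_concept_id = integer())
  DBI::dbWriteTable(con, "condition_occurrence",
                    if (is.null(cond_df)) empty_cond else cond_df)
  DBI::dbWriteTable(con, "observation",
                    if (is.null(obs_df)) empty_obs else obs_df)

  # longitudinal measurement series on a shared quarterly grid, MAR gaps
  lg <- config$longitudinal
  grid <- as.character(seq(as.Date("2019-01-01"), by = "3 months",
                           length.out = lg$n_time_points))
  meas <- expand.grid(person_id = cohort$person_id, measurement_date = grid,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(meas)) >= lg$missing_rate
  meas <- meas[keep, , drop = FALSE]
  meas$measurement_concept_id <- lg$concept_id
  meas$value_as_number <- round(stats::rnorm(nrow(meas), 13.5, 1.5), 1)
  meas <- meas[order(meas$person_id, meas$measurement_date), , drop = FALSE]
  meas <- cbind(measurement_id = seq_len(nrow(meas)), meas)
  DBI::dbWriteTable(con, "measurement",
                    meas[, c("measurement_id", "person_id",
                             "measurement_concept_id", "measurement_date",
                             "value_as_number")])

  concept <- unique(data.frame(
    concept_id = c(pr$concept_id, config$outcome$concept_id, lg$concept_id,
                   8507L, 8532L, 9191L, 32020L),
    concept_name = c(pr$name, config$outcome$name, lg$name,
                     "MALE", "FEMALE", "Positive", "EHR encounter diagnosis"),
    domain_id = c(ifelse(pr$domain == "condition_occurrence", "Condition",
                         "Observation"),
                  "Condition", "Measurement", "Gender", "Gender", "Meas Value",
                  "Type Concept"),
    vocabulary_id = "None", stringsAsFactors = FALSE))
  DBI::dbWriteTable(con, "concept", concept)
  invisible(destination)
}

#' Partition a CDM database into per-site databases
#'
#' Shuffles the person ids with the given seed and deals them round-robin
#' into \code{n_sites} disjoint groups covering the whole cohort (sizes
#' differ by at most one). Each site database receives the person rows and
#' every event row belonging to its persons; the concept vocabulary is
#' replicated to every site.
#'
#' @param db_path Source SQLite database.
#' @param n_sites Number of sites (at most the number of persons).
#' @param seed Shuffle seed.
#' @param out_dir Directory for the site databases (defaults to the source's
#'   directory).
#' @return Character vector of site database paths.
#' @export
partition_sites <- function(db_path, n_sites, seed = 1L,
                            out_dir = dirname(db_path)) {
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con))
  persons <- DBI::dbGetQuery(con, "SELECT person_id FROM person")$person_id
  if (n_sites > length(persons))
    stop("n_sites exceeds the number of persons", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(persons)
  assignment <- rep(seq_len(n_sites), length.out = length(shuffled))
  schema <- introspect_schema(con)
  stem <- sub("\\.[^.]*$", "", basename(db_path))
  paths <- file.path(out_dir, sprintf("%s_site%d.sqlite", stem,
                                      seq_len(n_sites)))
  for (s in seq_len(n_sites)) {
    ids <- sort(shuffled[assignment == s])
    if (file.exists(paths[s])) file.remove(paths[s])
    scon <- DBI::dbConnect(RSQLite::SQLite(), paths[s])
    for (td in schema$tables) {
      pcol <- person_column_of(td)
      if (td$name == "concept" || is.null(pcol)) {
        full <- DBI::dbReadTable(con, td$name)
        DBI::dbWriteTable(scon, td$name, full)
      } else {
        rec <- fetch_filtered(con, td, query_filter(person_ids = ids))
        DBI::dbWriteTable(scon, td$name, as.data.frame(rec))
      }
    }
    DBI::dbDisconnect(scon)
  }
  paths
}
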