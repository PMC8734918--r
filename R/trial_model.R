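# Domain model for a multisite trial: table schemas, constructors with
# invariant checking, and CSV readers/writers for the interchange format
# shared by the analytics, randomization, reporting and data-quality layers.
#
# Conventions: all dates are ISO-8601 (YYYY-MM-DD) with daily granularity;
# CSV is comma-separated, double-quote quoted, UTF-8, header required; absent
# values are empty strings (the literal string "NA" is data, not missingness,
# and is flagged downstream by the data-quality checks).

PARTICIPANT_STATUSES <- c("screened", "enrolled", "on_treatment", "completed",
                          "withdrawn", "lost_to_followup")
ENROLLED_STATUSES <- setdiff(PARTICIPANT_STATUSES, "screened")
AE_ATTRIBUTIONS <- c("unrelated", "possibly", "probably", "definitely", "unassessed")
FIELD_KINDS <- c("categorical", "numeric", "date", "text")

# column name -> storage type, in the documented on-disk column order.
# "verbatim" columns round-trip exactly (no empty-string -> NA coercion).
trial_table_schemas <- function() {
  list(
    sites = c(site_id = "character", name = "character",
              activation_date = "date",
              target_weekly_accrual_low = "numeric",
              target_weekly_accrual_high = "numeric"),
    participants = c(participant_id = "character", site_id = "character",
                     screening_date = "date", consent_date = "date",
                     enrollment_date = "date",
                     gestational_age_weeks_at_enrollment = "numeric",
                     strata = "character", arm = "character",
                     status = "character",
                     estimated_delivery_date = "date",
                     actual_delivery_date = "date",
                     signoff_done = "logical"),
    enrollment = c(participant_id = "character", site_id = "character",
                   date = "date"),
    randomization_table = c(site_id = "character", stratum_key = "character",
                            sequence_no = "integer", arm = "character",
                            schedule_version = "integer",
                            assigned_to = "character"),
    dispenses = c(participant_id = "character", dispense_date = "date",
                  days_supplied = "integer"),
    adverse_events = c(ae_id = "character", participant_id = "character",
                       onset_date = "date", description = "character",
                       serious = "logical", reviewed = "logical",
                       attribution = "character"),
    deviations = c(deviation_id = "character", participant_id = "character",
                   date = "date", description = "character"),
    field_definitions = c(form_name = "character", field_name = "character",
                          value_kind = "character", required = "logical",
                          allowed_categories = "character",
                          numeric_min = "numeric", numeric_max = "numeric",
                          logic_rules = "character"),
    form_records = c(participant_id = "character", form_name = "character",
                     field_name = "character", value = "verbatim")
  )
}

trial_table_names <- function() names(trial_table_schemas())

empty_trial_table <- function(table) {
  schema <- trial_table_schemas()[[table]]
  cols <- lapply(schema, function(type) {
    switch(type,
           character = character(0), verbatim = character(0),
           date = as.Date(character(0)),
           numeric = numeric(0), integer = integer(0), logical = logical(0))
  })
  as.data.frame(cols, stringsAsFactors = FALSE)
}

coerce_trial_table <- function(df, table) {
  schema <- trial_table_schemas()[[table]]
  missing_cols <- setdiff(names(schema), names(df))
  if (length(missing_cols) > 0)
    abort_format(sprintf("table '%s' is missing column(s): %s",
                         table, paste(missing_cols, collapse = ", ")))
  df <- df[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    x <- df[[col]]
    df[[col]] <- switch(type,
      character = as.character(x),
      verbatim  = as.character(x),
      date      = as.Date(x),
      numeric   = as.numeric(x),
      integer   = as.integer(x),
      logical   = as.logical(x))
  }
  rownames(df) <- NULL
  df
}

#' Assemble a trial dataset from its component tables
#'
#' Bundles the nine operational tables of a multisite trial (sites,
#' participants, enrollment events, randomization table, medication
#' dispenses, adverse events, protocol deviations, eCRF field definitions
#' and form records) into a single validated object. Any table omitted is
#' created empty. All type and referential invariants are enforced; a
#' violation raises a classed integrity/format error naming the table and
#' row.
#'
#' @param sites,participants,enrollment,randomization_table,dispenses,adverse_events,deviations,field_definitions,form_records
#'   data frames following the documented column schemas (see
#'   [read_trial_tables()] for the on-disk layout).
#' @param validate logical; skip invariant checking when `FALSE` (internal
#'   use while building datasets incrementally).
#' @return an object of class `trial_dataset`: a named list of the nine
#'   typed data frames.
#' @seealso [read_trial_tables()], [write_trial_tables()], [simulate_trial()]
#' @export
trial_dataset <- function(sites = NULL, participants = NULL, enrollment = NULL,
                          randomization_table = NULL, dispenses = NULL,
                          adverse_events = NULL, deviations = NULL,
                          field_definitions = NULL, form_records = NULL,
                          validate = TRUE) {
  supplied <- list(sites = sites, participants = participants,
                   enrollment = enrollment,
                   randomization_table = randomization_table,
                   dispenses = dispenses, adverse_events = adverse_events,
                   deviations = deviations,
                   field_definitions = field_definitions,
                   form_records = form_records)
  tables <- lapply(trial_table_names(), function(tb) {
    df <- supplied[[tb]]
    if (is.null(df)) empty_trial_table(tb) else coerce_trial_table(df, tb)
  })
  names(tables) <- trial_table_names()
  out <- structure(tables, class = "trial_dataset")
  if (validate) validate_trial_dataset(out)
  out
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>\n")
  for (tb in names(x))
    cat(sprintf("  %-20s %5d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

fail_rows <- function(table, rows, what) {
  abort_integrity(sprintf("table '%s': %s (row%s %s)",
                          table, what, if (length(rows) > 1) "s" else "",
                          paste(rows, collapse = ", ")))
}

#' Validate every invariant of a trial dataset
#'
#' Checks key uniqueness, referential links (participant to site, dispense /
#' adverse event / deviation to participant, enrollment to both), date
#' orderings (screening <= consent <= enrollment; enrollment not before site
#' activation; dispense not before enrollment), enum membership, and the
#' status-dependent presence rules for treatment arm and actual delivery
#' date. Violations raise an integrity error naming the table and offending
#' rows.
#'
#' @param ds a `trial_dataset`
#' @return `ds`, invisibly, when valid.
#' @export
validate_trial_dataset <- function(ds) {
  s <- ds$sites; p <- ds$participants
  if (anyDuplicated(s$site_id))
    fail_rows("sites", which(duplicated(s$site_id)), "duplicate site_id")
  if (any(bad <- is.na(s$site_id) | s$site_id == ""))
    fail_rows("sites", which(bad), "empty site_id")
  if (any(bad <- is.na(s$activation_date)))
    fail_rows("sites", which(bad), "missing activation_date")
  if (any(bad <- !is.na(s$target_weekly_accrual_low) &
            (s$target_weekly_accrual_low < 0 |
             s$target_weekly_accrual_low > s$target_weekly_accrual_high)))
    fail_rows("sites", which(bad), "weekly accrual targets must satisfy 0 <= low <= high")

  if (anyDuplicated(p$participant_id))
    fail_rows("participants", which(duplicated(p$participant_id)),
              "duplicate participant_id")
  if (any(bad <- !p$site_id %in% s$site_id))
    fail_rows("participants", which(bad), "site_id not present in sites")
  if (any(bad <- !is.na(p$status) & !p$status %in% PARTICIPANT_STATUSES))
    fail_rows("participants", which(bad),
              sprintf("status outside {%s}", paste(PARTICIPANT_STATUSES, collapse = ", ")))
  bad <- (!is.na(p$screening_date) & !is.na(p$consent_date) &
            p$screening_date > p$consent_date) |
         (!is.na(p$consent_date) & !is.na(p$enrollment_date) &
            p$consent_date > p$enrollment_date)
  if (any(bad))
    fail_rows("participants", which(bad),
              "dates must satisfy screening <= consent <= enrollment")
  if (any(bad <- !is.na(p$gestational_age_weeks_at_enrollment) &
            p$gestational_age_weeks_at_enrollment < 0))
    fail_rows("participants", which(bad), "negative gestational age")
  arm_expected <- p$status %in% ENROLLED_STATUSES
  if (any(bad <- arm_expected & (is.na(p$arm) | p$arm == "")))
    fail_rows("participants", which(bad), "enrolled participant without arm")
  if (any(bad <- !arm_expected & !is.na(p$arm) & p$arm != ""))
    fail_rows("participants", which(bad), "arm present before enrollment")
  delivery_ok <- p$status %in% c("on_treatment", "completed", "withdrawn",
                                 "lost_to_followup")
  if (any(bad <- !delivery_ok & !is.na(p$actual_delivery_date)))
    fail_rows("participants", which(bad),
              "actual_delivery_date present for a non-enrolled status")

  e <- ds$enrollment
  if (anyDuplicated(e$participant_id))
    fail_rows("enrollment", which(duplicated(e$participant_id)),
              "more than one enrollment event per participant")
  if (any(bad <- !e$participant_id %in% p$participant_id))
    fail_rows("enrollment", which(bad), "participant_id not present in participants")
  if (any(bad <- !e$site_id %in% s$site_id))
    fail_rows("enrollment", which(bad), "site_id not present in sites")
  act <- s$activation_date[match(e$site_id, s$site_id)]
  if (any(bad <- !is.na(e$date) & !is.na(act) & e$date < act))
    fail_rows("enrollment", which(bad), "enrollment precedes site activation")

  d <- ds$dispenses
  if (any(bad <- !d$participant_id %in% p$participant_id))
    fail_rows("dispenses", which(bad), "participant_id not present in participants")
  if (any(bad <- is.na(d$days_supplied) | d$days_supplied < 1))
    fail_rows("dispenses", which(bad), "days_supplied must be >= 1")
  enr <- p$enrollment_date[match(d$participant_id, p$participant_id)]
  if (any(bad <- !is.na(enr) & d$dispense_date < enr))
    fail_rows("dispenses", which(bad), "dispense precedes enrollment")

  a <- ds$adverse_events
  if (anyDuplicated(a$ae_id))
    fail_rows("adverse_events", which(duplicated(a$ae_id)), "duplicate ae_id")
  if (any(bad <- !a$participant_id %in% p$participant_id))
    fail_rows("adverse_events", which(bad), "participant_id not present in participants")
  if (any(bad <- !is.na(a$attribution) & !a$attribution %in% AE_ATTRIBUTIONS))
    fail_rows("adverse_events", which(bad), "unknown attribution")
  if (any(bad <- a$attribution == "unassessed" & a$reviewed))
    fail_rows("adverse_events", which(bad),
              "reviewed adverse event cannot have attribution 'unassessed'")

  dv <- ds$deviations
  if (anyDuplicated(dv$deviation_id))
    fail_rows("deviations", which(duplicated(dv$deviation_id)), "duplicate deviation_id")
  if (any(bad <- !dv$participant_id %in% p$participant_id))
    fail_rows("deviations", which(bad), "participant_id not present in participants")

  fd <- ds$field_definitions
  if (any(bad <- !fd$value_kind %in% FIELD_KINDS))
    fail_rows("field_definitions", which(bad), "unknown value_kind")
  if (any(bad <- fd$value_kind == "categorical" &
            (is.na(fd$allowed_categories) | fd$allowed_categories == "")))
    fail_rows("field_definitions", which(bad),
              "categorical field without allowed_categories")
  if (any(bad <- !is.na(fd$numeric_min) & !is.na(fd$numeric_max) &
            fd$numeric_min > fd$numeric_max))
    fail_rows("field_definitions", which(bad), "numeric_min exceeds numeric_max")
  if (anyDuplicated(fd[c("form_name", "field_name")]))
    fail_rows("field_definitions",
              which(duplicated(fd[c("form_name", "field_name")])),
              "duplicate (form_name, field_name)")

  validate_randomization_entries(ds$randomization_table)

  invisible(ds)
}

trial_table_paths <- function(dir) {
  stats::setNames(file.path(dir, paste0(trial_table_names(), ".csv")),
                  trial_table_names())
}

read_one_table <- function(path, table) {
  if (!file.exists(path))
    abort_io(sprintf("file for table '%s' not found: %s", table, path))
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = FALSE,
                         fileEncoding = "UTF-8")
  schema <- trial_table_schemas()[[table]]
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0)
    abort_format(sprintf("table '%s': missing column(s) %s",
                         table, paste(missing_cols, collapse = ", ")))
  raw <- raw[names(schema)]
  out <- raw
  for (col in names(schema)) {
    x <- raw[[col]]
    type <- schema[[col]]
    if (type != "verbatim") x[x == ""] <- NA_character_
    out[[col]] <- switch(type,
      character = x,
      verbatim  = x,
      date = {
        d <- parse_iso_date(x)
        bad <- !is.na(x) & is.na(d)
        if (any(bad))
          abort_format(sprintf(
            "table '%s', column '%s': unparseable date '%s' at row %d",
            table, col, x[which(bad)[1]], which(bad)[1]))
        d
      },
      numeric = {
        v <- suppressWarnings(as.numeric(x))
        bad <- !is.na(x) & is.na(v)
        if (any(bad))
          abort_format(sprintf(
            "table '%s', column '%s': non-numeric value '%s' at row %d",
            table, col, x[which(bad)[1]], which(bad)[1]))
        v
      },
      integer = {
        v <- suppressWarnings(as.integer(x))
        bad <- !is.na(x) & is.na(v)
        if (any(bad))
          abort_format(sprintf(
            "table '%s', column '%s': non-integer value '%s' at row %d",
            table, col, x[which(bad)[1]], which(bad)[1]))
        v
      },
      logical = {
        v <- rep(NA, length(x))
        v[x %in% c("TRUE", "true")] <- TRUE
        v[x %in% c("FALSE", "false")] <- FALSE
        bad <- !is.na(x) & is.na(v)
        if (any(bad))
          abort_format(sprintf(
            "table '%s', column '%s': non-logical value '%s' at row %d",
            table, col, x[which(bad)[1]], which(bad)[1]))
        v
      })
  }
  rownames(out) <- NULL
  out
}

#' Read a full trial dataset from CSV tables
#'
#' Loads the nine interchange tables, parses every column to its documented
#' type (ISO-8601 dates, numerics, logicals), and cross-validates all
#' referential links and type invariants via [validate_trial_dataset()].
#'
#' @param paths either a directory containing `sites.csv`,
#'   `participants.csv`, `enrollment.csv`, `randomization_table.csv`,
#'   `dispenses.csv`, `adverse_events.csv`, `deviations.csv`,
#'   `field_definitions.csv` and `form_records.csv`, or a named character
#'   vector/list mapping table names to file paths.
#' @return a validated `trial_dataset`.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_trial_tables(trial_dataset(), dir)
#' ds <- read_trial_tables(dir)
#' @export
read_trial_tables <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && is.null(names(paths))) {
    if (!dir.exists(paths))
      abort_io(sprintf("data directory not found: %s", paths))
    paths <- trial_table_paths(paths)
  }
  paths <- as.list(paths)
  missing_tables <- setdiff(trial_table_names(), names(paths))
  if (length(missing_tables) > 0)
    abort_io(sprintf("no path given for table(s): %s",
                     paste(missing_tables, collapse = ", ")))
  tables <- lapply(trial_table_names(),
                   function(tb) read_one_table(paths[[tb]], tb))
  names(tables) <- trial_table_names()
  do.call(trial_dataset, c(tables, list(validate = TRUE)))
}

format_csv_column <- function(x, type) {
  out <- switch(type,
    date = format(x, "%Y-%m-%d"),
    logical = ifelse(x, "TRUE", "FALSE"),
    numeric = as.character(x),
    integer = as.character(x),
    character = x,
    verbatim = x)
  out[is.na(out)] <- ""
  out
}

#' Write a trial dataset to CSV tables
#'
#' Writes one CSV per table with the fixed documented column order, ISO-8601
#' dates, UTF-8 encoding and empty strings for absent values. Writing a
#' dataset and reading it back yields an identical dataset, and a
#' write-read-write cycle is byte-identical.
#'
#' @param ds a validated `trial_dataset`
#' @param out_dir output directory (created if needed)
#' @return invisibly, the named vector of files written.
#' @export
write_trial_tables <- function(ds, out_dir) {
  validate_trial_dataset(ds)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create output directory: %s", out_dir))
  paths <- trial_table_paths(out_dir)
  schemas <- trial_table_schemas()
  for (tb in trial_table_names()) {
    schema <- schemas[[tb]]
    df <- ds[[tb]]
    out <- df
    for (col in names(schema))
      out[[col]] <- format_csv_column(df[[col]], schema[[col]])
    con <- file(paths[[tb]], open = "w", encoding = "UTF-8")
    utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
    close(con)
  }
  invisible(paths)
}

#' Compare two trial datasets table by table
#'
#' @param a,b `trial_dataset` objects
#' @return `TRUE` when every table is identical (same rows, values and
#'   types), else `FALSE`.
#' @export
trial_datasets_equal <- function(a, b) {
  all(vapply(trial_table_names(), function(tb) {
    x <- a[[tb]]; y <- b[[tb]]
    rownames(x) <- NULL; rownames(y) <- NULL
    isTRUE(all.equal(x, y, check.attributes = FALSE))
  }, logical(1)))
}
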