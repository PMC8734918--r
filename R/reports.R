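# Scheduled operational report suite. Each report is a report_document: a
# kind, an as-of date, a recipients hint, and named sections that are plain
# data frames — renderable to Markdown and JSON, both byte-deterministic
# given the same dataset and date. Treatment-arm labels never appear for
# participants who have not completed the study (blinding hygiene); in fact
# no report in this suite prints arm labels at all.

REPORT_KINDS <- c("accrual", "resupply", "delivery_watchlist",
                  "adverse_events", "pi_signoff", "data_query")
REPORT_CADENCES <- c("weekly", "twice_weekly", "twice_monthly",
                     "immediate_on_event")

report_document <- function(report_kind, as_of, sections, recipients_hint) {
  if (!report_kind %in% REPORT_KINDS)
    abort_domain(sprintf("unknown report kind '%s'", report_kind))
  stopifnot(is.list(sections), !is.null(names(sections)))
  structure(list(report_kind = report_kind, as_of = as.Date(as_of),
                 sections = sections, recipients_hint = recipients_hint),
            class = "report_document")
}

#' @export
print.report_document <- function(x, ...) {
  cat(render_report_md(x))
  invisible(x)
}

#' Default report schedule
#'
#' The standing cadence of each report kind: accrual, data query, resupply
#' and delivery watch list weekly; adverse events twice weekly plus
#' immediately when a serious event arrives; principal-investigator
#' sign-off twice monthly.
#'
#' @return data frame with columns `report_kind`, `cadence`,
#'   `immediate_on_serious_ae`.
#' @export
default_report_schedule <- function() {
  data.frame(
    report_kind = c("accrual", "data_query", "resupply",
                    "delivery_watchlist", "adverse_events", "pi_signoff"),
    cadence = c("weekly", "weekly", "weekly", "weekly", "twice_weekly",
                "twice_monthly"),
    immediate_on_serious_ae = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Which reports are due on a date?
#'
#' Weekly reports fall on a configured weekday (default Monday),
#' twice-weekly on Monday and Thursday, twice-monthly on the 1st and 15th;
#' kinds flagged immediate-on-serious-AE are additionally due whenever a new
#' serious adverse event has arrived.
#'
#' @param schedule schedule data frame, default [default_report_schedule()].
#' @param on_date calendar date.
#' @param new_serious_ae has a new serious adverse event arrived?
#' @param weekly_weekday ISO weekday number for weekly reports (1 = Monday).
#' @return character vector of due report kinds, in schedule order.
#' @export
reports_due <- function(schedule = default_report_schedule(), on_date,
                        new_serious_ae = FALSE, weekly_weekday = 1L) {
  on_date <- as.Date(on_date)
  wday <- as.integer(format(on_date, "%u"))
  mday <- as.integer(format(on_date, "%d"))
  due <- vapply(seq_len(nrow(schedule)), function(i) {
    by_cadence <- switch(schedule$cadence[i],
      weekly = wday == weekly_weekday,
      twice_weekly = wday %in% c(1L, 4L),
      twice_monthly = mday %in% c(1L, 15L),
      immediate_on_event = FALSE)
    by_cadence || (isTRUE(schedule$immediate_on_serious_ae[i]) && new_serious_ae)
  }, logical(1))
  schedule$report_kind[due]
}

site_count_rows <- function(counts) {
  if (length(counts) == 0)
    return(data.frame(site_id = character(0), n = integer(0)))
  data.frame(site_id = names(counts), n = as.integer(counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weekly accrual and delivery report
#'
#' The flagship weekly report: (1) an enrollment and delivery summary
#' including the posterior-predictive completion forecast with its 95%
#' prediction interval; (2) participant status counts (on treatment,
#' completed, discontinued); (3) accrual by site for the current month, the
#' last 30 days, and the whole study; (4) births in the last 30 days by
#' site and total deliveries by site.
#'
#' @param ds a `trial_dataset`.
#' @param as_of reporting date.
#' @param target_n total enrollment target.
#' @param prediction optional `accrual_prediction` computed at the same
#'   `as_of` (a mismatch is an error); when `NULL` (e.g. before any
#'   enrollment) the forecast row is flagged "insufficient data".
#' @return a `report_document` for all team members.
#' @export
accrual_report <- function(ds, as_of, target_n, prediction = NULL) {
  as_of <- as.Date(as_of)
  if (!is.null(prediction) && prediction$as_of != as_of)
    abort_precondition("prediction was computed at a different as_of date")
  p <- ds$participants
  # snapshot semantics: the report describes the trial as of `as_of`
  ev <- ds$enrollment[ds$enrollment$date <= as_of, , drop = FALSE]
  windows <- accrual_by_window(ev, as_of)
  delivered <- !is.na(p$actual_delivery_date) & p$actual_delivery_date <= as_of

  summary_df <- data.frame(
    measure = c("enrolled", "target_n", "total_deliveries",
                "predicted_completion", "pi_low_95", "pi_high_95"),
    value = c(nrow(ev), target_n, sum(delivered),
              if (is.null(prediction)) rep("insufficient data", 3)
              else format(c(prediction$predicted_completion,
                            prediction$pi_low, prediction$pi_high))),
    stringsAsFactors = FALSE)

  status_df <- data.frame(
    status = c("on_treatment", "completed", "discontinued"),
    n = c(sum(p$status == "on_treatment"), sum(p$status == "completed"),
          sum(p$status %in% c("withdrawn", "lost_to_followup"))))

  accrual_df <- do.call(rbind, lapply(
    c("current_month", "last_30_days", "total"), function(w) {
      rows <- site_count_rows(windows[[w]])
      if (nrow(rows) == 0) return(NULL)
      cbind(window = w, rows, stringsAsFactors = FALSE)
    }))
  if (is.null(accrual_df))
    accrual_df <- data.frame(window = character(0), site_id = character(0),
                             n = integer(0))

  recent_births <- delivered & p$actual_delivery_date >= as_of - 29L
  measure_rows <- function(measure, x) {
    tab <- table(x)
    df <- site_count_rows(tab[tab > 0])
    cbind(measure = rep(measure, nrow(df)), df, stringsAsFactors = FALSE)
  }
  births_df <- rbind(measure_rows("births_last_30_days", p$site_id[recent_births]),
                     measure_rows("total_deliveries", p$site_id[delivered]))

  report_document("accrual", as_of,
                  list(summary = summary_df, participant_status = status_df,
                       accrual_by_site = accrual_df, deliveries = births_df),
                  recipients_hint = "all_team")
}

#' Pharmacy resupply report
#'
#' For each actively treated participant (status enrolled or on_treatment)
#' the latest dispense defines the run-out date (`dispense_date +
#' days_supplied`) and a flag date `lead_days` (default 14, the two-week
#' rule) before run-out. Participants whose flag date has arrived
#' (`as_of >= flag_date`) are listed, sorted by run-out date; actively
#' treated participants with no dispense on file are listed first with a
#' "never dispensed" note.
#'
#' @param ds a `trial_dataset`.
#' @param as_of reporting date.
#' @param lead_days days of lead time before run-out (>= 0).
#' @return a `report_document` for coordinators and pharmacists.
#' @export
resupply_report <- function(ds, as_of, lead_days = 14L) {
  as_of <- as.Date(as_of)
  if (lead_days < 0) abort_precondition("lead_days must be >= 0")
  p <- ds$participants
  active <- p[p$status %in% c("enrolled", "on_treatment"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(active)), function(i) {
    pid <- active$participant_id[i]
    disp <- ds$dispenses[ds$dispenses$participant_id == pid, , drop = FALSE]
    disp <- disp[disp$dispense_date <= as_of, , drop = FALSE]
    if (nrow(disp) == 0)
      return(data.frame(participant_id = pid, site_id = active$site_id[i],
                        last_refill_date = as.Date(NA),
                        runout_date = as.Date(NA), flag_date = as.Date(NA),
                        note = "never dispensed", stringsAsFactors = FALSE))
    last <- disp[which.max(disp$dispense_date), ]
    runout <- last$dispense_date + last$days_supplied
    flag <- runout - lead_days
    if (as_of < flag) return(NULL)
    data.frame(participant_id = pid, site_id = active$site_id[i],
               last_refill_date = last$dispense_date, runout_date = runout,
               flag_date = flag,
               note = if (runout <= as_of) "already run out" else "",
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(participant_id = character(0), site_id = character(0),
                       last_refill_date = as.Date(character(0)),
                       runout_date = as.Date(character(0)),
                       flag_date = as.Date(character(0)),
                       note = character(0))
  rows <- rows[order(!is.na(rows$runout_date), rows$runout_date,
                     rows$participant_id), , drop = FALSE]
  rownames(rows) <- NULL
  report_document("resupply", as_of, list(upcoming_refills = rows),
                  recipients_hint = "coordinators_pharmacists")
}

#' Delivery watch list
#'
#' Participants without a recorded delivery whose estimated delivery date
#' falls within the look-ahead horizon (`[as_of, as_of + horizon_days]`,
#' default 60 days), grouped by site and sorted by estimated delivery date,
#' so site teams can watch the delivery service for sample collection.
#' Undelivered enrolled participants with no estimated delivery date on
#' file are listed in an exceptions section.
#'
#' @param ds a `trial_dataset`.
#' @param as_of reporting date.
#' @param horizon_days look-ahead horizon in days (> 0).
#' @return a `report_document` for site teams.
#' @export
delivery_watchlist <- function(ds, as_of, horizon_days = 60L) {
  as_of <- as.Date(as_of)
  if (horizon_days <= 0) abort_precondition("horizon_days must be > 0")
  p <- ds$participants
  undelivered <- is.na(p$actual_delivery_date)
  due <- undelivered & !is.na(p$estimated_delivery_date) &
    p$estimated_delivery_date >= as_of &
    p$estimated_delivery_date <= as_of + horizon_days
  watch <- p[due, c("participant_id", "site_id", "estimated_delivery_date")]
  watch <- watch[order(watch$site_id, watch$estimated_delivery_date,
                       watch$participant_id), , drop = FALSE]
  rownames(watch) <- NULL
  missing_edd <- p$status %in% ENROLLED_STATUSES & undelivered &
    is.na(p$estimated_delivery_date)
  exceptions <- p[missing_edd, c("participant_id", "site_id")]
  rownames(exceptions) <- NULL
  report_document("delivery_watchlist", as_of,
                  list(due_to_deliver = watch,
                       missing_estimated_delivery_date = exceptions),
                  recipients_hint = "site_teams")
}

#' Adverse-event report
#'
#' Adverse events with onset in `(since, as_of]` plus any event still
#' awaiting review, for principal investigators to determine attribution
#' and relatedness. Serious events are listed first and flagged. Arm labels
#' are never shown.
#'
#' @param ds a `trial_dataset`.
#' @param since exclusive start of the reporting window (<= `as_of`).
#' @param as_of inclusive end of the reporting window.
#' @return a `report_document` for principal investigators.
#' @export
ae_report <- function(ds, since, as_of) {
  since <- as.Date(since); as_of <- as.Date(as_of)
  if (since > as_of) abort_precondition("since must not exceed as_of")
  a <- ds$adverse_events
  keep <- (a$onset_date > since & a$onset_date <= as_of) | !a$reviewed
  rows <- a[keep, c("ae_id", "participant_id", "onset_date", "description",
                    "serious", "reviewed", "attribution")]
  rows <- rows[order(!rows$serious, rows$onset_date, rows$ae_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  report_document("adverse_events", as_of, list(adverse_events = rows),
                  recipients_hint = "principal_investigators")
}

#' Principal-investigator sign-off report
#'
#' Participants who completed the study but whose records have not yet been
#' signed off by a principal investigator, grouped by site.
#'
#' @param ds a `trial_dataset`.
#' @param as_of reporting date.
#' @return a `report_document` for principal investigators.
#' @export
pi_signoff_report <- function(ds, as_of) {
  p <- ds$participants
  pending <- p$status == "completed" & !p$signoff_done
  rows <- p[pending, c("participant_id", "site_id", "actual_delivery_date")]
  rows <- rows[order(rows$site_id, rows$participant_id), , drop = FALSE]
  rownames(rows) <- NULL
  report_document("pi_signoff", as.Date(as_of),
                  list(awaiting_signoff = rows),
                  recipients_hint = "principal_investigators")
}

#' Weekly data-query report
#'
#' All unresolved data queries (open or sent), grouped by site so each
#' site's team sees its own outstanding discrepancies.
#'
#' @param ds a `trial_dataset` (used to map participants to sites).
#' @param queries query data frame from [run_checks()] /
#'   [batch_send_queries()].
#' @param as_of reporting date.
#' @return a `report_document` for site teams.
#' @export
data_query_report <- function(ds, queries, as_of) {
  unresolved <- queries[queries$status != "resolved", , drop = FALSE]
  site <- ds$participants$site_id[match(unresolved$participant_id,
                                        ds$participants$participant_id)]
  rows <- cbind(site_id = site,
                unresolved[c("query_id", "participant_id", "form_name",
                             "field_name", "rule", "detail", "status",
                             "opened_on")])
  rows <- rows[order(rows$site_id, rows$participant_id, rows$query_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  report_document("data_query", as.Date(as_of),
                  list(outstanding_queries = rows),
                  recipients_hint = "site_teams")
}

md_table <- function(df) {
  if (nrow(df) == 0)
    return(paste0("(no rows)\n"))
  cells <- as.data.frame(lapply(df, function(col) {
    if (inherits(col, "Date")) col <- format(col, "%Y-%m-%d")
    col <- as.character(col)
    col[is.na(col)] <- ""
    col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste0(paste(c(header, rule, body), collapse = "\n"), "\n")
}

#' Render a report document as Markdown
#'
#' @param doc a `report_document`.
#' @return a single Markdown string (deterministic for a given document).
#' @export
render_report_md <- function(doc) {
  parts <- c(sprintf("# %s report — as of %s\n", gsub("_", " ", doc$report_kind),
                     format(doc$as_of)),
             sprintf("recipients: %s\n", doc$recipients_hint))
  for (nm in names(doc$sections))
    parts <- c(parts, sprintf("\n## %s\n\n", gsub("_", " ", nm)),
               md_table(doc$sections[[nm]]))
  paste(parts, collapse = "")
}

report_to_list <- function(doc) {
  sections <- lapply(doc$sections, function(df) {
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    df
  })
  list(report_kind = doc$report_kind, as_of = format(doc$as_of, "%Y-%m-%d"),
       recipients_hint = doc$recipients_hint, sections = sections)
}

#' Write a report document to disk
#'
#' Writes `<kind>_<as_of>.json` (machine-readable) and `<kind>_<as_of>.md`
#' (human-readable) into `out_dir`. Output is byte-identical across runs
#' for the same document.
#'
#' @param doc a `report_document`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_report <- function(doc, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    abort_io(sprintf("cannot create output directory: %s", out_dir))
  stem <- file.path(out_dir, sprintf("%s_%s", doc$report_kind,
                                     format(doc$as_of, "%Y-%m-%d")))
  json_path <- paste0(stem, ".json"); md_path <- paste0(stem, ".md")
  jsonlite::write_json(report_to_list(doc), json_path, dataframe = "rows",
                       auto_unbox = TRUE, na = "null", digits = NA)
  writeLines(render_report_md(doc), md_path, useBytes = TRUE)
  invisible(c(json = json_path, md = md_path))
}
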