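# Edit/logic/range validation of eCRF form records plus the query
# lifecycle. "Edit checks" cover format and required-field problems,
# "logic checks" are registered cross-field predicates, and "range checks"
# are numeric bounds and category membership. Each violation opens one
# query, which moves open -> sent (weekly batch) -> resolved; a dataset may
# be locked for analysis only once every query is resolved.

QUERY_RULES <- c("missing_required", "out_of_range", "invalid_category",
                 "bad_date", "logic_violation", "format_error")

empty_query_table <- function() {
  data.frame(query_id = character(0), participant_id = character(0),
             form_name = character(0), field_name = character(0),
             rule = character(0), detail = character(0),
             status = character(0),
             opened_on = as.Date(character(0)),
             sent_on = as.Date(character(0)),
             resolved_on = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

#' Built-in cross-field logic rules
#'
#' Logic rules are named predicates over the parsed values of one
#' participant's form; a rule passes when its predicate returns `TRUE`. Each
#' registry entry names the fields it needs, the field a violation is
#' charged to, and a human-readable description. Field definitions reference
#' rules by id in their `logic_rules` column (`|`-separated). The built-in
#' registry ships `enrollment_before_20_weeks`: gestational age at
#' enrollment must be strictly below 20 weeks.
#'
#' @return named list of rule definitions (`fields`, `blame_field`,
#'   `description`, `predicate`).
#' @export
default_logic_rules <- function() {
  list(
    enrollment_before_20_weeks = list(
      fields = "gestational_age_weeks",
      blame_field = "gestational_age_weeks",
      description = "enrollment must occur before 20 weeks gestation",
      predicate = function(values) {
        ga <- values[["gestational_age_weeks"]]
        is.na(ga) || ga < 20
      }
    )
  )
}

parse_field_value <- function(value, kind) {
  v <- trimws(value)
  if (v == "") return(NA)
  switch(kind,
         numeric = suppressWarnings(as.numeric(v)),
         date = if (is_valid_iso_date_string(v)) as.Date(v) else as.Date(NA),
         v)
}

# single-record edit/range checks; returns NULL or list(rule, detail)
check_one_value <- function(value, def) {
  raw <- value
  if (is.na(raw)) raw <- ""
  trimmed <- trimws(raw)
  if (trimmed == "") {
    if (raw != "")
      return(list(rule = "format_error", detail = "whitespace-only value"))
    if (isTRUE(def$required))
      return(list(rule = "missing_required", detail = "required field is empty"))
    return(NULL)
  }
  if (toupper(trimmed) %in% c("NA", "N/A", "NULL", ".")) {
    return(list(rule = "format_error",
                detail = sprintf("placeholder value '%s' entered as data", trimmed)))
  }
  if (def$value_kind == "numeric") {
    num <- suppressWarnings(as.numeric(trimmed))
    if (is.na(num))
      return(list(rule = "format_error",
                  detail = sprintf("'%s' is not numeric", trimmed)))
    if ((!is.na(def$numeric_min) && num < def$numeric_min) ||
        (!is.na(def$numeric_max) && num > def$numeric_max))
      return(list(rule = "out_of_range",
                  detail = sprintf("%s outside [%s, %s]", trimmed,
                                   def$numeric_min, def$numeric_max)))
  } else if (def$value_kind == "categorical") {
    allowed <- strsplit(def$allowed_categories, "|", fixed = TRUE)[[1]]
    if (!trimmed %in% allowed)
      return(list(rule = "invalid_category",
                  detail = sprintf("'%s' not in {%s}", trimmed,
                                   paste(allowed, collapse = ", "))))
  } else if (def$value_kind == "date") {
    if (!is_valid_iso_date_string(trimmed))
      return(list(rule = "bad_date",
                  detail = sprintf("'%s' is not a valid ISO date", trimmed)))
  }
  NULL
}

#' Run edit, logic and range checks over eCRF form records
#'
#' Validates every form record against its field definition and the
#' registered cross-field logic rules, opening one query per violation:
#' required-but-empty values (`missing_required`), numerics outside their
#' bounds (`out_of_range`), categories outside the allowed set
#' (`invalid_category`), unparseable or impossible dates (`bad_date`),
#' failed cross-field predicates (`logic_violation`), and placeholder or
#' malformed entries such as the literal "NA" or whitespace junk
#' (`format_error`). Queries are ordered deterministically by
#' (participant, form, field, rule) and assigned sequential ids.
#'
#' @param records form records data frame (`participant_id`, `form_name`,
#'   `field_name`, `value` as entered).
#' @param defs field definitions data frame (see `field_definitions.csv`
#'   layout); must cover every field present in `records`.
#' @param as_of date recorded as `opened_on` for every query.
#' @param logic_rules rule registry, default [default_logic_rules()].
#' @return a query data frame with the full lifecycle columns, all rows
#'   `status = "open"`.
#' @export
run_checks <- function(records, defs, as_of,
                       logic_rules = default_logic_rules()) {
  as_of <- as.Date(as_of)
  defs_key <- paste(defs$form_name, defs$field_name, sep = "\r")
  rec_key <- paste(records$form_name, records$field_name, sep = "\r")
  unknown <- !rec_key %in% defs_key
  if (any(unknown))
    trialops_error("trialops_definition_error", sprintf(
      "form field(s) with no definition: %s",
      paste(unique(paste0(records$form_name, ".", records$field_name)[unknown]),
            collapse = ", ")))

  hits <- list()
  di <- match(rec_key, defs_key)
  for (i in seq_len(nrow(records))) {
    def <- defs[di[i], ]
    res <- check_one_value(records$value[i], def)
    if (!is.null(res))
      hits[[length(hits) + 1]] <- data.frame(
        participant_id = records$participant_id[i],
        form_name = records$form_name[i],
        field_name = records$field_name[i],
        rule = res$rule, detail = res$detail, stringsAsFactors = FALSE)
  }

  # cross-field logic: evaluate each referenced rule once per participant+form
  refs <- defs[!is.na(defs$logic_rules) & defs$logic_rules != "", , drop = FALSE]
  if (nrow(refs) > 0 && nrow(records) > 0) {
    rule_forms <- unique(do.call(rbind, lapply(seq_len(nrow(refs)), function(i) {
      data.frame(form_name = refs$form_name[i],
                 rule_id = strsplit(refs$logic_rules[i], "|", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)
    })))
    grp <- split(seq_len(nrow(records)),
                 paste(records$participant_id, records$form_name, sep = "\r"))
    for (idx in grp) {
      form <- records$form_name[idx[1]]
      pid <- records$participant_id[idx[1]]
      rules_here <- rule_forms$rule_id[rule_forms$form_name == form]
      if (length(rules_here) == 0) next
      fdefs <- defs[defs$form_name == form, , drop = FALSE]
      values <- stats::setNames(lapply(idx, function(i) {
        kind <- fdefs$value_kind[match(records$field_name[i], fdefs$field_name)]
        parse_field_value(records$value[i], kind)
      }), records$field_name[idx])
      for (rid in rules_here) {
        rule <- logic_rules[[rid]]
        if (is.null(rule))
          abort_config(sprintf("logic rule '%s' is not registered", rid))
        if (!isTRUE(rule$predicate(values)))
          hits[[length(hits) + 1]] <- data.frame(
            participant_id = pid, form_name = form,
            field_name = rule$blame_field, rule = "logic_violation",
            detail = sprintf("rule '%s': %s", rid, rule$description),
            stringsAsFactors = FALSE)
      }
    }
  }

  if (length(hits) == 0) return(empty_query_table())
  found <- do.call(rbind, hits)
  found <- found[order(found$participant_id, found$form_name,
                       found$field_name, found$rule), , drop = FALSE]
  n <- nrow(found)
  out <- data.frame(query_id = seq_ids("Q", n),
                    participant_id = found$participant_id,
                    form_name = found$form_name,
                    field_name = found$field_name,
                    rule = found$rule, detail = found$detail,
                    status = rep("open", n),
                    opened_on = rep(as_of, n),
                    sent_on = as.Date(rep(NA, n)),
                    resolved_on = as.Date(rep(NA, n)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge newly detected violations into an existing query log
#'
#' Re-running [run_checks()] re-detects violations that are still present.
#' Detections matching an *unresolved* existing query on
#' (participant, form, field, rule) are not duplicated; detections matching
#' only resolved queries reopen as new queries. New queries continue the id
#' sequence.
#'
#' @param existing current query data frame.
#' @param detected output of [run_checks()].
#' @return the combined query data frame.
#' @export
reconcile_queries <- function(existing, detected) {
  if (nrow(existing) == 0) return(detected)
  keyof <- function(q) paste(q$participant_id, q$form_name, q$field_name,
                             q$rule, sep = "\r")
  live <- keyof(existing[existing$status != "resolved", , drop = FALSE])
  new <- detected[!keyof(detected) %in% live, , drop = FALSE]
  if (nrow(new) > 0) {
    next_id <- max(as.integer(sub("^Q", "", existing$query_id))) + 1L
    new$query_id <- seq_ids("Q", nrow(new), start = next_id)
  }
  out <- rbind(existing, new)
  rownames(out) <- NULL
  out
}

#' Batch-send all open queries
#'
#' Marks every open query as sent on `on_date` (the weekly query email);
#' already-sent and resolved queries are untouched, so sending twice is the
#' same as sending once.
#'
#' @param queries query data frame.
#' @param on_date send date.
#' @return the updated query data frame.
#' @export
batch_send_queries <- function(queries, on_date) {
  on_date <- as.Date(on_date)
  open <- queries$status == "open"
  queries$status[open] <- "sent"
  queries$sent_on[open] <- on_date
  queries
}

#' Resolve a sent query
#'
#' A query can only be resolved after it has been sent; resolving an open or
#' already-resolved query is a lifecycle error.
#'
#' @param queries query data frame.
#' @param query_id id of the query to resolve.
#' @param on_date resolution date.
#' @return the updated query data frame.
#' @export
resolve_query <- function(queries, query_id, on_date) {
  i <- match(query_id, queries$query_id)
  if (is.na(i)) abort_state(sprintf("no query with id '%s'", query_id))
  if (queries$status[i] != "sent")
    abort_state(sprintf("query %s is '%s'; only sent queries can be resolved",
                        query_id, queries$status[i]))
  queries$status[i] <- "resolved"
  queries$resolved_on[i] <- as.Date(on_date)
  queries
}

#' Is the dataset ready to lock for analysis?
#'
#' Analysis datasets are created only after every query is resolved.
#'
#' @param queries query data frame.
#' @return list with `ready` (logical) and `blockers` (the unresolved
#'   queries, possibly empty).
#' @export
check_lock_ready <- function(queries) {
  blockers <- queries[queries$status != "resolved", , drop = FALSE]
  rownames(blockers) <- NULL
  list(ready = nrow(blockers) == 0, blockers = blockers)
}

#' Trial-quality metrics: protocol deviations and loss to follow-up
#'
#' Computes the two benefit measures tracked for the trial: the protocol
#' deviation rate per enrolled participant (rounded to 4 decimal places) and
#' the percentage lost to follow-up (rounded to the nearest whole percent),
#' with all enrolled participants as the denominator.
#'
#' @param ds a `trial_dataset`.
#' @return a `quality_metrics` list: `n_participants`, `n_deviations`,
#'   `deviation_rate`, `n_lost`, `loss_pct`.
#' @examples
#' # 2 deviations and 68 losses among 1100 enrolled -> 0.0018 and 6%
#' @export
quality_metrics <- function(ds) {
  enrolled <- ds$participants$status %in% ENROLLED_STATUSES
  n <- sum(enrolled)
  if (n == 0) abort_domain("no enrolled participants")
  n_dev <- nrow(ds$deviations)
  n_lost <- sum(ds$participants$status == "lost_to_followup")
  structure(list(n_participants = n, n_deviations = n_dev,
                 deviation_rate = round(n_dev / n, 4),
                 n_lost = n_lost,
                 loss_pct = round_half_up(100 * n_lost / n)),
            class = "quality_metrics")
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat(sprintf("<quality_metrics> %d enrolled; %d deviations (%.4f per participant); %d lost to follow-up (%d%%)\n",
              x$n_participants, x$n_deviations, x$deviation_rate,
              x$n_lost, x$loss_pct))
  invisible(x)
}
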