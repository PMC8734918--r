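# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (loops, direct formulas) and share no code
# with the implementation paths they check.

make_sites <- function(ids = c("A", "B", "C"),
                       activation = as.Date("2021-01-01") + c(0, 30, 60)) {
  data.frame(site_id = ids, name = paste("Site", ids),
             activation_date = activation,
             target_weekly_accrual_low = 2, target_weekly_accrual_high = 3,
             stringsAsFactors = FALSE)
}

# a one-row participant with sensible defaults, overridable field by field
make_participant <- function(participant_id, site_id = "A",
                             enrollment_date = as.Date("2021-02-01"),
                             status = "on_treatment",
                             arm = if (status == "screened") NA_character_ else "active",
                             ga = 12,
                             estimated_delivery_date = enrollment_date + (40 - ga) * 7,
                             actual_delivery_date = as.Date(NA),
                             signoff_done = FALSE,
                             strata = "ga_stratum=lt14w") {
  data.frame(participant_id = participant_id, site_id = site_id,
             screening_date = enrollment_date - 7,
             consent_date = enrollment_date - 3,
             enrollment_date = enrollment_date,
             gestational_age_weeks_at_enrollment = ga,
             strata = strata, arm = arm, status = status,
             estimated_delivery_date = estimated_delivery_date,
             actual_delivery_date = actual_delivery_date,
             signoff_done = signoff_done, stringsAsFactors = FALSE)
}

make_dataset <- function(participants, sites = make_sites(), dispenses = NULL,
                         adverse_events = NULL, deviations = NULL,
                         form_records = NULL, field_definitions = NULL,
                         randomization_table = NULL) {
  enrolled <- participants[participants$status != "screened", , drop = FALSE]
  enrollment <- data.frame(participant_id = enrolled$participant_id,
                           site_id = enrolled$site_id,
                           date = enrolled$enrollment_date,
                           stringsAsFactors = FALSE)
  trial_dataset(sites = sites, participants = participants,
                enrollment = enrollment, dispenses = dispenses,
                adverse_events = adverse_events, deviations = deviations,
                form_records = form_records,
                field_definitions = field_definitions,
                randomization_table = randomization_table)
}

# Gini oracle: rank formula G = 2 * sum(i * x_(i)) / (n * sum(x)) - (n+1)/n,
# algebraically equal to the mean-absolute-difference definition but a
# distinct computation route.
oracle_gini_rank <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

# brute-force window count: literal date filter, one site at a time
bf_window_counts <- function(events, from, to) {
  out <- integer(0)
  for (sid in sort(unique(events$site_id))) {
    k <- 0L
    for (i in seq_len(nrow(events)))
      if (events$site_id[i] == sid && events$date[i] >= from &&
          events$date[i] <= to) k <- k + 1L
    if (k > 0) out[sid] <- k
  }
  out
}

# Brute-force eCRF validator: independent re-statement of the edit/logic/
# range rules as literal per-record loops.
bf_validate <- function(records, defs, logic_rules = default_logic_rules()) {
  hits <- data.frame(participant_id = character(0), form_name = character(0),
                     field_name = character(0), rule = character(0),
                     stringsAsFactors = FALSE)
  add <- function(p, fo, fi, r) rbind(hits, data.frame(
    participant_id = p, form_name = fo, field_name = fi, rule = r,
    stringsAsFactors = FALSE))
  for (i in seq_len(nrow(records))) {
    v <- records$value[i]
    if (is.na(v)) v <- ""
    d <- defs[defs$form_name == records$form_name[i] &
                defs$field_name == records$field_name[i], ]
    t <- trimws(v)
    rule <- NULL
    if (t == "") {
      if (v != "") rule <- "format_error"
      else if (d$required) rule <- "missing_required"
    } else if (toupper(t) %in% c("NA", "N/A", "NULL", ".")) {
      rule <- "format_error"
    } else if (d$value_kind == "numeric") {
      num <- suppressWarnings(as.numeric(t))
      if (is.na(num)) rule <- "format_error"
      else if ((!is.na(d$numeric_min) && num < d$numeric_min) ||
               (!is.na(d$numeric_max) && num > d$numeric_max))
        rule <- "out_of_range"
    } else if (d$value_kind == "categorical") {
      if (!t %in% strsplit(d$allowed_categories, "|", fixed = TRUE)[[1]])
        rule <- "invalid_category"
    } else if (d$value_kind == "date") {
      if (!grepl("^\\d{4}-\\d{2}-\\d{2}$", t) ||
          is.na(as.Date(t, format = "%Y-%m-%d")))
        rule <- "bad_date"
    }
    if (!is.null(rule))
      hits <- add(records$participant_id[i], records$form_name[i],
                  records$field_name[i], rule)
  }
  # cross-field logic, evaluated per participant+form
  for (j in seq_len(nrow(defs))) {
    if (is.na(defs$logic_rules[j]) || defs$logic_rules[j] == "") next
    for (rid in strsplit(defs$logic_rules[j], "|", fixed = TRUE)[[1]]) {
      rule <- logic_rules[[rid]]
      for (pid in unique(records$participant_id[
          records$form_name == defs$form_name[j]])) {
        vals <- list()
        sel <- records$participant_id == pid &
          records$form_name == defs$form_name[j]
        for (i in which(sel)) {
          fd <- defs[defs$form_name == records$form_name[i] &
                       defs$field_name == records$field_name[i], ]
          t <- trimws(ifelse(is.na(records$value[i]), "", records$value[i]))
          vals[[records$field_name[i]]] <-
            if (t == "") NA
            else if (fd$value_kind == "numeric") suppressWarnings(as.numeric(t))
            else if (fd$value_kind == "date") {
              if (grepl("^\\d{4}-\\d{2}-\\d{2}$", t))
                as.Date(t, format = "%Y-%m-%d") else as.Date(NA)
            } else t
        }
        if (!isTRUE(rule$predicate(vals)))
          hits <- add(pid, defs$form_name[j], rule$blame_field,
                      "logic_violation")
      }
    }
  }
  hits <- hits[order(hits$participant_id, hits$form_name, hits$field_name,
                     hits$rule), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Randomization replay oracle: naive sequential consumer over plain data
# frames. The script interleaves enroll and append actions; enrollments
# always consume from the site's newest schedule version (anything older
# and unconsumed is superseded), lowest sequence number first.
oracle_replay <- function(entries, script) {
  entries$assigned_to <- NA_character_
  arms <- character(0)
  for (act in script) {
    if (identical(act$type, "append")) {
      entries <- rbind(entries, act$entries)
      next
    }
    maxv <- max(entries$schedule_version[entries$site_id == act$site_id])
    cand <- which(entries$site_id == act$site_id &
                    entries$stratum_key == act$stratum_key &
                    entries$schedule_version == maxv &
                    is.na(entries$assigned_to))
    cand <- cand[order(entries$sequence_no[cand])]
    if (length(cand) == 0) {
      arms <- c(arms, NA_character_)
      next
    }
    entries$assigned_to[cand[1]] <- act$participant_id
    arms <- c(arms, entries$arm[cand[1]])
  }
  list(arms = arms, entries = entries)
}

all_report_cells <- function(doc) {
  unlist(lapply(doc$sections, function(df) {
    unlist(lapply(df, function(col) as.character(col)), use.names = FALSE)
  }), use.names = FALSE)
}
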