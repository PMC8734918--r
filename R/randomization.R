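# Table-driven stratified randomization. All randomness lives in the
# pre-generated table: at enrollment a participant consumes the lowest
# (schedule_version, sequence_no) unconsumed entry matching their site and
# stratum, so replaying the enrollment log against the original table
# reproduces every assignment. Adaptive re-randomization schedules produced
# externally (e.g. at interim analyses) are appended per site with a strictly
# increasing schedule_version; appending supersedes that site's unconsumed
# lower-version entries.

#' Canonical stratum key from stratification factors
#'
#' Builds the order-independent key used to match participants to
#' randomization-table rows: factor names are sorted lexicographically and
#' joined as `name=level` pairs with `|`.
#'
#' @param strata named character vector or named list mapping
#'   stratification-factor name to category label; must be non-empty.
#' @return a single string, e.g. `"bmi=high|parity=nulli"`.
#' @export
stratum_key <- function(strata) {
  strata <- unlist(strata)
  if (length(strata) == 0 || is.null(names(strata)) || any(names(strata) == ""))
    abort_domain("strata must be a non-empty named vector")
  ord <- order(names(strata), method = "radix")
  paste(paste0(names(strata)[ord], "=", as.character(strata)[ord]),
        collapse = "|")
}

# entries-level invariants shared by the dataset validator and the loader
validate_randomization_entries <- function(entries) {
  if (nrow(entries) == 0) return(invisible(entries))
  key <- paste(entries$site_id, entries$stratum_key, entries$sequence_no,
               entries$schedule_version, sep = "\r")
  if (anyDuplicated(key))
    fail_rows("randomization_table", which(duplicated(key)),
              "duplicate (site_id, stratum_key, sequence_no, schedule_version)")
  if (any(bad <- is.na(entries$sequence_no) | entries$sequence_no < 1))
    fail_rows("randomization_table", which(bad), "sequence_no must be >= 1")
  if (any(bad <- is.na(entries$schedule_version) | entries$schedule_version < 1))
    fail_rows("randomization_table", which(bad), "schedule_version must be >= 1")
  if (any(bad <- is.na(entries$arm) | entries$arm == ""))
    fail_rows("randomization_table", which(bad), "missing arm label")
  # within site x stratum x version, consumed entries form a prefix in
  # sequence_no order
  grp <- split(seq_len(nrow(entries)),
               paste(entries$site_id, entries$stratum_key,
                     entries$schedule_version, sep = "\r"))
  for (idx in grp) {
    o <- idx[order(entries$sequence_no[idx])]
    consumed <- !is.na(entries$assigned_to[o])
    if (any(consumed) && any(!consumed[seq_len(max(which(consumed)))]))
      fail_rows("randomization_table", o[1],
                "consumed entries do not form a prefix within site/stratum/version")
  }
  invisible(entries)
}

mark_superseded <- function(entries) {
  superseded <- rep(FALSE, nrow(entries))
  if (nrow(entries) > 0) {
    for (sid in unique(entries$site_id)) {
      in_site <- entries$site_id == sid
      active <- max(entries$schedule_version[in_site])
      superseded[in_site & entries$schedule_version < active &
                   is.na(entries$assigned_to)] <- TRUE
    }
  }
  superseded
}

new_randomization_table <- function(entries, arms) {
  entries <- coerce_trial_table(entries, "randomization_table")
  validate_randomization_entries(entries)
  if (!is.null(arms)) {
    unknown <- setdiff(unique(entries$arm), arms)
    if (length(unknown) > 0)
      abort_config(sprintf("arm label(s) not in configured arms: %s",
                           paste(unknown, collapse = ", ")))
  } else {
    arms <- sort(unique(entries$arm))
  }
  structure(list(entries = entries, arms = arms,
                 superseded = mark_superseded(entries)),
            class = "randomization_table")
}

#' Load a randomization table from CSV
#'
#' Reads the pre-generated stratified assignment table (columns `site_id`,
#' `stratum_key`, `sequence_no`, `arm`, `schedule_version`, `assigned_to`),
#' verifying key uniqueness, prefix consumption within each site, stratum
#' and schedule version, and (when `arms` is given) that every arm label is
#' known. Unconsumed entries whose schedule_version is below their site's
#' newest version are marked superseded and are never assigned.
#'
#' @param path CSV file path.
#' @param arms optional character vector of permitted arm labels.
#' @return a `randomization_table` object.
#' @export
load_randomization_table <- function(path, arms = NULL) {
  entries <- read_one_table(path, "randomization_table")
  new_randomization_table(entries, arms)
}

#' Write a randomization table to CSV
#'
#' @param table a `randomization_table`
#' @param path output CSV path
#' @return invisibly, `path`.
#' @export
write_randomization_table <- function(table, path) {
  schema <- trial_table_schemas()$randomization_table
  out <- table$entries
  for (col in names(schema))
    out[[col]] <- format_csv_column(table$entries[[col]], schema[[col]])
  con <- file(path, open = "w", encoding = "UTF-8")
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  close(con)
  invisible(path)
}

#' @export
print.randomization_table <- function(x, ...) {
  cat(sprintf("<randomization_table> %d entries (%d consumed, %d superseded), arms: %s\n",
              nrow(x$entries), sum(!is.na(x$entries$assigned_to)),
              sum(x$superseded), paste(x$arms, collapse = ", ")))
  invisible(x)
}

#' Assign a participant to a treatment arm from the randomization table
#'
#' Consumes the lowest (schedule_version, sequence_no) unconsumed,
#' non-superseded entry matching the participant's site and stratum. The
#' assignment is fully deterministic given the table — all randomness was
#' embodied in table generation.
#'
#' @param table a `randomization_table`.
#' @param participant a list or one-row data frame with `participant_id`,
#'   `site_id` and either `strata` (named vector, see [stratum_key()]) or a
#'   ready-made `stratum_key` string; must not already carry an arm.
#' @return list with `arm` (label), `table` (updated), and `entry` (the
#'   consumed row).
#' @export
randomize_participant <- function(table, participant) {
  pid <- participant$participant_id
  if (!is.null(participant$arm) && !is.na(participant$arm) &&
      participant$arm != "")
    abort_state(sprintf("participant %s is already assigned to an arm", pid))
  key <- if (!is.null(participant$stratum_key) &&
             !is.na(participant$stratum_key)) participant$stratum_key
         else stratum_key(participant$strata)
  e <- table$entries
  if (pid %in% e$assigned_to)
    abort_state(sprintf("participant %s already consumed a table entry", pid))
  cand <- which(e$site_id == participant$site_id & e$stratum_key == key &
                  is.na(e$assigned_to) & !table$superseded)
  if (length(cand) == 0)
    trialops_error("trialops_exhaustion_error", sprintf(
      "randomization table exhausted for site '%s', stratum '%s'",
      participant$site_id, key))
  pick <- cand[order(e$schedule_version[cand], e$sequence_no[cand])][1]
  table$entries$assigned_to[pick] <- pid
  list(arm = e$arm[pick], table = table, entry = table$entries[pick, ])
}

#' Append an adaptively re-generated randomization schedule
#'
#' New entries (for example from an interim-analysis adaptation) must carry a
#' `schedule_version` strictly greater than every existing version at their
#' site and must be unassigned. After appending, that site's unconsumed
#' lower-version entries are superseded and are never consumed again.
#'
#' @param table a `randomization_table`.
#' @param new_entries data frame of entries in randomization-table layout.
#' @return the updated `randomization_table`.
#' @export
append_schedule <- function(table, new_entries) {
  new_entries <- coerce_trial_table(new_entries, "randomization_table")
  if (any(!is.na(new_entries$assigned_to)))
    abort_state("appended schedule entries must not be pre-assigned")
  for (sid in unique(new_entries$site_id)) {
    existing <- table$entries$schedule_version[table$entries$site_id == sid]
    newv <- new_entries$schedule_version[new_entries$site_id == sid]
    if (length(existing) > 0 && min(newv) <= max(existing))
      trialops_error("trialops_version_error", sprintf(
        "schedule_version for site '%s' must exceed the current version %d",
        sid, max(existing)))
  }
  entries <- rbind(table$entries, new_entries)
  out <- new_randomization_table(entries, table$arms)
  unknown <- setdiff(unique(new_entries$arm), table$arms)
  if (length(unknown) > 0)
    abort_config(sprintf("appended entries use unknown arm(s): %s",
                         paste(unknown, collapse = ", ")))
  out
}

#' Arm balance summary
#'
#' Counts assigned participants by site, stratum and arm; participants
#' without an arm are excluded.
#'
#' @param participants participants data frame (columns `site_id`, `strata`,
#'   `arm`).
#' @return data frame with columns `site_id`, `stratum_key`, `arm`, `n`,
#'   sorted by the first three columns.
#' @export
arm_balance <- function(participants) {
  p <- participants[!is.na(participants$arm) & participants$arm != "", ,
                    drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame(site_id = character(0), stratum_key = character(0),
                      arm = character(0), n = integer(0)))
  agg <- stats::aggregate(list(n = rep(1L, nrow(p))),
                          by = list(site_id = p$site_id,
                                    stratum_key = p$strata, arm = p$arm),
                          FUN = sum)
  agg <- agg[order(agg$site_id, agg$stratum_key, agg$arm), ]
  rownames(agg) <- NULL
  agg
}
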