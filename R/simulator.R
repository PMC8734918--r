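# Synthetic multisite trial generator. Emulates the operational structure
# the analytics assume: staggered site activation, Poisson enrollment at
# 2-3 participants/site/week, pregnancy timelines (enrollment before 20
# weeks gestation, estimated and actual delivery dates), stratified
# table-driven randomization, 30-day medication dispensing, ~6% loss to
# follow-up, rare protocol deviations, and eCRF records with injected data
# errors recorded in an answer key. Fully deterministic given the seed.

#' Simulation configuration
#'
#' Defaults emulate a three-site pregnancy trial: sites activating 0, 91 and
#' 152 days after study start (the second site three months and the third
#' five months after the first), each enrolling 2-3 participants per week,
#' a total target of 1100 over a maximum of four years, enrollment before
#' 20 weeks gestation, two arms, 6% loss to follow-up, a deviation
#' probability of 2/1100 per participant, and a 1% per-field data-entry
#' error rate.
#'
#' @param n_sites number of sites.
#' @param site_ids,site_names site identifiers and display names.
#' @param site_activation_offsets_days activation delay of each site, in
#'   days after `start_date`.
#' @param weekly_accrual_range (low, high) expected enrollments per site
#'   per week; each site's daily Poisson rate is drawn uniformly from
#'   `[low, high] / 7`.
#' @param target_n total enrollment target; accrual stops when reached.
#' @param site_caps optional named vector of per-site enrollment caps; when
#'   given, each site's event stream is truncated at its cap and
#'   `target_n` is the sum of caps (used by the fixed-totals preset).
#' @param enrollment_gestation_max_weeks upper gestational-age limit at
#'   enrollment (weeks); simulated gestational ages are Uniform(8, max).
#' @param arms treatment-arm labels.
#' @param dropout_prob per-participant probability of loss to follow-up.
#' @param deviation_prob per-participant probability of a protocol
#'   deviation.
#' @param error_injection_rate per-field probability of a data-entry error
#'   in the eCRF records.
#' @param start_date study start (first site activation).
#' @param max_days simulation horizon in days.
#' @param dispense_days days supplied per medication dispense.
#' @param block_size permuted-block size for the generated randomization
#'   table.
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_sites = 3L,
                       site_ids = c("KUMC", "OSU", "UC")[seq_len(n_sites)],
                       site_names = site_ids,
                       site_activation_offsets_days = c(0L, 91L, 152L)[seq_len(n_sites)],
                       weekly_accrual_range = c(2, 3),
                       target_n = 1100L,
                       site_caps = NULL,
                       enrollment_gestation_max_weeks = 20,
                       arms = c("treatment", "control"),
                       dropout_prob = 0.06,
                       deviation_prob = 2 / 1100,
                       error_injection_rate = 0.01,
                       start_date = as.Date("2016-06-01"),
                       max_days = 1461L,
                       dispense_days = 30L,
                       block_size = 4L,
                       seed = 20160601L) {
  cfg <- list(n_sites = as.integer(n_sites), site_ids = site_ids,
              site_names = site_names,
              site_activation_offsets_days = as.integer(site_activation_offsets_days),
              weekly_accrual_range = as.numeric(weekly_accrual_range),
              target_n = as.integer(target_n), site_caps = site_caps,
              enrollment_gestation_max_weeks = enrollment_gestation_max_weeks,
              arms = arms, dropout_prob = dropout_prob,
              deviation_prob = deviation_prob,
              error_injection_rate = error_injection_rate,
              start_date = as.Date(start_date),
              max_days = as.integer(max_days),
              dispense_days = as.integer(dispense_days),
              block_size = as.integer(block_size), seed = as.integer(seed))
  if (cfg$n_sites < 1 || length(cfg$site_ids) != cfg$n_sites ||
      length(cfg$site_activation_offsets_days) != cfg$n_sites)
    abort_config("site_ids and activation offsets must match n_sites")
  if (any(cfg$site_activation_offsets_days < 0))
    abort_config("site activation offsets must be non-negative")
  if (length(cfg$weekly_accrual_range) != 2 ||
      cfg$weekly_accrual_range[1] > cfg$weekly_accrual_range[2] ||
      cfg$weekly_accrual_range[1] < 0)
    abort_config("weekly_accrual_range must be (low, high) with 0 <= low <= high")
  for (pname in c("dropout_prob", "deviation_prob", "error_injection_rate"))
    if (cfg[[pname]] < 0 || cfg[[pname]] > 1)
      abort_config(sprintf("%s must lie in [0, 1]", pname))
  if (!is.null(cfg$site_caps)) {
    if (!setequal(names(cfg$site_caps), cfg$site_ids))
      abort_config("site_caps must be named by site_id")
    cfg$target_n <- as.integer(sum(cfg$site_caps))
  }
  structure(cfg, class = "sim_config")
}

#' Fixed per-site-totals preset
#'
#' A configuration whose per-site event streams are truncated at 489, 359
#' and 252 participants for the three sites, so the total accrual table is
#' reproduced by construction — useful for exercising the reporting layer
#' against known totals. The horizon is extended so every site reaches its
#' cap under any seed.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_fixed_totals <- function(...) {
  sim_config(site_caps = c(KUMC = 489L, OSU = 359L, UC = 252L),
             max_days = 2557L, ...)
}

#' Generate a permuted-block stratified randomization table
#'
#' For every site and stratum, blocks of size `block_size` are filled with
#' arms in the allocation ratio and independently permuted. Deterministic
#' given the seed.
#'
#' @param site_ids site identifiers.
#' @param strata_keys canonical stratum keys (see [stratum_key()]).
#' @param arms treatment-arm labels.
#' @param ratio integer allocation ratio, one entry per arm (default 1:1);
#'   `block_size` must be a multiple of `sum(ratio)`.
#' @param block_size entries per block.
#' @param n_blocks blocks per site-stratum.
#' @param seed integer seed.
#' @param schedule_version version stamp for the generated entries.
#' @return a `randomization_table`.
#' @export
generate_block_table <- function(site_ids, strata_keys, arms,
                                 ratio = rep(1L, length(arms)),
                                 block_size = 4L, n_blocks, seed,
                                 schedule_version = 1L) {
  ratio <- as.integer(ratio)
  if (length(ratio) != length(arms) || any(ratio < 1))
    abort_config("ratio must give a positive integer per arm")
  if (block_size %% sum(ratio) != 0)
    abort_config(sprintf("block_size %d is not a multiple of the ratio total %d",
                         block_size, sum(ratio)))
  block_arms <- rep(arms, ratio * (block_size %/% sum(ratio)))
  with_seed(seed, {
    rows <- list()
    for (sid in site_ids) for (key in strata_keys) {
      assigned <- unlist(lapply(seq_len(n_blocks),
                                function(b) sample(block_arms)))
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sid, stratum_key = key,
        sequence_no = seq_along(assigned), arm = assigned,
        schedule_version = as.integer(schedule_version),
        assigned_to = NA_character_, stringsAsFactors = FALSE)
    }
    new_randomization_table(do.call(rbind, rows), arms)
  })
}

# one site's enrollment dates: Poisson process at `rate`/day from activation
site_event_days <- function(rate, horizon_days) {
  if (rate <= 0) return(numeric(0))
  n_expect <- rate * horizon_days
  gaps <- stats::rexp(ceiling(n_expect + 6 * sqrt(n_expect) + 20), rate)
  times <- cumsum(gaps)
  while (length(times) > 0 && times[length(times)] < horizon_days) {
    gaps <- stats::rexp(ceiling(n_expect / 2) + 20, rate)
    times <- c(times, times[length(times)] + cumsum(gaps))
  }
  times[times <= horizon_days]
}

#' Simulate a complete multisite trial dataset
#'
#' Generates all nine operational tables plus a "truth" answer key
#' describing what was simulated: each site's realized daily enrollment
#' rate and total, the realized dropout fraction and deviation count, and
#' the exact location and kind of every injected eCRF data error (so the
#' data-quality checks can be scored against ground truth). The output is
#' fully deterministic given `config$seed` and satisfies every dataset
#' invariant.
#'
#' @param config a [sim_config()].
#' @return a validated `trial_dataset`; the answer key is attached as
#'   attribute `"truth"` and retrievable with [sim_truth()].
#' @examples
#' ds <- simulate_trial(sim_config(target_n = 40, max_days = 200, seed = 7))
#' table(ds$participants$status)
#' @export
simulate_trial <- function(config = sim_config()) {
  with_seed(config$seed, simulate_trial_impl(config))
}

simulate_trial_impl <- function(cfg) {
  horizon <- cfg$max_days
  offsets <- cfg$site_activation_offsets_days
  avail <- pmax(horizon - offsets, 0)
  mean_rate <- mean(cfg$weekly_accrual_range) / 7
  if (is.null(cfg$site_caps) && mean_rate * sum(avail) < cfg$target_n)
    abort_config(sprintf(
      "infeasible config: expected total accrual %.0f (rate %.3f/day over %d site-days) cannot reach target_n %d within max_days %d",
      mean_rate * sum(avail), mean_rate, sum(avail), cfg$target_n, horizon))

  sites <- data.frame(
    site_id = cfg$site_ids, name = cfg$site_names,
    activation_date = cfg$start_date + offsets,
    target_weekly_accrual_low = cfg$weekly_accrual_range[1],
    target_weekly_accrual_high = cfg$weekly_accrual_range[2],
    stringsAsFactors = FALSE)

  daily_rates <- stats::runif(cfg$n_sites, cfg$weekly_accrual_range[1],
                              cfg$weekly_accrual_range[2]) / 7
  events <- do.call(rbind, lapply(seq_len(cfg$n_sites), function(i) {
    days <- site_event_days(daily_rates[i], avail[i])
    if (!is.null(cfg$site_caps)) {
      cap <- cfg$site_caps[[cfg$site_ids[i]]]
      if (length(days) < cap)
        abort_config(sprintf(
          "infeasible config: site %s produced %d events, below its cap %d",
          cfg$site_ids[i], length(days), cap))
      days <- days[seq_len(cap)]
    }
    data.frame(site_id = cfg$site_ids[i],
               date = cfg$start_date + offsets[i] + floor(days),
               stringsAsFactors = FALSE)
  }))
  events <- events[order(events$date, events$site_id), , drop = FALSE]
  if (is.null(cfg$site_caps) && nrow(events) > cfg$target_n)
    events <- events[seq_len(cfg$target_n), , drop = FALSE]
  n <- nrow(events)
  if (n == 0)
    abort_config("infeasible config: no enrollment events within max_days")
  pid <- seq_ids("P", n)
  as_of_final <- max(events$date)

  # pregnancy timelines
  # keep strictly below the enrollment limit after rounding to 2 decimals
  ga <- pmin(round(stats::runif(n, 8, cfg$enrollment_gestation_max_weeks), 2),
             cfg$enrollment_gestation_max_weeks - 0.01)
  enroll <- events$date
  screening <- enroll - sample.int(14L, n, replace = TRUE)
  consent <- screening + floor(stats::runif(n) *
                                 (as.numeric(enroll - screening) + 1))
  edd <- enroll + round_half_up((40 - ga) * 7)
  delivery <- edd + round_half_up(stats::rnorm(n, 0, 10))
  delivery <- pmax(delivery, enroll + 7L)

  dropped <- stats::runif(n) < cfg$dropout_prob
  # dropouts leave partway through treatment, before delivery
  last_active <- delivery
  frac <- stats::runif(n)
  last_active[dropped] <- enroll[dropped] +
    floor(frac[dropped] * pmax(as.numeric(delivery - enroll)[dropped] - 1, 1))

  status <- ifelse(dropped, "lost_to_followup",
                   ifelse(delivery <= as_of_final, "completed", "on_treatment"))
  actual_delivery <- as.Date(ifelse(status == "completed", delivery, NA),
                             origin = "1970-01-01")
  signoff <- status == "completed" & stats::runif(n) < 0.8

  # stratification: a single gestational-age factor, two levels
  ga_group <- ifelse(ga < 14, "lt14w", "ge14w")
  skeys <- vapply(ga_group, function(g) stratum_key(c(ga_stratum = g)),
                  character(1), USE.NAMES = FALSE)

  # randomization table sized for the worst-case per-cell demand, then
  # consumed sequentially in enrollment order (equivalent to repeated
  # randomize_participant calls; the replay equivalence is tested)
  max_site_n <- if (is.null(cfg$site_caps)) n else max(cfg$site_caps)
  per_cell <- ceiling(max_site_n / cfg$block_size) + 5L
  rt <- generate_block_table(cfg$site_ids,
                             vapply(c("lt14w", "ge14w"),
                                    function(g) stratum_key(c(ga_stratum = g)),
                                    character(1), USE.NAMES = FALSE),
                             cfg$arms, block_size = cfg$block_size,
                             n_blocks = per_cell,
                             seed = floor(stats::runif(1, 1, 2^30)))
  e <- rt$entries
  arm <- character(n)
  ord <- order(e$site_id, e$stratum_key, e$schedule_version, e$sequence_no)
  pool <- split(ord, paste(e$site_id[ord], e$stratum_key[ord], sep = "\r"))
  next_idx <- stats::setNames(rep(1L, length(pool)), names(pool))
  for (i in seq_len(n)) {
    cell <- paste(events$site_id[i], skeys[i], sep = "\r")
    j <- pool[[cell]][next_idx[[cell]]]
    if (is.null(j) || is.na(j))
      abort_config("generated randomization table exhausted; increase n_blocks")
    e$assigned_to[j] <- pid[i]
    arm[i] <- e$arm[j]
    next_idx[[cell]] <- next_idx[[cell]] + 1L
  }

  participants <- data.frame(
    participant_id = pid, site_id = events$site_id,
    screening_date = screening, consent_date = consent,
    enrollment_date = enroll,
    gestational_age_weeks_at_enrollment = ga,
    strata = skeys, arm = arm, status = status,
    estimated_delivery_date = edd, actual_delivery_date = actual_delivery,
    signoff_done = signoff, stringsAsFactors = FALSE)

  enrollment <- data.frame(participant_id = pid, site_id = events$site_id,
                           date = enroll, stringsAsFactors = FALSE)

  # 30-day dispense cycles while active
  disp_end <- pmin(last_active, as_of_final)
  dispenses <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (disp_end[i] < enroll[i]) return(NULL)
    dates <- seq(enroll[i], disp_end[i], by = cfg$dispense_days)
    data.frame(participant_id = pid[i], dispense_date = dates,
               days_supplied = cfg$dispense_days, stringsAsFactors = FALSE)
  }))
  if (is.null(dispenses)) dispenses <- empty_trial_table("dispenses")

  # adverse events: ~10% of participants, 10% of those serious
  has_ae <- stats::runif(n) < 0.10
  ae_idx <- which(has_ae)
  adverse_events <- if (length(ae_idx) > 0) {
    onset <- enroll[ae_idx] + floor(stats::runif(length(ae_idx)) *
                                      pmax(as.numeric(disp_end[ae_idx] -
                                                        enroll[ae_idx]), 1))
    serious <- stats::runif(length(ae_idx)) < 0.10
    reviewed <- stats::runif(length(ae_idx)) < 0.8
    attribution <- ifelse(reviewed,
                          sample(c("unrelated", "possibly", "probably",
                                   "definitely"), length(ae_idx),
                                 replace = TRUE,
                                 prob = c(0.6, 0.25, 0.1, 0.05)),
                          "unassessed")
    data.frame(ae_id = seq_ids("AE", length(ae_idx)),
               participant_id = pid[ae_idx], onset_date = onset,
               description = "adverse event (simulated)", serious = serious,
               reviewed = reviewed, attribution = attribution,
               stringsAsFactors = FALSE)
  } else empty_trial_table("adverse_events")

  dev_idx <- which(stats::runif(n) < cfg$deviation_prob)
  deviations <- if (length(dev_idx) > 0) {
    data.frame(deviation_id = seq_ids("DV", length(dev_idx), width = 3),
               participant_id = pid[dev_idx],
               date = enroll[dev_idx] +
                 floor(stats::runif(length(dev_idx)) * 30),
               description = "protocol deviation (simulated)",
               stringsAsFactors = FALSE)
  } else empty_trial_table("deviations")

  field_definitions <- default_field_definitions()
  fr <- sim_form_records(pid, enroll, ga, cfg$error_injection_rate)

  ds <- trial_dataset(sites = sites, participants = participants,
                      enrollment = enrollment,
                      randomization_table = e, dispenses = dispenses,
                      adverse_events = adverse_events,
                      deviations = deviations,
                      field_definitions = field_definitions,
                      form_records = fr$records)

  site_tab <- table(enrollment$site_id)
  truth <- list(
    seed = cfg$seed,
    n_enrolled = n,
    per_site_totals = as.list(stats::setNames(as.integer(site_tab),
                                              names(site_tab))),
    daily_rates = as.list(stats::setNames(daily_rates, cfg$site_ids)),
    realized_dropout_fraction = sum(dropped) / n,
    n_lost = as.integer(sum(dropped)),
    n_deviations = nrow(deviations),
    final_enrollment_date = format(as_of_final, "%Y-%m-%d"),
    injected_errors = fr$answer_key)
  attr(ds, "truth") <- truth
  ds
}

#' Answer key of a simulated dataset
#'
#' @param ds a dataset from [simulate_trial()].
#' @return the truth list (realized rates, totals, dropout fraction,
#'   deviation count, injected-error locations), or `NULL` for datasets not
#'   produced by the simulator.
#' @export
sim_truth <- function(ds) attr(ds, "truth")

#' Write a simulator answer key as JSON
#'
#' @param truth a truth list from [sim_truth()].
#' @param path output path (conventionally `truth.json` beside the CSVs).
#' @return invisibly, `path`.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Default eCRF field definitions used by the simulator
#'
#' A compact enrollment form: gestational age (numeric, range 4-45 weeks,
#' with the cross-field rule that enrollment occurs before 20 weeks),
#' maternal age (numeric, 18-50), smoking status (categorical), enrollment
#' date (date), and free-text contact notes (optional).
#'
#' @return field definitions data frame.
#' @export
default_field_definitions <- function() {
  data.frame(
    form_name = "enrollment",
    field_name = c("gestational_age_weeks", "maternal_age", "smoking_status",
                   "enrollment_date", "contact_notes"),
    value_kind = c("numeric", "numeric", "categorical", "date", "text"),
    required = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    allowed_categories = c(NA, NA, "never|former|current", NA, NA),
    numeric_min = c(4, 18, NA, NA, NA),
    numeric_max = c(45, 50, NA, NA, NA),
    logic_rules = c("enrollment_before_20_weeks", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}

# Build clean enrollment-form records, then corrupt a random subset of
# fields, one rule kind per corrupted field, logging each to the answer key.
sim_form_records <- function(pid, enroll, ga, error_rate) {
  n <- length(pid)
  maternal_age <- round_half_up(stats::runif(n, 18, 45))
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.7, 0.2, 0.1))
  values <- list(
    gestational_age_weeks = as.character(ga),
    maternal_age = as.character(maternal_age),
    smoking_status = smoking,
    enrollment_date = format(enroll, "%Y-%m-%d"),
    contact_notes = rep("", n))
  # applicable corruption kinds per field
  kinds <- list(
    gestational_age_weeks = c("missing_required", "format_error",
                              "out_of_range", "logic_violation"),
    maternal_age = c("missing_required", "format_error", "out_of_range"),
    smoking_status = c("missing_required", "format_error", "invalid_category"),
    enrollment_date = c("missing_required", "bad_date"),
    contact_notes = character(0))
  key_rows <- list()
  for (field in names(values)) {
    applicable <- kinds[[field]]
    if (length(applicable) == 0) next
    hit <- which(stats::runif(n) < error_rate)
    for (i in hit) {
      kind <- applicable[sample.int(length(applicable), 1)]
      values[[field]][i] <- switch(kind,
        missing_required = "",
        format_error = "NA",
        # below-range for gestational age so the range check fires without
        # also tripping the 20-week logic rule
        out_of_range = if (field == "gestational_age_weeks") "2" else "12",
        invalid_category = "occasionally",
        logic_violation = as.character(round(stats::runif(1, 21, 35), 1)),
        bad_date = sample(c("2021-02-30", "not-a-date", "31/12/2020"), 1))
      key_rows[[length(key_rows) + 1]] <- data.frame(
        participant_id = pid[i], form_name = "enrollment",
        field_name = field, rule = kind, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, lapply(names(values), function(field) {
    data.frame(participant_id = pid, form_name = "enrollment",
               field_name = field, value = values[[field]],
               stringsAsFactors = FALSE)
  }))
  records <- records[order(records$participant_id, records$form_name,
                           records$field_name), , drop = FALSE]
  rownames(records) <- NULL
  answer_key <- if (length(key_rows) > 0) {
    k <- do.call(rbind, key_rows)
    k <- k[order(k$participant_id, k$form_name, k$field_name, k$rule), ,
           drop = FALSE]
    rownames(k) <- NULL
    k
  } else data.frame(participant_id = character(0), form_name = character(0),
                    field_name = character(0), rule = character(0))
  list(records = records, answer_key = answer_key)
}
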