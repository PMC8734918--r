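# Operational report suite: inclusion rules, cadences, blinding and
# deterministic rendering.

test_that("the resupply flag date is two weeks before run-out", {
  p <- rbind(make_participant("P1", status = "on_treatment"),
             make_participant("P2", status = "on_treatment"),
             make_participant("P3", status = "completed",
                              actual_delivery_date = as.Date("2021-03-05")))
  disp <- data.frame(participant_id = c("P1", "P3"),
                     dispense_date = as.Date(c("2021-03-01", "2021-03-01")),
                     days_supplied = 30L)
  ds <- make_dataset(p, dispenses = disp)

  # run-out 2021-03-31, flag 2021-03-17: included on the 18th...
  rows <- resupply_report(ds, as.Date("2021-03-18"))$sections$upcoming_refills
  expect_true("P1" %in% rows$participant_id)
  expect_identical(rows$flag_date[rows$participant_id == "P1"],
                   as.Date("2021-03-17"))
  expect_identical(rows$runout_date[rows$participant_id == "P1"],
                   as.Date("2021-03-31"))
  # ...and on the flag date itself, but not before
  expect_true("P1" %in% resupply_report(ds, as.Date("2021-03-17"))$
                sections$upcoming_refills$participant_id)
  early <- resupply_report(ds, as.Date("2021-03-10"))$sections$upcoming_refills
  expect_false("P1" %in% early$participant_id)
  # completed participants are never listed, whatever their dates
  expect_false("P3" %in% rows$participant_id)
  # active participant with no dispense on file is flagged, listed first
  expect_identical(rows$note[rows$participant_id == "P2"], "never dispensed")
  expect_identical(rows$participant_id[1], "P2")
  # only the latest dispense defines run-out
  ds2 <- make_dataset(p[1, , drop = FALSE],
                      dispenses = data.frame(
                        participant_id = "P1",
                        dispense_date = as.Date(c("2021-02-10", "2021-03-01")),
                        days_supplied = 30L))
  r2 <- resupply_report(ds2, as.Date("2021-03-18"))$sections$upcoming_refills
  expect_identical(r2$last_refill_date, as.Date("2021-03-01"))
})

test_that("the delivery watch list honours the horizon and reports missing EDDs", {
  as_of <- as.Date("2021-06-01")
  p <- rbind(
    make_participant("IN59", estimated_delivery_date = as_of + 59),
    make_participant("IN60", estimated_delivery_date = as_of + 60),
    make_participant("OUT61", estimated_delivery_date = as_of + 61),
    make_participant("PAST", estimated_delivery_date = as_of - 1),
    make_participant("DONE", status = "completed",
                     estimated_delivery_date = as_of + 10,
                     actual_delivery_date = as_of - 5),
    make_participant("NOEDD", estimated_delivery_date = as.Date(NA)))
  doc <- delivery_watchlist(make_dataset(p), as_of)
  expect_setequal(doc$sections$due_to_deliver$participant_id, c("IN59", "IN60"))
  expect_identical(doc$sections$missing_estimated_delivery_date$participant_id,
                   "NOEDD")
  expect_error(delivery_watchlist(make_dataset(p), as_of, horizon_days = 0),
               class = "trialops_precondition_error")
})

test_that("watch-list rows equal a brute-force filter on a random fixture", {
  set.seed(52)
  as_of <- as.Date("2021-06-01")
  p <- do.call(rbind, lapply(1:50, function(i) {
    delivered <- runif(1) < 0.3
    make_participant(sprintf("P%02d", i),
                     sample(c("A", "B", "C"), 1),
                     enrollment_date = as.Date("2021-03-15"),
                     status = if (delivered) "completed" else "on_treatment",
                     estimated_delivery_date = as_of + sample(-30:120, 1),
                     actual_delivery_date = if (delivered) as_of - sample(1:50, 1)
                                            else as.Date(NA))
  }))
  ds <- make_dataset(p)
  got <- delivery_watchlist(ds, as_of, horizon_days = 60)$sections$due_to_deliver
  want <- character(0)
  for (i in seq_len(nrow(p)))
    if (is.na(p$actual_delivery_date[i]) &&
        !is.na(p$estimated_delivery_date[i]) &&
        p$estimated_delivery_date[i] >= as_of &&
        p$estimated_delivery_date[i] <= as_of + 60)
      want <- c(want, p$participant_id[i])
  expect_setequal(got$participant_id, want)
  # grouped by site, then ordered by estimated delivery date
  expect_false(is.unsorted(got$site_id))
  for (s in unique(got$site_id))
    expect_false(is.unsorted(got$estimated_delivery_date[got$site_id == s]))
})

test_that("the AE report lists new and unreviewed events, serious first, without arms", {
  p <- make_participant("P1")
  ae <- data.frame(
    ae_id = sprintf("AE%d", 1:5), participant_id = "P1",
    onset_date = as.Date(c("2021-03-01", "2021-03-20", "2021-03-25",
                           "2021-02-01", "2021-02-10")),
    description = "event",
    serious = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    reviewed = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    attribution = c("unrelated", "possibly", "unrelated", "unassessed",
                    "probably"))
  ds <- make_dataset(p, adverse_events = ae)
  doc <- ae_report(ds, since = as.Date("2021-03-15"), as_of = as.Date("2021-04-01"))
  rows <- doc$sections$adverse_events
  # AE2, AE3 are in-window; AE4 is unreviewed; AE1, AE5 are old and reviewed
  expect_setequal(rows$ae_id, c("AE2", "AE3", "AE4"))
  expect_identical(rows$ae_id[1], "AE2")        # serious first
  expect_false("arm" %in% names(rows))
  expect_identical(nrow(ae_report(make_dataset(p),
                                  as.Date("2021-01-01"),
                                  as.Date("2021-04-01"))$sections$adverse_events),
                   0L)
})

test_that("the sign-off report lists completed participants awaiting sign-off", {
  p <- do.call(rbind, lapply(1:7, function(i)
    make_participant(sprintf("P%d", i),
                     status = if (i <= 5) "completed" else "on_treatment",
                     actual_delivery_date = if (i <= 5) as.Date("2021-08-01")
                                            else as.Date(NA),
                     signoff_done = i <= 2)))
  doc <- pi_signoff_report(make_dataset(p), as.Date("2021-09-01"))
  expect_setequal(doc$sections$awaiting_signoff$participant_id,
                  c("P3", "P4", "P5"))
  p$signoff_done[1:5] <- TRUE
  expect_identical(nrow(pi_signoff_report(make_dataset(p),
                                          as.Date("2021-09-01"))$
                          sections$awaiting_signoff), 0L)
})

test_that("report cadences: weekly Monday, twice-weekly Mon+Thu, twice-monthly 1st+15th, serious AEs immediately", {
  # 2021-03-08 is a Monday (and not the 1st or 15th)
  expect_setequal(reports_due(on_date = as.Date("2021-03-08")),
                  c("accrual", "data_query", "resupply", "delivery_watchlist",
                    "adverse_events"))
  # Thursday: only the twice-weekly AE report
  expect_identical(reports_due(on_date = as.Date("2021-03-18")),
                   "adverse_events")
  # 2021-09-15 is a Wednesday: twice-monthly sign-off is due
  expect_identical(reports_due(on_date = as.Date("2021-09-15")), "pi_signoff")
  expect_true("pi_signoff" %in% reports_due(on_date = as.Date("2021-09-01")))
  # a quiet Tuesday
  expect_length(reports_due(on_date = as.Date("2021-03-16")), 0)
  # serious AE forces the AE report on any day
  expect_identical(reports_due(on_date = as.Date("2021-03-16"),
                               new_serious_ae = TRUE), "adverse_events")
})

test_that("an empty trial yields an all-zero accrual report flagged insufficient data", {
  ds <- trial_dataset(sites = make_sites())
  doc <- accrual_report(ds, as.Date("2021-02-01"), target_n = 1100)
  s <- doc$sections$summary
  expect_identical(s$value[s$measure == "enrolled"], "0")
  expect_identical(s$value[s$measure == "predicted_completion"],
                   "insufficient data")
  expect_identical(nrow(doc$sections$accrual_by_site), 0L)
  expect_true(all(doc$sections$participant_status$n == 0))
})

test_that("accrual report sections equal brute-force filters and check the as-of date", {
  ds <- simulate_trial(sim_config(target_n = 70, max_days = 300, seed = 23))
  as_of <- max(ds$enrollment$date)
  post <- fit_accrual_model(ds$enrollment, min(ds$sites$activation_date), as_of)
  pr <- predict_completion(post, nrow(ds$enrollment), 100, as_of, 1000, seed = 4)
  doc <- accrual_report(ds, as_of, 100, pr)

  acc <- doc$sections$accrual_by_site
  tot <- acc[acc$window == "total", ]
  want <- bf_window_counts(ds$enrollment, min(ds$enrollment$date), as_of)
  expect_identical(setNames(tot$n, tot$site_id), want)

  p <- ds$participants
  recent <- !is.na(p$actual_delivery_date) &
    p$actual_delivery_date >= as_of - 29 & p$actual_delivery_date <= as_of
  births <- doc$sections$deliveries
  got <- births[births$measure == "births_last_30_days", ]
  for (s in unique(p$site_id[recent]))
    expect_identical(got$n[got$site_id == s], sum(recent & p$site_id == s))
  expect_error(accrual_report(ds, as_of - 1, 100, pr),
               class = "trialops_precondition_error")
})

test_that("no report ever shows a treatment arm and rendering is deterministic", {
  ds <- simulate_trial(sim_config(target_n = 60, max_days = 250, seed = 31))
  as_of <- max(ds$enrollment$date)
  q <- run_checks(ds$form_records, ds$field_definitions, as_of)
  docs <- list(
    accrual_report(ds, as_of, 100),
    resupply_report(ds, as_of),
    delivery_watchlist(ds, as_of),
    ae_report(ds, as_of - 14, as_of),
    pi_signoff_report(ds, as_of),
    data_query_report(ds, q, as_of))
  arms <- unique(ds$participants$arm)
  for (doc in docs) {
    cells <- all_report_cells(doc)
    expect_false(any(cells %in% arms), label = doc$report_kind)
    expect_false(any(vapply(doc$sections, function(df) "arm" %in% names(df),
                            logical(1))))
  }
  # byte-determinism: regenerate everything from the same seed
  ds2 <- simulate_trial(sim_config(target_n = 60, max_days = 250, seed = 31))
  expect_identical(render_report_md(accrual_report(ds2, as_of, 100)),
                   render_report_md(docs[[1]]))
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  f1 <- write_report(docs[[2]], dir1)
  f2 <- write_report(resupply_report(ds2, as_of), dir2)
  expect_identical(readLines(f1["json"]), readLines(f2["json"]))
  expect_identical(readLines(f1["md"]), readLines(f2["md"]))
})
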