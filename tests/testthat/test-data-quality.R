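# Edit/logic/range checks, the query lifecycle state machine, lock
# readiness, and the trial-quality metrics.

defs_fixture <- default_field_definitions()

clean_records <- function(pid) {
  data.frame(participant_id = pid, form_name = "enrollment",
             field_name = c("gestational_age_weeks", "maternal_age",
                            "smoking_status", "enrollment_date",
                            "contact_notes"),
             value = c("12.5", "29", "never", "2021-02-01", ""),
             stringsAsFactors = FALSE)
}

test_that("clean records produce no queries", {
  recs <- rbind(clean_records("P1"), clean_records("P2"))
  expect_identical(nrow(run_checks(recs, defs_fixture, as.Date("2021-03-01"))), 0L)
})

test_that("each violation kind is detected once, at its location, matching a brute-force validator", {
  recs <- rbind(clean_records("P1"), clean_records("P2"), clean_records("P3"))
  # seven injected violations of known, disjoint kinds
  inject <- function(pid, field, value) {
    recs$value[recs$participant_id == pid & recs$field_name == field] <<- value
  }
  inject("P1", "gestational_age_weeks", "25")      # logic: >= 20 weeks
  inject("P1", "maternal_age", "12")               # below range
  inject("P1", "smoking_status", "sometimes")      # invalid category
  inject("P2", "enrollment_date", "2021-02-30")    # impossible date
  inject("P2", "maternal_age", "NA")               # placeholder junk
  inject("P2", "gestational_age_weeks", "")        # required but empty
  inject("P3", "maternal_age", "abc")              # non-numeric edit check

  got <- run_checks(recs, defs_fixture, as.Date("2021-03-01"))
  expect_identical(nrow(got), 7L)
  expect_true(all(got$status == "open"))
  expect_true(all(got$opened_on == as.Date("2021-03-01")))
  want <- bf_validate(recs, defs_fixture)
  expect_identical(got[c("participant_id", "form_name", "field_name", "rule")],
                   want)
  expect_identical(
    got$rule[got$participant_id == "P1" &
               got$field_name == "gestational_age_weeks"], "logic_violation")
  # a field present in the records but absent from the definitions
  rogue <- rbind(recs, data.frame(participant_id = "P1",
                                  form_name = "enrollment",
                                  field_name = "shoe_size", value = "38"))
  expect_error(run_checks(rogue, defs_fixture, as.Date("2021-03-01")),
               class = "trialops_definition_error", regexp = "shoe_size")
})

test_that("random fuzzed records agree with the brute-force validator", {
  set.seed(1234)
  pool <- c("12", "19.9", "25", "55", "", "NA", "never", "sometimes",
            "2021-02-01", "2021-13-01", "abc", "  ", "n/a", "30")
  for (rep in 1:10) {
    recs <- do.call(rbind, lapply(sprintf("P%02d", 1:6), clean_records))
    mutate <- sample(nrow(recs), 12)
    recs$value[mutate] <- sample(pool, 12, replace = TRUE)
    got <- run_checks(recs, defs_fixture, as.Date("2021-03-01"))
    want <- bf_validate(recs, defs_fixture)
    expect_identical(got[c("participant_id", "form_name", "field_name", "rule")],
                     want)
  }
})

test_that("queries move open -> sent -> resolved and never backwards", {
  recs <- rbind(clean_records("P1"), clean_records("P2"))
  recs$value[recs$field_name == "maternal_age"] <- c("12", "70")
  q <- run_checks(recs, defs_fixture, as.Date("2021-03-01"))
  expect_identical(nrow(q), 2L)

  # resolving before sending is a lifecycle error
  expect_error(resolve_query(q, q$query_id[1], as.Date("2021-03-02")),
               class = "trialops_state_error")

  sent <- batch_send_queries(q, as.Date("2021-03-08"))
  expect_true(all(sent$status == "sent"))
  expect_true(all(sent$sent_on == as.Date("2021-03-08")))
  # idempotence: a second send changes nothing
  expect_identical(batch_send_queries(sent, as.Date("2021-03-15")), sent)

  res <- resolve_query(sent, sent$query_id[1], as.Date("2021-03-10"))
  expect_identical(res$status[1], "resolved")
  expect_identical(res$resolved_on[1], as.Date("2021-03-10"))
  expect_error(resolve_query(res, res$query_id[1], as.Date("2021-03-11")),
               class = "trialops_state_error")
  expect_error(resolve_query(res, "Q99999", as.Date("2021-03-11")),
               class = "trialops_state_error")

  lock <- check_lock_ready(res)
  expect_false(lock$ready)
  expect_identical(nrow(lock$blockers), 1L)
  res2 <- resolve_query(res, res$query_id[2], as.Date("2021-03-11"))
  expect_true(check_lock_ready(res2)$ready)
  expect_identical(nrow(check_lock_ready(res2)$blockers), 0L)
})

test_that("random valid lifecycle sequences match a state-machine oracle", {
  set.seed(99)
  for (rep in 1:10) {
    recs <- do.call(rbind, lapply(sprintf("P%02d", 1:4), clean_records))
    recs$value[recs$field_name == "maternal_age"] <- "70"
    q <- run_checks(recs, defs_fixture, as.Date("2021-03-01"))
    oracle <- setNames(rep("open", nrow(q)), q$query_id)
    for (step in 1:12) {
      if (runif(1) < 0.3) {
        q <- batch_send_queries(q, as.Date("2021-03-01") + step)
        oracle[oracle == "open"] <- "sent"
      } else {
        id <- sample(names(oracle), 1)
        ok <- oracle[id] == "sent"
        r <- try(resolve_query(q, id, as.Date("2021-03-01") + step),
                 silent = TRUE)
        if (ok) {
          q <- r
          oracle[id] <- "resolved"
        } else {
          expect_s3_class(attr(r, "condition"), "trialops_state_error")
        }
      }
    }
    expect_identical(setNames(q$status, q$query_id), oracle)
    done <- q[q$status == "resolved", ]
    expect_true(all(done$resolved_on >= done$sent_on &
                      done$sent_on >= done$opened_on))
  }
})

test_that("re-detection does not duplicate unresolved queries; resolved ones reopen", {
  recs <- clean_records("P1")
  recs$value[recs$field_name == "maternal_age"] <- "70"
  q1 <- run_checks(recs, defs_fixture, as.Date("2021-03-01"))
  q2 <- reconcile_queries(q1, run_checks(recs, defs_fixture, as.Date("2021-03-08")))
  expect_identical(nrow(q2), 1L)
  # resolve it, but the violation persists: a fresh query with a new id opens
  q3 <- resolve_query(batch_send_queries(q2, as.Date("2021-03-08")),
                      q2$query_id[1], as.Date("2021-03-10"))
  q4 <- reconcile_queries(q3, run_checks(recs, defs_fixture, as.Date("2021-03-15")))
  expect_identical(nrow(q4), 2L)
  expect_identical(q4$status, c("resolved", "open"))
  expect_false(q4$query_id[2] == q4$query_id[1])
})

test_that("quality metrics reproduce the deviation rate and loss percentage", {
  p <- do.call(rbind, lapply(seq_len(1100), function(i)
    make_participant(sprintf("P%04d", i), "A",
                     as.Date("2021-02-01") + (i %% 300),
                     status = if (i <= 68) "lost_to_followup" else "completed",
                     actual_delivery_date = as.Date("2022-06-01"))))
  dev <- data.frame(deviation_id = c("D1", "D2"),
                    participant_id = c("P0100", "P0200"),
                    date = as.Date("2021-06-01"), description = "deviation")
  m <- quality_metrics(make_dataset(p, deviations = dev))
  expect_identical(m$n_participants, 1100L)
  expect_equal(m$deviation_rate, 0.0018)
  expect_equal(m$loss_pct, 6)
  expect_identical(m$n_lost, 68L)

  # the literature benchmark rate: 88 deviations in 1100
  dev88 <- data.frame(deviation_id = sprintf("D%03d", 1:88),
                      participant_id = sprintf("P%04d", 1:88),
                      date = as.Date("2021-06-01"), description = "deviation")
  expect_equal(quality_metrics(make_dataset(p, deviations = dev88))$deviation_rate,
               0.08)

  screened_only <- make_participant("P1", status = "screened",
                                    arm = NA_character_)
  expect_error(quality_metrics(make_dataset(screened_only)),
               class = "trialops_domain_error")
})
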