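# Accrual analytics: windowed enrollment summaries, the Gini index of
# accrual inequality across sites, and Bayesian posterior-predictive
# forecasting of the enrollment completion date.
#
# Model: enrollment is treated as a homogeneous Poisson process with daily
# rate lambda. With a conjugate Gamma(shape, rate) prior on lambda, observing
# n events over t days of exposure gives the posterior
# Gamma(shape + n, rate + t). The time to enroll the remaining m
# participants is the sum of m exponential waiting times, i.e.
# Gamma(m, lambda); integrating over the lambda posterior gives the
# posterior-predictive completion-time distribution, sampled by Monte Carlo.

#' Accrual counts by reporting window
#'
#' Summarizes enrollment events into the three windows used on weekly
#' accrual reports: the current calendar month (day 1 of the month of
#' `as_of` through `as_of`), the past 30 days (the closed window
#' `as_of - 29` through `as_of`), and the whole study. Sites with a zero
#' count in a window are omitted from that window's counts.
#'
#' @param events data frame of enrollment events with columns
#'   `participant_id`, `site_id`, `date` (Date).
#' @param as_of reporting date; every event must be on or before it.
#' @return an object of class `accrual_windows`: a list with Date `as_of`
#'   and named integer vectors `current_month`, `last_30_days`, `total`
#'   (site_id -> count).
#' @examples
#' ev <- data.frame(participant_id = c("P1", "P2"), site_id = c("A", "B"),
#'                  date = as.Date(c("2021-03-02", "2021-02-20")))
#' accrual_by_window(ev, as.Date("2021-03-15"))
#' @export
accrual_by_window <- function(events, as_of) {
  as_of <- as.Date(as_of)
  dates <- as.Date(events$date)
  if (any(!is.na(dates) & dates > as_of))
    abort_precondition("enrollment events dated after as_of")
  count_in <- function(from) {
    keep <- dates >= from & dates <= as_of
    tab <- table(events$site_id[keep])
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    counts[counts > 0]
  }
  structure(list(
    as_of = as_of,
    current_month = count_in(first_of_month(as_of)),
    last_30_days = count_in(as_of - 29L),
    total = count_in(as.Date("0001-01-01"))
  ), class = "accrual_windows")
}

#' @export
print.accrual_windows <- function(x, ...) {
  cat(sprintf("<accrual_windows> as of %s\n", format(x$as_of)))
  for (w in c("current_month", "last_30_days", "total")) {
    cat(sprintf("  %-14s", w))
    if (length(x[[w]]) == 0) cat(" (none)")
    else cat(sprintf(" %s=%d", names(x[[w]]), x[[w]]))
    cat("\n")
  }
  invisible(x)
}

#' Gini coefficient of per-site accrual
#'
#' The unweighted mean-absolute-difference Gini index,
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar{x}),}
#' with no small-sample correction, so `G` lies in `[0, (n-1)/n]`.
#' `G = 0` means perfectly equal accrual across sites; values below 0.2 are
#' conventionally read as low accrual inequality in multisite trials.
#'
#' @param counts numeric vector of per-site enrollment totals (length >= 2,
#'   all non-negative, not all zero).
#' @return the Gini coefficient, a number in `[0, 1)`.
#' @examples
#' gini_coefficient(c(489, 359, 252))  # ~0.144
#' @seealso [classify_inequality()]
#' @export
gini_coefficient <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2)
    abort_domain("gini_coefficient needs at least 2 sites")
  if (anyNA(counts) || any(counts < 0))
    abort_domain("counts must be non-negative and non-missing")
  if (all(counts == 0))
    abort_domain("counts must not all be zero")
  n <- length(counts)
  sum(abs(outer(counts, counts, "-"))) / (2 * n^2 * mean(counts))
}

#' Classify accrual inequality from a Gini coefficient
#'
#' @param gini Gini coefficient in `[0, 1)`.
#' @param threshold classification cut point; inequality is `low` iff
#'   `gini < threshold` (strict). Default 0.2.
#' @param n_sites optional number of sites, recorded in the result.
#' @return a `gini_result`: list with `gini`, `n_sites`, `classification`
#'   (`"low"` or `"not_low"`) and `threshold`.
#' @export
classify_inequality <- function(gini, threshold = 0.2, n_sites = NA_integer_) {
  if (!is.numeric(gini) || length(gini) != 1 || is.na(gini) ||
      gini < 0 || gini >= 1)
    abort_domain("gini must be a single number in [0, 1)")
  structure(list(gini = gini, n_sites = as.integer(n_sites),
                 classification = if (gini < threshold) "low" else "not_low",
                 threshold = threshold),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("Gini coefficient %.4f across %s sites: %s accrual inequality (threshold %.2f)\n",
              x$gini, ifelse(is.na(x$n_sites), "?", x$n_sites),
              ifelse(x$classification == "low", "low", "not low"), x$threshold))
  invisible(x)
}

#' Gini accrual-inequality assessment for a set of site totals
#'
#' Convenience wrapper: computes [gini_coefficient()] and classifies it with
#' [classify_inequality()].
#'
#' @inheritParams gini_coefficient
#' @inheritParams classify_inequality
#' @return a `gini_result`.
#' @export
accrual_inequality <- function(counts, threshold = 0.2) {
  classify_inequality(gini_coefficient(counts), threshold = threshold,
                      n_sites = length(counts))
}

#' Fit the Poisson-gamma accrual model
#'
#' Conjugate update for a homogeneous-Poisson enrollment process: with a
#' Gamma(`prior_shape`, `prior_rate`) prior on the daily enrollment rate,
#' the posterior after observing the events in `[start, as_of]` is
#' Gamma(`prior_shape + n`, `prior_rate + t`) where `n` is the event count
#' and `t` the exposure in days. The default prior (0.001, 0.001) is vague,
#' so the forecast is dominated by the observed accrual.
#'
#' @param events enrollment events data frame (columns `site_id`, `date`).
#' @param start exposure start date (typically first site activation).
#' @param as_of end of the observation window; must not precede `start`.
#' @param prior_shape,prior_rate positive Gamma prior parameters.
#' @return an `accrual_posterior`: list with `shape`, `rate`, `n_observed`,
#'   `exposure_days`.
#' @export
fit_accrual_model <- function(events, start, as_of,
                              prior_shape = 0.001, prior_rate = 0.001) {
  start <- as.Date(start); as_of <- as.Date(as_of)
  if (as_of < start) abort_precondition("as_of precedes start")
  if (!is.numeric(prior_shape) || !is.numeric(prior_rate) ||
      prior_shape <= 0 || prior_rate <= 0)
    abort_domain("prior_shape and prior_rate must be positive")
  dates <- as.Date(events$date)
  n <- sum(!is.na(dates) & dates >= start & dates <= as_of)
  t <- as.numeric(as_of - start)
  structure(list(shape = prior_shape + n, rate = prior_rate + t,
                 n_observed = as.integer(n), exposure_days = t),
            class = "accrual_posterior")
}

#' @export
print.accrual_posterior <- function(x, ...) {
  cat(sprintf("<accrual_posterior> Gamma(shape=%.4g, rate=%.4g): %d events / %.0f days; posterior mean rate %.4g/day\n",
              x$shape, x$rate, x$n_observed, x$exposure_days, x$shape / x$rate))
  invisible(x)
}

#' Posterior-predictive completion-date forecast
#'
#' Monte Carlo forecast of the date on which cumulative enrollment reaches
#' `target_n`. Each draw samples a daily rate `lambda` from the Gamma
#' posterior, then a remaining enrollment time from
#' Gamma(`target_n - enrolled_so_far`, `lambda`) (the sum of the remaining
#' exponential waiting times). The point forecast is the posterior-predictive
#' median; `pi_low`/`pi_high` are the central 95% prediction interval. Days
#' are rounded to whole days with ties to the later day. If the target is
#' already met all three dates equal `as_of`.
#'
#' @param posterior an `accrual_posterior` from [fit_accrual_model()].
#' @param enrolled_so_far participants enrolled as of `as_of`.
#' @param target_n total enrollment target (>= 1).
#' @param as_of forecast origin date.
#' @param n_draws Monte Carlo draws (>= 1000; default 20000).
#' @param seed integer seed; the forecast is deterministic given it.
#' @return an `accrual_prediction`: list with `target_n`, `as_of`,
#'   `predicted_completion`, `pi_low`, `pi_high` (Dates), `n_draws`, `seed`,
#'   and the raw `draws` of completion dates for plotting.
#' @examples
#' post <- structure(list(shape = 1e6, rate = 2e6, n_observed = 0L,
#'                        exposure_days = 1), class = "accrual_posterior")
#' predict_completion(post, 1000, 1100, as.Date("2020-06-01"), 2000, seed = 1)
#' @export
predict_completion <- function(posterior, enrolled_so_far, target_n, as_of,
                               n_draws = 20000, seed = 1L) {
  as_of <- as.Date(as_of)
  if (target_n < 1) abort_precondition("target_n must be >= 1")
  if (n_draws < 1000) abort_precondition("n_draws must be >= 1000")
  if (!inherits(posterior, "accrual_posterior") ||
      posterior$shape <= 0 || posterior$rate <= 0)
    abort_domain("posterior must have positive shape and rate")
  remaining <- target_n - enrolled_so_far
  if (remaining <= 0) {
    return(structure(list(target_n = as.integer(target_n), as_of = as_of,
                          predicted_completion = as_of, pi_low = as_of,
                          pi_high = as_of, n_draws = as.integer(n_draws),
                          seed = as.integer(seed), draws = rep(as_of, 0)),
                     class = "accrual_prediction"))
  }
  days <- with_seed(seed, {
    lambda <- stats::rgamma(n_draws, shape = posterior$shape,
                            rate = posterior$rate)
    stats::rgamma(n_draws, shape = remaining, rate = lambda)
  })
  qs <- stats::quantile(days, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  dts <- as_of + round_half_up(qs)
  structure(list(target_n = as.integer(target_n), as_of = as_of,
                 predicted_completion = dts[2], pi_low = dts[1],
                 pi_high = dts[3], n_draws = as.integer(n_draws),
                 seed = as.integer(seed), draws = as_of + days),
            class = "accrual_prediction")
}

#' @export
print.accrual_prediction <- function(x, ...) {
  cat(sprintf("<accrual_prediction> target n=%d as of %s\n", x$target_n,
              format(x$as_of)))
  cat(sprintf("  predicted completion %s (95%% PI %s to %s; %d draws, seed %d)\n",
              format(x$predicted_completion), format(x$pi_low),
              format(x$pi_high), x$n_draws, x$seed))
  invisible(x)
}

#' Per-site completion forecasts
#'
#' Convenience wrapper fitting one Poisson-gamma model per site (exposure
#' starting at each site's activation date) and forecasting each site's own
#' target.
#'
#' @param ds a `trial_dataset`
#' @param as_of forecast origin date
#' @param site_targets named vector site_id -> target enrollment
#' @inheritParams predict_completion
#' @return named list of `accrual_prediction` objects, one per site.
#' @export
predict_completion_by_site <- function(ds, as_of, site_targets,
                                       n_draws = 20000, seed = 1L,
                                       prior_shape = 0.001, prior_rate = 0.001) {
  out <- lapply(names(site_targets), function(sid) {
    ev <- ds$enrollment[ds$enrollment$site_id == sid, , drop = FALSE]
    start <- ds$sites$activation_date[match(sid, ds$sites$site_id)]
    post <- fit_accrual_model(ev, start, as_of, prior_shape, prior_rate)
    predict_completion(post, nrow(ev), site_targets[[sid]], as_of,
                       n_draws = n_draws, seed = seed)
  })
  names(out) <- names(site_targets)
  out
}

#' Plot the posterior-predictive completion distribution
#'
#' Histogram of the Monte Carlo completion-date draws with the median
#' forecast, the 95% prediction interval, and (optionally) the study
#' deadline marked as a red reference line.
#'
#' @param prediction an `accrual_prediction` with draws.
#' @param deadline optional Date drawn as a red vertical line.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the prediction.
#' @export
plot_completion_forecast <- function(prediction, deadline = NULL, ...) {
  if (length(prediction$draws) == 0) {
    graphics::plot.new()
    graphics::title(main = "Enrollment target already reached")
    return(invisible(prediction))
  }
  graphics::hist(prediction$draws, breaks = 50, freq = FALSE,
                 col = "grey85", border = "grey60",
                 main = "Posterior-predictive completion date",
                 xlab = "Completion date", ...)
  graphics::abline(v = as.numeric(prediction$predicted_completion), lwd = 2)
  graphics::abline(v = as.numeric(c(prediction$pi_low, prediction$pi_high)),
                   lty = 2)
  if (!is.null(deadline))
    graphics::abline(v = as.numeric(as.Date(deadline)), col = "red", lwd = 2)
  invisible(prediction)
}
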