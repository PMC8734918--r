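# Shared helpers: date handling, rounding, seeded RNG scoping.

#' Round to the nearest integer, ties away from zero (upward for positives)
#'
#' Base `round()` rounds half to even; completion dates and whole-percent
#' metrics round ties to the later day / larger value instead.
#' @param x numeric vector
#' @return numeric vector of integers
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

# Parse "YYYY-MM-DD" strictly; impossible dates (2021-02-30) come back NA.
parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- as.Date(x[ok], format = "%Y-%m-%d")
  # as.Date() rolls nothing: invalid component combinations give NA already
  out[ok] <- d
  out
}

is_valid_iso_date_string <- function(x) {
  !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x) &
    !is.na(as.Date(x, format = "%Y-%m-%d"))
}

first_of_month <- function(d) as.Date(format(d, "%Y-%m-01"))

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable integer sequence formatter for generated keys
seq_ids <- function(prefix, n, start = 1L, width = 5L) {
  if (n == 0L) return(character(0))
  sprintf(paste0(prefix, "%0", width, "d"), seq.int(start, length.out = n))
}
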