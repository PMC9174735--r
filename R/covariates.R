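#' Hierarchy stability index
#'
#' A \[0, 1\] score of how little the ordinal rank order changes over a time
#' window ending at `date`. For each pair of consecutive days in the window
#' the fraction of male dyads whose rank order flips between the two days is
#' computed (restricted to males present on both days); the index is one
#' minus the mean of these fractions, so 1 means ordinal ranks never changed
#' and 0 means complete daily reversal. Depending only on ranks, it is
#' invariant under strictly monotone rating transforms.
#'
#' @param traj an [elo_trajectories()] object.
#' @param group group id.
#' @param date window end date.
#' @param window window length in days (default 30, i.e. 29 day pairs).
#' @return stability index in \[0, 1\].
#' @export
stability_index <- function(traj, group, date, window = 30) {
  date <- assert_date(date, "date")
  p <- traj$presence
  start <- date - (window - 1)
  first <- min(p$entry[p$group == group])
  if (start < first) {
    warning(sprintf("stability window truncated to start of data (%s)",
                    format(first)))
    start <- first
  }
  days <- seq(start, date, by = "day")
  if (length(days) < 2) {
    abort("stability window has fewer than 2 days", "coalrank_covariate_error")
  }
  rank_on <- function(d) {
    res <- p$group == group & p$entry <= d & p$exit >= d
    males <- p$male[res]
    if (length(males) < 2) return(NULL)
    r <- rating_at(traj, males, rep(d, length(males)))
    stats::setNames(rank(r, ties.method = "first"), males)
  }
  ranks <- lapply(days, rank_on)
  fracs <- vapply(seq_len(length(days) - 1), function(i) {
    r1 <- ranks[[i]]; r2 <- ranks[[i + 1]]
    if (is.null(r1) || is.null(r2)) return(NA_real_)
    common <- intersect(names(r1), names(r2))
    n <- length(common)
    if (n < 2) return(NA_real_)
    a <- r1[common]; b <- r2[common]
    pairs <- utils::combn(n, 2)
    inv <- sum(sign(a[pairs[1, ]] - a[pairs[2, ]]) !=
                 sign(b[pairs[1, ]] - b[pairs[2, ]]))
    inv / (n * (n - 1) / 2)
  }, numeric(1))
  if (all(is.na(fracs))) {
    abort(sprintf("fewer than 2 co-resident males throughout window in %s",
                  group), "coalrank_covariate_error")
  }
  1 - mean(fracs, na.rm = TRUE)
}

#' Male competition index
#'
#' Number of co-resident adult males in the group on a date (the simplest
#' reading of male competition; a step function changing only at entry and
#' exit dates). When `min_age` is given and birth dates are available, only
#' males at least that old are counted.
#'
#' @param presence presence table (`male`, `group`, `entry`, `exit`,
#'   optionally `birth_date`).
#' @param group group id.
#' @param date reference date.
#' @param min_age optional minimum age in years.
#' @return integer headcount.
#' @export
competition_index <- function(presence, group, date, min_age = NULL) {
  date <- assert_date(date, "date")
  res <- presence$group == group & presence$entry <= date &
    presence$exit >= date
  if (!is.null(min_age) && "birth_date" %in% names(presence)) {
    age <- as.numeric(date - as.Date(presence$birth_date)) / 365.25
    res <- res & !is.na(age) & age >= min_age
  }
  n <- sum(res)
  if (n < 1) {
    abort(sprintf("no adult male present in %s on %s", group, format(date)),
          "coalrank_covariate_error")
  }
  n
}

#' Focal aggression rate
#'
#' Aggressive events per focal hour for a male over a window ending at
#' `date`. Zero observation effort yields a flagged missing value, never a
#' zero rate.
#'
#' @param focal focal-effort table (`male`, `date`, `duration_min`,
#'   `n_aggressive_events`).
#' @param male male id.
#' @param date window end date.
#' @param window window length in days (default 30).
#' @return events per hour, or `NA` (with a warning) when effort is zero.
#' @export
aggression_rate <- function(focal, male, date, window = 30) {
  assert_cols(focal, c("male", "date", "duration_min", "n_aggressive_events"),
              "focal")
  date <- assert_date(date, "date")
  fd <- assert_date(focal$date, "focal date")
  sel <- focal$male == male & fd > date - window & fd <= date
  hours <- sum(focal$duration_min[sel]) / 60
  if (hours <= 0) {
    warning(sprintf("zero focal effort for %s in window ending %s",
                    male, format(date)))
    return(NA_real_)
  }
  sum(focal$n_aggressive_events[sel]) / hours
}

#' Age in years on a date
#'
#' @param presence presence table with a `birth_date` column.
#' @param male male id.
#' @param date reference date.
#' @return age in years (`(date - birth) / 365.25`), or `NA` with a warning
#'   when the birth date is unknown.
#' @export
age_at <- function(presence, male, date) {
  date <- assert_date(date, "date")
  i <- match(male, presence$male)
  if (is.na(i)) abort(sprintf("unknown male id: %s", male),
                      "coalrank_lookup_error")
  bd <- presence$birth_date[i]
  if (is.null(bd) || is.na(bd)) {
    warning(sprintf("missing birth date for %s", male))
    return(NA_real_)
  }
  as.numeric(date - as.Date(bd)) / 365.25
}
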