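#' Elo-rating parameters
#'
#' Parameters of the sequential Elo-rating system used to score individual
#' dominance strength. After each decided contest the winner gains
#' \eqn{k (1 - E(R_w - R_l))} rating points and the loser loses the same
#' amount, where \eqn{E} maps the pre-contest rating difference to the
#' winner's expected success.
#'
#' Two expected-score functions are provided. `"logistic-400"` is the chess
#' convention, \eqn{E(d) = 1 / (1 + 10^{-d/400})}. `"normal-cdf"` is the
#' variant common in the animal-dominance literature,
#' \eqn{E(d) = \Phi(d / (200\sqrt{2}))}. Both satisfy \eqn{E(0) = 0.5} and
#' \eqn{E(d) + E(-d) = 1}.
#'
#' @param start_value rating assigned to a male on entry (default 1000).
#' @param k maximum points exchanged per contest (default 100, a common
#'   choice for macaque hierarchies, where single contests are informative).
#' @param expected_score `"logistic-400"` or `"normal-cdf"`.
#' @return an object of class `elo_params`.
#' @export
elo_params <- function(start_value = 1000, k = 100,
                       expected_score = c("logistic-400", "normal-cdf")) {
  expected_score <- match.arg(expected_score)
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    abort("'k' must be a single positive number", "coalrank_config_error")
  }
  structure(list(start_value = start_value, k = k,
                 expected_score = expected_score),
            class = "elo_params")
}

expected_score_fun <- function(params) {
  switch(params$expected_score,
         "logistic-400" = function(d) 1 / (1 + 10^(-d / 400)),
         "normal-cdf"   = function(d) stats::pnorm(d / (200 * sqrt(2))))
}

#' Compute sequential Elo-rating trajectories
#'
#' Processes decided dyadic agonistic interactions in chronological order
#' (stable input order within a day) and returns each male's full rating
#' trajectory. Newly present males are initialized at `start_value` on their
#' entry date. Coalition events are not Elo inputs; only dyadic agonism
#' updates ratings, so future ratings are never mechanically coupled to the
#' coalition predictors built from them.
#'
#' @param interactions data.frame with columns `date`, `group`, `winner`,
#'   `loser` — one decided contest per row.
#' @param presence data.frame with columns `male`, `group`, `entry`, `exit`
#'   (and optionally `birth_date`).
#' @param params an [elo_params()] object.
#' @return an object of class `elo_trajectories`: the update log plus
#'   presence and parameters, consumed by [rating_at()], [future_ratings()]
#'   and [standardize_ratings()].
#' @export
#' @examples
#' pres <- data.frame(male = c("a", "b"), group = "G1",
#'                    entry = as.Date("2020-01-01"),
#'                    exit = as.Date("2020-12-31"))
#' ints <- data.frame(date = as.Date("2020-02-01"), group = "G1",
#'                    winner = "a", loser = "b")
#' tr <- elo_trajectories(ints, pres)
#' rating_at(tr, c("a", "b"), as.Date("2020-03-01"))  # 1050, 950
elo_trajectories <- function(interactions, presence, params = elo_params()) {
  assert_cols(presence, c("male", "group", "entry", "exit"), "presence")
  presence$entry <- assert_date(presence$entry, "entry")
  presence$exit <- assert_date(presence$exit, "exit")
  if (anyDuplicated(presence$male)) {
    abort("presence must have one row per male", "coalrank_data_error")
  }

  n_int <- nrow(interactions)
  if (n_int > 0) {
    assert_cols(interactions, c("date", "winner", "loser"), "interactions")
    interactions$date <- assert_date(interactions$date, "date")
    bad <- which(interactions$winner == interactions$loser)
    if (length(bad)) {
      abort(sprintf("winner equals loser in interaction row(s): %s",
                    paste(utils::head(bad, 5), collapse = ", ")),
            "coalrank_data_error")
    }
    for (side in c("winner", "loser")) {
      m <- match(interactions[[side]], presence$male)
      if (anyNA(m)) {
        abort(sprintf("%s id absent from presence table (first bad row %d)",
                      side, which(is.na(m))[1]), "coalrank_data_error")
      }
      out <- interactions$date < presence$entry[m] |
        interactions$date > presence$exit[m]
      if (any(out)) {
        abort(sprintf("interaction outside %s's presence in row(s): %s",
                      side, paste(utils::head(which(out), 5), collapse = ", ")),
              "coalrank_data_error")
      }
    }
    # chronological, stable within day (recorded order stands in for time)
    ord <- order(as.integer(interactions$date), seq_len(n_int))
    interactions <- interactions[ord, , drop = FALSE]
  }

  males <- presence$male
  efun <- expected_score_fun(params)
  ratings <- stats::setNames(rep(params$start_value, length(males)), males)

  n_rec <- length(males) + 2L * n_int
  rec_male <- character(n_rec)
  rec_date <- rep(as.Date(NA), n_rec)
  rec_rating <- numeric(n_rec)
  rec_male[seq_along(males)] <- males
  rec_date[seq_along(males)] <- presence$entry
  rec_rating[seq_along(males)] <- params$start_value
  j <- length(males)

  if (n_int > 0) {
    w_idx <- match(interactions$winner, males)
    l_idx <- match(interactions$loser, males)
    for (i in seq_len(n_int)) {
      rw <- ratings[[w_idx[i]]]
      rl <- ratings[[l_idx[i]]]
      delta <- params$k * (1 - efun(rw - rl))
      ratings[[w_idx[i]]] <- rw + delta
      ratings[[l_idx[i]]] <- rl - delta
      rec_male[j + 1L] <- interactions$winner[i]
      rec_male[j + 2L] <- interactions$loser[i]
      rec_date[j + 1L] <- interactions$date[i]
      rec_date[j + 2L] <- interactions$date[i]
      rec_rating[j + 1L] <- rw + delta
      rec_rating[j + 2L] <- rl - delta
      j <- j + 2L
    }
  }

  updates <- data.frame(male = rec_male, date = rec_date, rating = rec_rating,
                        stringsAsFactors = FALSE)
  # per-male lookup tables in event order (last record on a date is current)
  by_male <- lapply(split(seq_len(n_rec), updates$male), function(ix) {
    list(dates = as.integer(updates$date[ix]), ratings = updates$rating[ix])
  })

  structure(list(updates = updates, by_male = by_male, presence = presence,
                 params = params),
            class = "elo_trajectories")
}

#' @export
print.elo_trajectories <- function(x, ...) {
  cat(sprintf(
    "<elo_trajectories> %d males, %d updates, k = %g, start = %g, E = %s\n",
    nrow(x$presence), nrow(x$updates) - nrow(x$presence),
    x$params$k, x$params$start_value, x$params$expected_score))
  invisible(x)
}

presence_row <- function(traj, male) {
  i <- match(male, traj$presence$male)
  if (anyNA(i)) {
    abort(sprintf("unknown male id: %s",
                  paste(male[is.na(i)], collapse = ", ")),
          "coalrank_lookup_error")
  }
  i
}

#' Extract ratings on a date (carry-forward)
#'
#' Returns the last updated rating on or before `date` for each male; before
#' any contest this is the start value. On a day with interactions the value
#' is the post-update rating after all of that day's contests.
#'
#' @param traj an [elo_trajectories()] object.
#' @param male character vector of male ids.
#' @param date Date vector (recycled against `male`).
#' @return numeric vector of ratings.
#' @export
rating_at <- function(traj, male, date) {
  date <- assert_date(date, "date")
  n <- max(length(male), length(date))
  male <- rep_len(male, n)
  date <- rep_len(date, n)
  i <- presence_row(traj, male)
  out_of_presence <- date < traj$presence$entry[i] | date > traj$presence$exit[i]
  if (any(out_of_presence)) {
    abort(sprintf("date outside presence for male(s): %s",
                  paste(unique(male[out_of_presence]), collapse = ", ")),
          "coalrank_lookup_error")
  }
  vapply(seq_len(n), function(q) {
    tab <- traj$by_male[[male[q]]]
    k <- findInterval(as.integer(date[q]), tab$dates)
    tab$ratings[[k]]
  }, numeric(1))
}

#' Future ratings at fixed offsets after an event
#'
#' Extracts a male's ratings at offsets 0, `step`, ..., `horizon` days after
#' `event_date` (defaults: 10-day increments up to 120 days, i.e. 12 future
#' time points plus day 0). Offsets falling after the male has left the
#' group are marked absent, never imputed.
#'
#' @param traj an [elo_trajectories()] object.
#' @param male a single male id.
#' @param event_date event date (within the male's presence).
#' @param step offset increment in days.
#' @param horizon maximum offset in days.
#' @return data.frame with columns `offset`, `date`, `present`, `rating`
#'   (`NA` where absent).
#' @export
future_ratings <- function(traj, male, event_date, step = 10, horizon = 120) {
  if (step <= 0 || horizon < step) {
    abort("'step' must be > 0 and 'horizon' >= 'step'",
          "coalrank_config_error")
  }
  event_date <- assert_date(event_date, "event_date")
  i <- presence_row(traj, male)
  if (event_date < traj$presence$entry[i] || event_date > traj$presence$exit[i]) {
    abort(sprintf("event_date outside presence of %s", male),
          "coalrank_lookup_error")
  }
  offsets <- seq(0, horizon, by = step)
  dates <- event_date + offsets
  present <- dates <= traj$presence$exit[i]
  rating <- rep(NA_real_, length(offsets))
  if (any(present)) {
    rating[present] <- rating_at(traj, rep(male, sum(present)), dates[present])
  }
  data.frame(offset = offsets, date = dates, present = present,
             rating = rating)
}

#' Standardize ratings among co-resident males
#'
#' Min–max rescaling of the Elo ratings of all males present in a group on a
#' date: the highest rating maps to 1 and the lowest to 0. This is the scale
#' on which coalition feasibility is computed and on which conception-window
#' ratings enter the paternity model.
#'
#' @param traj an [elo_trajectories()] object.
#' @param group group id.
#' @param date reference date.
#' @return data.frame with columns `male`, `rating`, `s` (standardized, in
#'   \[0, 1\]), one row per co-resident male.
#' @export
standardize_ratings <- function(traj, group, date) {
  date <- assert_date(date, "date")
  p <- traj$presence
  res <- p$group == group & p$entry <= date & p$exit >= date
  males <- p$male[res]
  if (length(males) < 2) {
    abort(sprintf("standardization needs >= 2 co-resident males in %s on %s",
                  group, format(date)),
          "coalrank_standardization_error")
  }
  r <- rating_at(traj, males, rep(date, length(males)))
  rng <- range(r)
  if (rng[1] == rng[2]) {
    abort(sprintf("degenerate rating range in %s on %s (all equal)",
                  group, format(date)),
          "coalrank_standardization_error")
  }
  data.frame(male = males, rating = r, s = (r - rng[1]) / (rng[2] - rng[1]),
             stringsAsFactors = FALSE)
}

#' Daily long-format ratings for export
#'
#' Expands trajectories to one row per male and presence day, for plotting
#' and audit.
#'
#' @param traj an [elo_trajectories()] object.
#' @return data.frame with columns `male`, `group`, `date`, `rating`.
#' @export
daily_ratings <- function(traj) {
  p <- traj$presence
  out <- lapply(seq_len(nrow(p)), function(i) {
    dates <- seq(p$entry[i], p$exit[i], by = "day")
    data.frame(male = p$male[i], group = p$group[i], date = dates,
               rating = rating_at(traj, rep(p$male[i], length(dates)), dates),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
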