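#' Assemble the event x male x future-offset rank table
#'
#' For every coalition event, every involved male contributes one row per
#' future offset (10, 20, ..., 120 days by default) while he remains
#' resident; offsets after emigration are dropped, not imputed. The response
#' is the raw Elo rating at the future date; the day-0 rating enters only as
#' the "current rank" control, never as a response. All numeric predictors
#' get z-scored copies (suffix `_z`) computed on the assembled table, so
#' model predictions at 0 are predictions at the mean.
#'
#' @param coalitions long-format coalition table (`event_id`, `date`,
#'   `group`, `male`, `role`).
#' @param traj an [elo_trajectories()] object.
#' @param focal optional focal-effort table for the aggression-rate control.
#' @param step,horizon future-offset grid in days (defaults 10 and 120:
#'   twelve future time points per event).
#' @param stability_window window for the hierarchy stability index (days).
#' @return data.frame, one row per (event, male, available offset), with raw
#'   and z-scored predictors. Events whose day-0 ratings cannot be computed
#'   are excluded with a message.
#' @export
build_rank_dataset <- function(coalitions, traj, focal = NULL, step = 10,
                               horizon = 120, stability_window = 30) {
  schema <- data.frame(
    event_id = character(), male = character(), role = character(),
    configuration = character(), feasibility = numeric(),
    days_since = numeric(), response = numeric(), group = character(),
    rank0 = numeric(), age = numeric(), aggr_rate = numeric(),
    stability = numeric(), competition = numeric(),
    stringsAsFactors = FALSE)
  if (nrow(coalitions) == 0) return(finish_rank_dataset(schema))

  # per-event metrics; events without computable day-0 ratings are excluded
  metric_list <- lapply(split(coalitions, coalitions$event_id), function(ev) {
    tryCatch(coalition_metrics(ev, traj), coalrank_error = function(e) {
      message(sprintf("excluding event %s: %s", ev$event_id[1],
                      conditionMessage(e)))
      NULL
    })
  })
  metrics <- do.call(rbind, metric_list[!vapply(metric_list, is.null,
                                                logical(1))])
  if (is.null(metrics) || nrow(metrics) == 0) {
    return(finish_rank_dataset(schema))
  }
  metrics <- metrics[order(metrics$date, metrics$event_id), , drop = FALSE]
  offsets <- seq(step, horizon, by = step)
  rows <- list()
  for (e in seq_len(nrow(metrics))) {
    ev <- metrics[e, ]
    members <- coalitions[coalitions$event_id == ev$event_id, ]
    stab <- suppressWarnings(
      stability_index(traj, ev$group, ev$date, stability_window))
    comp <- competition_index(traj$presence, ev$group, ev$date)
    for (m in seq_len(nrow(members))) {
      male <- members$male[m]
      fut <- future_ratings(traj, male, ev$date, step = step,
                            horizon = horizon)
      fut <- fut[fut$offset > 0 & fut$present, , drop = FALSE]
      if (nrow(fut) == 0) next
      aggr <- if (is.null(focal)) NA_real_ else suppressWarnings(
        aggression_rate(focal, male, ev$date, stability_window))
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = ev$event_id, male = male, role = members$role[m],
        configuration = ev$configuration, feasibility = ev$feasibility,
        days_since = fut$offset, response = fut$rating, group = ev$group,
        rank0 = rating_at(traj, male, ev$date),
        age = suppressWarnings(age_at(traj$presence, male, ev$date)),
        aggr_rate = aggr, stability = stab, competition = comp,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(finish_rank_dataset(schema))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  finish_rank_dataset(out)
}

finish_rank_dataset <- function(out) {
  out$role <- factor(out$role, levels = c("participant", "target"))
  out$configuration <- factor(out$configuration,
                              levels = c("all-down", "bridging", "all-up"))
  out$feasibility_z <- zscore(out$feasibility)
  out$days_z <- zscore(out$days_since)
  out$rank0_z <- zscore(out$rank0)
  out$age_z <- zscore(out$age)
  out$aggr_z <- zscore(out$aggr_rate)
  out$stability_z <- zscore(out$stability)
  out$competition_z <- zscore(out$competition)
  out
}

#' Assemble the conception-window paternity table
#'
#' One row per candidate male and infant. Candidates are the males present
#' on at least one day of the window (default 11 days, centred on the most
#' likely conception date); each candidate's rating is the mean of his daily
#' standardized ratings over the days he was present. `sired` is 1 for the
#' recorded sire. Conception events are analysed individually, never pooled
#' into aggregated time blocks.
#'
#' @param conceptions table (`infant`, `group`, `conception_date`, `sire`;
#'   `sire` may be `NA` when unassigned).
#' @param traj an [elo_trajectories()] object.
#' @param window window length in days; must be odd.
#' @param stability_window window for the group-level controls (days).
#' @return data.frame with raw `rating` (standardized \[0, 1\] scale, the
#'   scale of the reported slope) plus z-scored controls.
#' @export
build_paternity_dataset <- function(conceptions, traj, window = 11,
                                    stability_window = 30) {
  if (window %% 2 == 0) {
    abort("'window' must be odd (centred on the conception date)",
          "coalrank_config_error")
  }
  assert_cols(conceptions, c("infant", "group", "conception_date"),
              "conceptions")
  conceptions$conception_date <- assert_date(conceptions$conception_date,
                                             "conception_date")
  half <- (window - 1) / 2
  p <- traj$presence
  rows <- list()
  for (j in seq_len(nrow(conceptions))) {
    cc <- conceptions[j, ]
    wdays <- cc$conception_date + (-half):half
    in_win <- p$group == cc$group & p$entry <= max(wdays) &
      p$exit >= min(wdays)
    cand <- p$male[in_win]
    if (!length(cand)) {
      abort(sprintf("no candidate males for infant %s (window %s +/- %d)",
                    cc$infant, format(cc$conception_date), half),
            "coalrank_data_error")
    }
    smat <- matrix(NA_real_, nrow = length(cand), ncol = length(wdays),
                   dimnames = list(cand, NULL))
    for (k in seq_along(wdays)) {
      std <- tryCatch(standardize_ratings(traj, cc$group, wdays[k]),
                      coalrank_standardization_error = function(e) NULL)
      if (is.null(std)) next
      hit <- intersect(cand, std$male)
      smat[hit, k] <- std$s[match(hit, std$male)]
    }
    s_mean <- rowMeans(smat, na.rm = TRUE)
    keep <- !is.nan(s_mean)
    if (!any(keep)) {
      abort(sprintf("no computable window ratings for infant %s", cc$infant),
            "coalrank_data_error")
    }
    cand <- cand[keep]
    stab <- suppressWarnings(stability_index(traj, cc$group,
                                             cc$conception_date,
                                             stability_window))
    comp <- competition_index(p, cc$group, cc$conception_date)
    sire <- if ("sire" %in% names(cc)) cc$sire else NA_character_
    rows[[j]] <- data.frame(
      infant = cc$infant, male = cand, rating = unname(s_mean[keep]),
      sired = as.integer(!is.na(sire) & cand == sire), group = cc$group,
      age = vapply(cand, function(m) suppressWarnings(
        age_at(p, m, cc$conception_date)), numeric(1)),
      stability = stab, competition = comp, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$rating_z <- zscore(out$rating)
  out$age_z <- zscore(out$age)
  out$stability_z <- zscore(out$stability)
  out$competition_z <- zscore(out$competition)
  out
}

#' Fill the residual autocorrelation control
#'
#' Two-pass construction: given residuals from a first-pass fit of the rank
#' model (without the term), each row's autocorrelation term is the weighted
#' mean of the same male's residuals at the *other* offsets of the same
#' event, with weights proportional to `1 / (1 + |dt_i - dt_j| / 10)`. Rows
#' with no neighbours get 0. The filled column is `ac`, with z-scored copy
#' `ac_z`.
#'
#' @param rank_table table from [build_rank_dataset()].
#' @param residuals numeric vector of first-pass residuals, aligned with the
#'   rows of `rank_table`.
#' @return `rank_table` with `ac` and `ac_z` columns filled.
#' @export
add_autocorrelation_term <- function(rank_table, residuals) {
  if (length(residuals) != nrow(rank_table)) {
    abort("'residuals' must align with the rows of 'rank_table'",
          "coalrank_config_error")
  }
  key <- paste(rank_table$event_id, rank_table$male)
  ac <- numeric(nrow(rank_table))
  for (ix in split(seq_len(nrow(rank_table)), key)) {
    if (length(ix) < 2) next
    dt <- rank_table$days_since[ix]
    for (a in seq_along(ix)) {
      w <- 1 / (1 + abs(dt[a] - dt[-a]) / 10)
      ac[ix[a]] <- sum(w * residuals[ix[-a]]) / sum(w)
    }
  }
  rank_table$ac <- ac
  rank_table$ac_z <- zscore(ac)
  rank_table
}
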