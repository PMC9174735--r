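#' Validate and extract roles for a coalition event
#'
#' A coalition is simultaneous aggression by at least two participants
#' against at least one target, ending with the target fleeing. Each male in
#' an event holds exactly one role.
#'
#' @param event data.frame for a single event with columns `event_id`,
#'   `date`, `group`, `male`, `role` (`"participant"` or `"target"`), one
#'   row per involved male.
#' @param presence optional presence table; when supplied, every involved
#'   male must be resident on the event date.
#' @return named character vector mapping male id to role.
#' @export
assign_roles <- function(event, presence = NULL) {
  assert_cols(event, c("event_id", "date", "male", "role"), "event")
  id <- event$event_id[1]
  if (length(unique(event$event_id)) != 1) {
    abort("assign_roles() expects a single event", "coalrank_data_error")
  }
  if (!all(event$role %in% c("participant", "target"))) {
    abort(sprintf("event %s: roles must be 'participant' or 'target'", id),
          "coalrank_data_error")
  }
  parts <- event$male[event$role == "participant"]
  targs <- event$male[event$role == "target"]
  if (length(intersect(parts, targs))) {
    abort(sprintf("event %s: male(s) %s listed as both participant and target",
                  id, paste(intersect(parts, targs), collapse = ", ")),
          "coalrank_data_error")
  }
  if (length(parts) < 2 || length(targs) < 1) {
    abort(sprintf("event %s: need >= 2 participants and >= 1 target", id),
          "coalrank_data_error")
  }
  if (anyDuplicated(event$male)) {
    abort(sprintf("event %s: duplicated male id", id), "coalrank_data_error")
  }
  if (!is.null(presence)) {
    date <- assert_date(event$date[1], "date")
    m <- match(event$male, presence$male)
    if (anyNA(m) || any(date < presence$entry[m] | date > presence$exit[m])) {
      abort(sprintf("event %s: male(s) not resident on event date", id),
            "coalrank_data_error")
    }
  }
  stats::setNames(event$role, event$male)
}

#' Classify coalition configuration from day-0 ratings
#'
#' An event is *all-up* when every participant rates strictly below the
#' target, *all-down* when every participant rates strictly above, and
#' *bridging* otherwise. Ties between a participant and the target count as
#' "not lower" (a warning is issued), so a tie plus a lower-rated
#' participant yields bridging and a tie plus a higher-rated one all-down.
#' Classification depends only on rating order, so it is invariant under any
#' strictly monotone transform.
#'
#' @param participant_ratings numeric vector of participants' day-0 ratings.
#' @param target_rating the target's day-0 rating (for multi-target events
#'   pass the highest-rated target; see [coalition_metrics()]).
#' @return one of `"all-down"`, `"bridging"`, `"all-up"`.
#' @export
classify_configuration <- function(participant_ratings, target_rating) {
  if (anyNA(participant_ratings) || is.na(target_rating)) {
    abort("missing rating in configuration classification",
          "coalrank_data_error")
  }
  if (any(participant_ratings == target_rating)) {
    warning("participant rating tied with target; tie counts as 'not lower'")
  }
  # ties count as "not lower": tie + higher-rated partner is still all-down
  if (all(participant_ratings >= target_rating)) return("all-down")
  if (all(participant_ratings < target_rating)) return("all-up")
  "bridging"
}

#' Coalition feasibility score
#'
#' Feasibility is the sum of the participants' standardized ratings minus
#' the target's standardized rating, measured on the day of the coalition,
#' with standardization over all males present in the group that day.
#' Positive values mean the participants jointly outrank the target; only
#' all-up coalitions can have negative feasibility.
#'
#' @param participant_s numeric vector of participants' standardized ratings.
#' @param target_s the target's standardized rating.
#' @return numeric feasibility score.
#' @export
compute_feasibility <- function(participant_s, target_s) {
  if (anyNA(participant_s) || is.na(target_s)) {
    abort("missing standardized rating in feasibility computation",
          "coalrank_data_error")
  }
  sum(participant_s) - target_s
}

#' Per-event coalition metrics
#'
#' For every event: validates roles, extracts day-0 ratings (after all
#' dyadic interactions of the event day), standardizes over all co-resident
#' males, classifies the configuration and computes feasibility.
#' Multi-target events are scored against the highest-rated target and
#' flagged in the output.
#'
#' @param coalitions long-format coalition table (`event_id`, `date`,
#'   `group`, `male`, `role`).
#' @param traj an [elo_trajectories()] object built from the dyadic
#'   interactions (coalitions themselves are not rating inputs).
#' @return data.frame with one row per event: `event_id`, `date`, `group`,
#'   `configuration`, `feasibility`, `n_participants`, `n_targets`,
#'   `multi_target`, plus the target's and participants' day-0 standardized
#'   ratings (`target_s`, `participants_s` as a comma-joined string for
#'   export).
#' @export
coalition_metrics <- function(coalitions, traj) {
  assert_cols(coalitions, c("event_id", "date", "group", "male", "role"),
              "coalitions")
  coalitions$date <- assert_date(coalitions$date, "date")
  rows <- lapply(split(coalitions, coalitions$event_id), function(ev) {
    roles <- assign_roles(ev, traj$presence)
    date <- ev$date[1]
    grp <- ev$group[1]
    std <- standardize_ratings(traj, grp, date)
    s <- stats::setNames(std$s, std$male)
    if (anyNA(s[ev$male])) {
      abort(sprintf("event %s: rating missing for involved male",
                    ev$event_id[1]), "coalrank_data_error")
    }
    parts <- names(roles)[roles == "participant"]
    targs <- names(roles)[roles == "target"]
    tgt <- targs[which.max(s[targs])]  # highest-rated target for multi-target
    data.frame(
      event_id = ev$event_id[1], date = date, group = grp,
      configuration = classify_configuration(unname(s[parts]),
                                             unname(s[[tgt]])),
      feasibility = compute_feasibility(unname(s[parts]), unname(s[[tgt]])),
      n_participants = length(parts), n_targets = length(targs),
      multi_target = length(targs) > 1,
      target_s = unname(s[[tgt]]),
      participants_s = paste(signif(unname(s[parts]), 8), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$date, out$event_id), , drop = FALSE]
}

#' Configuration share table
#'
#' Counts and percentage shares of the three configurations, with
#' percentages rounded half away from zero (so 12.5% prints as 13%).
#'
#' @param configuration character vector of per-event labels.
#' @return data.frame with columns `configuration`, `n`, `percent`.
#' @export
#' @examples
#' labs <- rep(c("all-down", "bridging", "all-up"), c(88, 24, 16))
#' configuration_share_table(labs)  # 69 / 19 / 13
configuration_share_table <- function(configuration) {
  lev <- c("all-down", "bridging", "all-up")
  bad <- setdiff(unique(configuration), lev)
  if (length(bad)) {
    abort(sprintf("unknown configuration label(s): %s",
                  paste(bad, collapse = ", ")), "coalrank_data_error")
  }
  n <- as.integer(table(factor(configuration, levels = lev)))
  data.frame(configuration = lev, n = n,
             percent = round_half_up(100 * n / sum(n)))
}
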