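# Agent-based synthetic-data generator. Emulates the statistical structure
# the downstream analysis assumes (two groups, 7-18 adult males each with
# frequent migration, decided contests driven by latent strength, rare
# coalition events with transient injected rank consequences, conceptions
# whose siring odds are logit-linear in standardized rating) with known
# ground truth, so every pipeline stage is testable without field data.

resample <- function(x, n) x[sample.int(length(x), n)]

#' Population generator configuration
#'
#' @param n_groups number of social groups.
#' @param adult_males_per_group resident adult males per group (held constant
#'   by paired exit/entry migration); must lie within `male_band`.
#' @param study_days study length in days (>= 150 so 120-day horizons fit).
#' @param migration_rate per-male daily emigration probability; each exit is
#'   paired with the entry of a new identity the following day.
#' @param strength_sd SD of the between-male latent strength baseline
#'   (dimensionless strength units; the contest scale `tau` is measured in
#'   the same units).
#' @param strength_ar1 AR(1) coefficient of the within-male strength drift,
#'   in \[0, 1).
#' @param drift_frac stationary SD of the drift component as a fraction of
#'   `strength_sd`.
#' @param male_band plausibility band for `adult_males_per_group`.
#' @param start_date calendar date of study day 1.
#' @param seed integer seed; fully determines the population.
#' @return a `population_config` list.
#' @export
population_config <- function(n_groups = 2, adult_males_per_group = 12,
                              study_days = 730, migration_rate = 0.001,
                              strength_sd = 1, strength_ar1 = 0.97,
                              drift_frac = 0.3, male_band = c(7, 18),
                              start_date = as.Date("2009-03-01"), seed = 1) {
  cfg <- list(n_groups = n_groups,
              adult_males_per_group = adult_males_per_group,
              study_days = study_days, migration_rate = migration_rate,
              strength_sd = strength_sd, strength_ar1 = strength_ar1,
              drift_frac = drift_frac, male_band = male_band,
              start_date = as.Date(start_date), seed = as.integer(seed))
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid '%s': %s", field, msg),
                   "coalrank_config_error")
  }
  chk(n_groups >= 1, "n_groups", "need at least one group")
  chk(adult_males_per_group >= male_band[1] &&
        adult_males_per_group <= male_band[2],
      "adult_males_per_group",
      sprintf("must lie in [%d, %d]", male_band[1], male_band[2]))
  chk(study_days >= 150, "study_days", "must be >= 150 (120-day horizons)")
  chk(migration_rate >= 0 && migration_rate < 1, "migration_rate",
      "must be in [0, 1)")
  chk(strength_sd >= 0, "strength_sd", "must be >= 0")
  chk(strength_ar1 >= 0 && strength_ar1 < 1, "strength_ar1",
      "must be in [0, 1)")
  structure(cfg, class = "population_config")
}

#' Generate a synthetic male population
#'
#' Builds per-male contiguous presence intervals (migration implemented as
#' exit plus entry of a new identity), birth dates, and a latent strength
#' series per male: a fixed baseline drawn from
#' \eqn{N(0, \sigma^2_{strength})} plus a stationary AR(1) drift. Latent
#' strength is the generative truth behind contest outcomes; Elo ratings
#' estimated downstream are never compared against it directly in recovery
#' tests (injected effects are).
#'
#' @param cfg a [population_config()].
#' @return an object of class `coalrank_population`: `presence` (male,
#'   group, entry, exit, birth_date, plus integer day indices), `strength`
#'   (days x males matrix, `NA` outside presence), `days` (Date vector) and
#'   the config.
#' @export
generate_population <- function(cfg = population_config()) {
  if (!inherits(cfg, "population_config")) {
    abort("'cfg' must come from population_config()", "coalrank_config_error")
  }
  set.seed(child_seed(cfg$seed, "population"))
  nd <- cfg$study_days
  days <- cfg$start_date + 0:(nd - 1)

  rows <- list()
  for (g in seq_len(cfg$n_groups)) {
    gid <- sprintf("G%d", g)
    counter <- 0L
    for (slot in seq_len(cfg$adult_males_per_group)) {
      entry <- 1L
      while (entry <= nd) {
        counter <- counter + 1L
        residency <- if (cfg$migration_rate > 0) {
          stats::rgeom(1, cfg$migration_rate) + 1L
        } else nd
        exit <- min(entry + residency - 1L, nd)
        age_entry <- stats::runif(1, 8, 20)
        rows[[length(rows) + 1L]] <- data.frame(
          male = sprintf("%s_M%03d", gid, counter), group = gid,
          entry = days[entry], exit = days[exit],
          birth_date = days[entry] - round(age_entry * 365.25),
          entry_day = entry, exit_day = exit, stringsAsFactors = FALSE)
        entry <- exit + 1L
      }
    }
  }
  presence <- do.call(rbind, rows)
  rownames(presence) <- NULL

  S <- matrix(NA_real_, nrow = nd, ncol = nrow(presence),
              dimnames = list(NULL, presence$male))
  drift_sd <- cfg$drift_frac * cfg$strength_sd
  for (i in seq_len(nrow(presence))) {
    len <- presence$exit_day[i] - presence$entry_day[i] + 1L
    b <- stats::rnorm(1, 0, cfg$strength_sd)
    x <- numeric(len)
    x[1] <- stats::rnorm(1, 0, drift_sd)
    if (len > 1 && drift_sd > 0) {
      innov <- stats::rnorm(len - 1, 0,
                            drift_sd * sqrt(1 - cfg$strength_ar1^2))
      for (t in 2:len) x[t] <- cfg$strength_ar1 * x[t - 1] + innov[t - 1]
    }
    S[presence$entry_day[i]:presence$exit_day[i], i] <- b + x
  }
  structure(list(presence = presence, strength = S, days = days,
                 config = cfg),
            class = "coalrank_population")
}

#' @export
print.coalrank_population <- function(x, ...) {
  cat(sprintf("<coalrank_population> %d males, %d groups, %d days\n",
              nrow(x$presence), length(unique(x$presence$group)),
              length(x$days)))
  invisible(x)
}

presence_matrix <- function(pop) {
  p <- pop$presence
  M <- matrix(FALSE, nrow = length(pop$days), ncol = nrow(p),
              dimnames = list(NULL, p$male))
  for (i in seq_len(nrow(p))) M[p$entry_day[i]:p$exit_day[i], i] <- TRUE
  M
}

#' Simulate decided dyadic agonistic interactions
#'
#' Each co-resident dyad interacts on a given day with probability
#' `encounter_rate`; the winner is drawn with probability
#' \eqn{logistic((s_i - s_j)/\tau)} from the day's latent strengths. All
#' interactions are decided (draws are excluded at ingest in the field
#' protocol this emulates).
#'
#' @param pop a [generate_population()] object.
#' @param encounter_rate per dyad-day interaction probability.
#' @param tau contest scale in strength units (> 0); smaller values make
#'   outcomes more deterministic.
#' @param seed integer seed.
#' @return data.frame (`date`, `group`, `winner`, `loser`) sorted by date,
#'   with `tau` and `encounter_rate` attached as attributes.
#' @export
simulate_agonism <- function(pop, encounter_rate = 0.15, tau = 0.5,
                             seed = 1) {
  if (!is.numeric(tau) || tau <= 0) {
    abort("'tau' must be > 0", "coalrank_config_error")
  }
  if (encounter_rate < 0 || encounter_rate > 1) {
    abort("'encounter_rate' must be in [0, 1]", "coalrank_config_error")
  }
  set.seed(child_seed(seed, "agonism"))
  p <- pop$presence
  out <- list()
  for (gid in unique(p$group)) {
    gi <- which(p$group == gid)
    if (length(gi) < 2) next
    pairs <- utils::combn(gi, 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      lo <- max(p$entry_day[i], p$entry_day[j])
      hi <- min(p$exit_day[i], p$exit_day[j])
      if (lo > hi) next
      dd <- lo:hi
      hit <- dd[stats::runif(length(dd)) < encounter_rate]
      if (!length(hit)) next
      pw <- stats::plogis((pop$strength[hit, i] - pop$strength[hit, j]) / tau)
      iwins <- stats::runif(length(hit)) < pw
      out[[length(out) + 1L]] <- data.frame(
        day = hit, group = gid,
        winner = ifelse(iwins, p$male[i], p$male[j]),
        loser = ifelse(iwins, p$male[j], p$male[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- data.frame(date = as.Date(character()), group = character(),
                      winner = character(), loser = character())
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$day), , drop = FALSE]
    res <- data.frame(date = pop$days[res$day], group = res$group,
                      winner = res$winner, loser = res$loser,
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
  }
  attr(res, "tau") <- tau
  attr(res, "encounter_rate") <- encounter_rate
  res
}

#' Coalition generator configuration
#'
#' @param event_rate coalition events per group per day.
#' @param mix named probabilities over configurations `all-down`, `bridging`,
#'   `all-up`; must sum to 1. Defaults to the 88/24/16-in-128 mixture
#'   (0.6875 / 0.1875 / 0.125).
#' @param participant_effect transient strength gain per participant
#'   (strength units, >= 0).
#' @param target_effect transient strength loss of the target at unit
#'   feasibility modulation (strength units, >= 0).
#' @param decay_horizon days over which the perturbation decays linearly to
#'   zero (> 0).
#' @param feasibility_modulation coefficient making the target's loss
#'   increase with feasibility in all-up events (loss multiplier
#'   `max(0, 1 + feasibility_modulation * f)` for all-up, 1 otherwise).
#' @param size_p success parameter of the truncated geometric distribution
#'   of participant numbers on {2..`max_size`} (default gives mean ~ 2.2).
#' @param max_size largest participant count.
#' @return a `coalition_config` list.
#' @export
coalition_config <- function(event_rate = 0.08,
                             mix = c("all-down" = 0.6875,
                                     "bridging" = 0.1875,
                                     "all-up" = 0.125),
                             participant_effect = 0.5, target_effect = 1.0,
                             decay_horizon = 120,
                             feasibility_modulation = 0.5,
                             size_p = 0.85, max_size = 6) {
  if (!setequal(names(mix), c("all-down", "bridging", "all-up"))) {
    abort("'mix' must be named all-down, bridging, all-up",
          "coalrank_config_error")
  }
  if (abs(sum(mix) - 1) > 1e-12) {
    abort("'mix' must sum to 1", "coalrank_config_error")
  }
  if (decay_horizon <= 0) {
    abort("'decay_horizon' must be > 0", "coalrank_config_error")
  }
  if (participant_effect < 0 || target_effect < 0) {
    abort("coalition effects must be >= 0", "coalrank_config_error")
  }
  structure(list(event_rate = event_rate,
                 mix = mix[c("all-down", "bridging", "all-up")],
                 participant_effect = participant_effect,
                 target_effect = target_effect,
                 decay_horizon = decay_horizon,
                 feasibility_modulation = feasibility_modulation,
                 size_p = size_p, max_size = max_size),
            class = "coalition_config")
}

draw_coalition_size <- function(cfg, n_available) {
  kmax <- min(cfg$max_size, n_available)
  sizes <- 2:kmax
  if (length(sizes) == 1) return(sizes)
  pr <- cfg$size_p * (1 - cfg$size_p)^(sizes - 2)
  sizes[sample.int(length(sizes), 1, prob = pr)]
}

# pick target + participants among ids ordered strongest-first so that the
# drawn configuration holds in the current rating order
draw_members <- function(ordered, n_p, config) {
  n <- length(ordered)
  if (config == "all-down") {
    t_pos <- resample((n_p + 1):n, 1)
    parts <- resample(seq_len(t_pos - 1), n_p)
  } else if (config == "all-up") {
    t_pos <- resample(seq_len(n - n_p), 1)
    parts <- resample((t_pos + 1):n, n_p)
  } else {
    t_pos <- resample(2:(n - 1), 1)
    pa <- resample(seq_len(t_pos - 1), 1)
    pb <- resample((t_pos + 1):n, 1)
    pool <- setdiff(seq_len(n)[-t_pos], c(pa, pb))
    parts <- c(pa, pb, if (n_p > 2) resample(pool, n_p - 2))
  }
  list(target = ordered[t_pos], participants = ordered[parts])
}

#' Simulate coalition events and inject their rank consequences
#'
#' Replays the interaction structure (dyad, date) chronologically while
#' maintaining a running Elo rating. Coalition events arise at `event_rate`
#' per group-day (days with at least three co-resident males); the
#' configuration is drawn from `cfg$mix` and the target and participants are
#' chosen by the *current rating order* so the drawn configuration is
#' realized in the ratings a downstream analysis recomputes. From the event
#' day the target's latent strength is reduced by
#' `target_effect * g(feasibility)` and each participant's raised by
#' `participant_effect`, both decaying linearly to zero over
#' `decay_horizon` days; `g` increases with feasibility for all-up events.
#' Contest winners after an event are re-drawn under the perturbed
#' strengths, which is how injected effects reach the observable record.
#'
#' @param pop a [generate_population()] object.
#' @param interactions interaction table from [simulate_agonism()] (its
#'   dyads and dates are kept; outcomes are re-drawn under perturbation).
#' @param cfg a [coalition_config()].
#' @param elo [elo_params()] for the running rating used to select members.
#' @param seed integer seed.
#' @param tau contest scale; defaults to the value recorded by
#'   [simulate_agonism()].
#' @return list of class `coalrank_coalition_sim`: `coalitions` (long
#'   event table), `interactions` (final outcomes), `strength` (perturbed
#'   matrix), `perturbation`, and `truth` (config plus per-event injected
#'   effects).
#' @export
simulate_coalitions <- function(pop, interactions, cfg = coalition_config(),
                                elo = elo_params(), seed = 1,
                                tau = NULL) {
  tau <- tau %||% attr(interactions, "tau") %||% 0.5
  set.seed(child_seed(seed, "coalitions"))
  M <- presence_matrix(pop)
  n_days <- length(pop$days)
  males <- pop$presence$male
  groups <- unique(pop$presence$group)
  group_cols <- lapply(groups, function(g) which(pop$presence$group == g))
  names(group_cols) <- groups
  if (max(vapply(groups, function(g)
    max(rowSums(M[, group_cols[[g]], drop = FALSE])), numeric(1))) < 3) {
    abort("fewer than 3 co-resident males on every day; cannot place events",
          "coalrank_generation_error")
  }

  S <- pop$strength
  P <- matrix(0, nrow = n_days, ncol = ncol(S), dimnames = dimnames(S))
  efun <- expected_score_fun(elo)
  ratings <- stats::setNames(rep(elo$start_value, length(males)), males)

  n_int <- nrow(interactions)
  int_day <- if (n_int) as.integer(interactions$date - pop$days[1]) + 1L
             else integer()
  ai <- match(interactions$winner, males)
  bi <- match(interactions$loser, males)
  win_a <- logical(n_int)
  rows_by_day <- split(seq_len(n_int), factor(int_day, levels = 1:n_days))

  ev_rows <- list(); truth_rows <- list(); eid <- 0L
  H <- cfg$decay_horizon

  for (d in seq_len(n_days)) {
    eff <- S[d, ] + P[d, ]
    ix <- rows_by_day[[d]]
    if (length(ix)) {
      pw <- stats::plogis((eff[ai[ix]] - eff[bi[ix]]) / tau)
      win_a[ix] <- stats::runif(length(ix)) < pw
      for (r in ix) {
        wi <- if (win_a[r]) ai[r] else bi[r]
        li <- if (win_a[r]) bi[r] else ai[r]
        delta <- elo$k * (1 - efun(ratings[[wi]] - ratings[[li]]))
        ratings[[wi]] <- ratings[[wi]] + delta
        ratings[[li]] <- ratings[[li]] - delta
      }
    }
    for (g in groups) {
      if (stats::runif(1) >= cfg$event_rate) next
      pres <- group_cols[[g]][M[d, group_cols[[g]]]]
      if (length(pres) < 3) next
      r <- ratings[pres]
      if (max(r) == min(r)) next  # undifferentiated ratings: no rank order yet
      config <- sample(names(cfg$mix), 1, prob = cfg$mix)
      n_p <- draw_coalition_size(cfg, length(pres) - 1)
      ordered <- pres[order(r, decreasing = TRUE)]
      mem <- draw_members(ordered, n_p, config)
      s_std <- (r - min(r)) / (max(r) - min(r))
      names(s_std) <- males[pres]
      f <- sum(s_std[males[mem$participants]]) - s_std[[males[mem$target]]]
      g_mod <- if (config == "all-up") {
        max(0, 1 + cfg$feasibility_modulation * f)
      } else 1
      dT <- cfg$target_effect * g_mod
      dP <- cfg$participant_effect
      dd <- d:min(d + H, n_days)
      w <- pmax(0, 1 - (dd - d) / H)
      P[dd, mem$target] <- P[dd, mem$target] - dT * w
      for (pc in mem$participants) P[dd, pc] <- P[dd, pc] + dP * w
      eid <- eid + 1L
      id <- sprintf("E%04d", eid)
      ev_rows[[eid]] <- data.frame(
        event_id = id, date = pop$days[d], group = g,
        male = males[c(mem$participants, mem$target)],
        role = c(rep("participant", n_p), "target"),
        stringsAsFactors = FALSE)
      truth_rows[[eid]] <- data.frame(
        event_id = id, date = pop$days[d], group = g,
        configuration = config, n_participants = n_p,
        target = males[mem$target], feasibility = f,
        delta_target = dT, delta_participant = dP, g_mod = g_mod,
        stringsAsFactors = FALSE)
    }
  }

  final <- interactions
  if (n_int) {
    final$winner <- ifelse(win_a, males[ai], males[bi])
    final$loser <- ifelse(win_a, males[bi], males[ai])
  }
  attr(final, "tau") <- tau
  coalitions <- if (eid) do.call(rbind, ev_rows) else
    data.frame(event_id = character(), date = as.Date(character()),
               group = character(), male = character(), role = character())
  rownames(coalitions) <- NULL
  structure(list(coalitions = coalitions, interactions = final,
                 strength = S + P, perturbation = P,
                 truth = list(config = cfg,
                              events = if (eid) do.call(rbind, truth_rows)
                                       else NULL)),
            class = "coalrank_coalition_sim")
}

#' Simulate focal observation effort
#'
#' Generates focal protocols (up to 60 minutes) on random presence days,
#' with per-male aggressiveness drawn from a log-normal so aggression rates
#' vary between males.
#'
#' @param pop a [generate_population()] object.
#' @param focal_rate per-male daily probability of a focal protocol.
#' @param rate_meanlog,rate_sdlog log-normal parameters of the per-male
#'   hourly aggression rate.
#' @param seed integer seed.
#' @return data.frame (`male`, `date`, `duration_min`,
#'   `n_aggressive_events`).
#' @export
simulate_focal <- function(pop, focal_rate = 0.12, rate_meanlog = 0,
                           rate_sdlog = 0.5, seed = 1) {
  set.seed(child_seed(seed, "focal"))
  p <- pop$presence
  out <- list()
  for (i in seq_len(nrow(p))) {
    lambda <- stats::rlnorm(1, rate_meanlog, rate_sdlog)
    dd <- p$entry_day[i]:p$exit_day[i]
    hit <- dd[stats::runif(length(dd)) < focal_rate]
    if (!length(hit)) next
    dur <- stats::runif(length(hit), 20, 60)
    out[[length(out) + 1L]] <- data.frame(
      male = p$male[i], date = pop$days[hit], duration_min = round(dur, 1),
      n_aggressive_events = stats::rpois(length(hit), lambda * dur / 60),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$date, res$male), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Paternity generator configuration
#'
#' @param n_conceptions number of conception events (default 19).
#' @param candidates_per_conception candidate males per conception; `NULL`
#'   means all males present during the window.
#' @param slope true log-odds of siring per unit standardized rating
#'   (default 1.43).
#' @param intercept log-odds intercept; the default puts the expected
#'   number of sires near one per conception with 12 candidates.
#' @param male_re_sd SD of the per-male random intercept (log-odds).
#' @param window conception window length in days (odd).
#' @param n_males candidate pool size for the standalone cohort generator.
#' @return a `paternity_config` list.
#' @export
paternity_config <- function(n_conceptions = 19,
                             candidates_per_conception = 12,
                             slope = 1.43, intercept = -3,
                             male_re_sd = 0.2, window = 11, n_males = 24) {
  if (n_conceptions < 1) {
    abort("'n_conceptions' must be >= 1", "coalrank_config_error")
  }
  if (!is.null(candidates_per_conception) && candidates_per_conception < 2) {
    abort("'candidates_per_conception' must be >= 2",
          "coalrank_config_error")
  }
  if (window %% 2 == 0) {
    abort("'window' must be odd (centred on the conception date)",
          "coalrank_config_error")
  }
  structure(list(n_conceptions = n_conceptions,
                 candidates_per_conception = candidates_per_conception,
                 slope = slope, intercept = intercept,
                 male_re_sd = male_re_sd, window = window,
                 n_males = n_males),
            class = "paternity_config")
}

#' Simulate conception records from rating trajectories
#'
#' Draws conception dates, takes as candidates all males present during the
#' window (optionally subsampled to `candidates_per_conception`), computes
#' each candidate's window-mean standardized rating from the supplied
#' trajectories, and draws per-candidate sire indicators independently from
#' a Bernoulli with logit
#' \eqn{\alpha + \beta s + b_{male}}. A single-sire constraint is *not*
#' imposed: the downstream model is an unconditional binomial GLMM, and the
#' generator matches its likelihood exactly.
#'
#' @param pop a [generate_population()] object.
#' @param traj [elo_trajectories()] built from the final interaction table.
#' @param cfg a [paternity_config()].
#' @param seed integer seed.
#' @return list: `conceptions` (`infant`, `group`, `conception_date`,
#'   `sire` — first sired candidate or `NA`), `candidates` (one row per
#'   candidate x infant with `rating` and `sired`), and `truth`.
#' @export
simulate_conceptions <- function(pop, traj, cfg = paternity_config(),
                                 seed = 1) {
  set.seed(child_seed(seed, "conceptions"))
  half <- (cfg$window - 1) / 2
  nd <- length(pop$days)
  lo <- half + 60L  # leave burn-in so ratings have differentiated
  hi <- nd - half
  if (hi <= lo) abort("study too short for conception windows",
                      "coalrank_generation_error")
  groups <- unique(pop$presence$group)
  b_male <- stats::setNames(
    stats::rnorm(nrow(pop$presence), 0, cfg$male_re_sd), pop$presence$male)

  conc_days <- sort(resample(lo:hi, cfg$n_conceptions))
  conc_groups <- resample(rep(groups, length.out = cfg$n_conceptions),
                          cfg$n_conceptions)
  cand_rows <- list(); conc_rows <- list()
  for (j in seq_len(cfg$n_conceptions)) {
    date <- pop$days[conc_days[j]]
    g <- conc_groups[j]
    wdays <- pop$days[(conc_days[j] - half):(conc_days[j] + half)]
    p <- pop$presence
    in_win <- p$group == g & p$entry <= max(wdays) & p$exit >= min(wdays)
    cand <- p$male[in_win]
    if (!length(cand)) {
      abort(sprintf("no candidate males in window %s +/- %d days (%s)",
                    format(date), half, g), "coalrank_generation_error")
    }
    if (!is.null(cfg$candidates_per_conception) &&
        length(cand) > cfg$candidates_per_conception) {
      cand <- resample(cand, cfg$candidates_per_conception)
    }
    smat <- matrix(NA_real_, nrow = length(cand), ncol = length(wdays),
                   dimnames = list(cand, NULL))
    for (k in seq_along(wdays)) {
      std <- standardize_ratings(traj, g, wdays[k])
      hit <- intersect(cand, std$male)
      smat[hit, k] <- std$s[match(hit, std$male)]
    }
    s_mean <- rowMeans(smat, na.rm = TRUE)
    s_mean <- s_mean[!is.nan(s_mean)]
    cand <- names(s_mean)
    pr <- stats::plogis(cfg$intercept + cfg$slope * s_mean + b_male[cand])
    sired <- as.integer(stats::runif(length(cand)) < pr)
    infant <- sprintf("I%02d", j)
    cand_rows[[j]] <- data.frame(
      infant = infant, group = g, conception_date = date, male = cand,
      rating = unname(s_mean), sired = sired, stringsAsFactors = FALSE)
    conc_rows[[j]] <- data.frame(
      infant = infant, group = g, conception_date = date,
      sire = if (any(sired == 1)) cand[which(sired == 1)[1]] else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(conceptions = do.call(rbind, conc_rows),
       candidates = do.call(rbind, cand_rows),
       truth = list(config = cfg, male_intercepts = b_male))
}

#' Standalone paternity cohort generator
#'
#' Generates a conception cohort without the agent-based machinery, for
#' parameter-recovery studies of the paternity model: for each conception,
#' `candidates_per_conception` males are drawn from a pool of `n_males`
#' carrying persistent random intercepts, and their standardized ratings
#' are obtained by min-max rescaling of independent draws (conception
#' windows are months apart in a highly dynamic hierarchy, so
#' window ratings are treated as uncorrelated between conceptions); sire
#' indicators are Bernoulli with logit \eqn{\alpha + \beta s + b_{male}}.
#'
#' @param cfg a [paternity_config()].
#' @param seed integer seed.
#' @return data.frame (`infant`, `male`, `rating`, `sired`).
#' @export
simulate_paternity_cohort <- function(cfg = paternity_config(), seed = 1) {
  set.seed(child_seed(seed, "cohort"))
  k <- cfg$candidates_per_conception %||% 12
  if (cfg$n_males < k) {
    abort("'n_males' must be >= candidates_per_conception",
          "coalrank_config_error")
  }
  males <- sprintf("M%03d", seq_len(cfg$n_males))
  b <- stats::rnorm(cfg$n_males, 0, cfg$male_re_sd)
  rows <- lapply(seq_len(cfg$n_conceptions), function(j) {
    idx <- sample.int(cfg$n_males, k)
    latent <- stats::rnorm(k)
    s <- (latent - min(latent)) / (max(latent) - min(latent))
    pr <- stats::plogis(cfg$intercept + cfg$slope * s + b[idx])
    data.frame(infant = sprintf("I%02d", j), male = males[idx], rating = s,
               sired = as.integer(stats::runif(k) < pr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a full synthetic study
#'
#' Runs the whole generator chain — population, agonism, coalitions (with
#' effect injection and outcome re-drawing), Elo trajectories, focal effort
#' and conceptions — under a single seed, returning the five input tables
#' the pipeline consumes plus trajectories and ground truth.
#'
#' @param pop_cfg,coal_cfg,pat_cfg generator configurations.
#' @param encounter_rate,tau agonism parameters (see [simulate_agonism()]).
#' @param elo [elo_params()] used both for member selection during
#'   generation and for the returned trajectories.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return list of class `coalrank_study`: `presence`, `interactions`,
#'   `coalitions`, `focal`, `conceptions`, `candidates`, `trajectories`,
#'   `population`, `truth`.
#' @export
simulate_study <- function(pop_cfg = population_config(),
                           coal_cfg = coalition_config(),
                           pat_cfg = paternity_config(),
                           encounter_rate = 0.15, tau = 0.5,
                           elo = elo_params(), seed = 1) {
  pop_cfg$seed <- child_seed(seed, "pop")
  pop <- generate_population(pop_cfg)
  ints0 <- simulate_agonism(pop, encounter_rate, tau,
                            seed = child_seed(seed, "ago"))
  sim <- simulate_coalitions(pop, ints0, coal_cfg, elo,
                             seed = child_seed(seed, "coal"), tau = tau)
  pres <- pop$presence[, c("male", "group", "entry", "exit", "birth_date")]
  traj <- elo_trajectories(sim$interactions, pres, elo)
  focal <- simulate_focal(pop, seed = child_seed(seed, "foc"))
  conc <- simulate_conceptions(pop, traj, pat_cfg,
                               seed = child_seed(seed, "con"))
  structure(list(presence = pres, interactions = sim$interactions,
                 coalitions = sim$coalitions, focal = focal,
                 conceptions = conc$conceptions,
                 candidates = conc$candidates, trajectories = traj,
                 population = pop,
                 truth = list(coalition = sim$truth,
                              paternity = conc$truth, seed = seed)),
            class = "coalrank_study")
}
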