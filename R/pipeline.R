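# End-to-end orchestration: validated CSV input, stage-by-stage outputs,
# provenance. CSV dialect: UTF-8, comma, header row, ISO-8601 dates,
# missing values as empty fields.

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

write_table_csv <- function(df, path) {
  for (nm in names(df)) if (inherits(df[[nm]], "Date")) {
    df[[nm]] <- format(df[[nm]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

parse_date_col <- function(df, col, file, problems) {
  x <- as.Date(df[[col]], format = "%Y-%m-%d")
  bad <- which(is.na(x) & !is.na(df[[col]]))
  for (b in bad) {
    problems$add(file, b, sprintf("column '%s' is not an ISO-8601 date: %s",
                                  col, df[[col]][b]))
  }
  df[[col]] <- x
  df
}

problem_collector <- function() {
  env <- new.env()
  env$rows <- list()
  env$add <- function(file, row, rule) {
    env$rows[[length(env$rows) + 1L]] <- sprintf(
      "%s, data row %s: %s", file, row %||% "-", rule)
  }
  env
}

#' Validate the five input tables
#'
#' Reads (or takes) the standard tables — `interactions` (date, group,
#' winner, loser), `coalitions` (event_id, date, group, role, male),
#' `presence` (male, group, entry, exit, birth_date), `focal` (male, date,
#' duration_min, n_aggressive_events), `conceptions` (infant, group,
#' conception_date, sire) — checks schemas, ISO dates, and referential
#' integrity (every id appears in presence; interactions and events fall
#' inside the actors' presence intervals), and returns the tables in a
#' canonical row order so that shuffled input yields identical validated
#' output. All problems are reported together, each citing file, row and
#' rule.
#'
#' @param paths named list/vector of file paths (names as above), or a
#'   named list of already-loaded data.frames.
#' @return named list of validated tables.
#' @export
validate_inputs <- function(paths) {
  need <- c("interactions", "coalitions", "presence", "focal", "conceptions")
  miss <- setdiff(need, names(paths))
  if (length(miss)) {
    abort(sprintf("missing input table(s): %s", paste(miss, collapse = ", ")),
          "coalrank_config_error")
  }
  tabs <- lapply(need, function(nm) {
    x <- paths[[nm]]
    if (is.data.frame(x)) x else {
      if (!file.exists(x)) abort(sprintf("file not found: %s", x),
                                 "coalrank_config_error")
      read_table_csv(x)
    }
  })
  names(tabs) <- need
  pr <- problem_collector()

  schema <- list(
    interactions = c("date", "group", "winner", "loser"),
    coalitions = c("event_id", "date", "group", "role", "male"),
    presence = c("male", "group", "entry", "exit", "birth_date"),
    focal = c("male", "date", "duration_min", "n_aggressive_events"),
    conceptions = c("infant", "group", "conception_date", "sire"))
  for (nm in need) {
    mc <- setdiff(schema[[nm]], names(tabs[[nm]]))
    if (length(mc)) pr$add(nm, NULL, sprintf("missing column(s): %s",
                                             paste(mc, collapse = ", ")))
  }
  if (length(pr$rows)) {
    abort(paste(c("input validation failed:", unlist(pr$rows)),
                collapse = "\n"), "coalrank_validation_error")
  }

  tabs$presence <- parse_date_col(tabs$presence, "entry", "presence", pr)
  tabs$presence <- parse_date_col(tabs$presence, "exit", "presence", pr)
  tabs$presence <- parse_date_col(tabs$presence, "birth_date", "presence", pr)
  tabs$interactions <- parse_date_col(tabs$interactions, "date",
                                      "interactions", pr)
  tabs$coalitions <- parse_date_col(tabs$coalitions, "date", "coalitions", pr)
  tabs$focal <- parse_date_col(tabs$focal, "date", "focal", pr)
  tabs$conceptions <- parse_date_col(tabs$conceptions, "conception_date",
                                     "conceptions", pr)

  p <- tabs$presence
  bad <- which(p$entry > p$exit)
  for (b in bad) pr$add("presence", b, "entry after exit")

  check_presence <- function(tab, file, id_col, date_col) {
    m <- match(tab[[id_col]], p$male)
    for (b in which(is.na(m))) {
      pr$add(file, b, sprintf("%s '%s' absent from presence", id_col,
                              tab[[id_col]][b]))
    }
    ok <- !is.na(m) & !is.na(tab[[date_col]])
    out <- which(ok & (tab[[date_col]] < p$entry[m] |
                         tab[[date_col]] > p$exit[m]))
    for (b in out) {
      pr$add(file, b, sprintf("%s dated outside %s's presence interval",
                              date_col, tab[[id_col]][b]))
    }
  }
  check_presence(tabs$interactions, "interactions", "winner", "date")
  check_presence(tabs$interactions, "interactions", "loser", "date")
  check_presence(tabs$coalitions, "coalitions", "male", "date")
  check_presence(tabs$focal, "focal", "male", "date")

  for (b in which(tabs$interactions$winner == tabs$interactions$loser)) {
    pr$add("interactions", b, "winner equals loser")
  }
  for (b in which(!tabs$coalitions$role %in% c("participant", "target"))) {
    pr$add("coalitions", b, sprintf("invalid role '%s'",
                                    tabs$coalitions$role[b]))
  }
  for (id in unique(tabs$coalitions$event_id)) {
    ev <- tabs$coalitions[tabs$coalitions$event_id == id, ]
    if (sum(ev$role == "participant") < 2 || sum(ev$role == "target") < 1) {
      pr$add("coalitions", NULL,
             sprintf("event %s needs >= 2 participants and >= 1 target", id))
    }
  }
  sires <- tabs$conceptions$sire
  for (b in which(!is.na(sires) & !sires %in% p$male)) {
    pr$add("conceptions", b, sprintf("sire '%s' absent from presence",
                                     sires[b]))
  }
  if (length(pr$rows)) {
    abort(paste(c("input validation failed:", unlist(pr$rows)),
                collapse = "\n"), "coalrank_validation_error")
  }

  # canonical ordering: identical output regardless of input row order
  tabs$presence <- tabs$presence[order(p$male), , drop = FALSE]
  tabs$interactions <- tabs$interactions[
    do.call(order, tabs$interactions[c("date", "group", "winner", "loser")]),
    , drop = FALSE]
  tabs$coalitions <- tabs$coalitions[
    do.call(order, tabs$coalitions[c("date", "event_id", "role", "male")]),
    , drop = FALSE]
  tabs$focal <- tabs$focal[
    do.call(order, tabs$focal[c("date", "male", "duration_min")]),
    , drop = FALSE]
  tabs$conceptions <- tabs$conceptions[
    order(tabs$conceptions$conception_date, tabs$conceptions$infant),
    , drop = FALSE]
  lapply(tabs, function(t) {
    rownames(t) <- NULL
    for (a in setdiff(names(attributes(t)), c("names", "row.names", "class"))) {
      attr(t, a) <- NULL
    }
    t
  })
}

#' Pipeline configuration
#'
#' Exactly one of `inputs` (paths to the five CSV tables) or `synthetic`
#' (generator settings) must be given.
#'
#' @param synthetic list of generator settings passed to
#'   [simulate_study()]: any of `pop_cfg`, `coal_cfg`, `pat_cfg`,
#'   `encounter_rate`, `tau`. An empty list means defaults.
#' @param inputs named paths for `interactions`, `coalitions`, `presence`,
#'   `focal`, `conceptions`.
#' @param elo [elo_params()].
#' @param step,horizon future-offset grid (days).
#' @param conception_window conception window length (days, odd).
#' @param stability_window covariate window (days).
#' @param bootstrap_B bootstrap draws for the prediction bands.
#' @param autocorrelation add the two-pass residual autocorrelation control?
#' @param make_figures write the three summary figures?
#' @param seed master seed for every stochastic stage.
#' @param outdir output directory (created if needed).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, inputs = NULL,
                            elo = elo_params(), step = 10, horizon = 120,
                            conception_window = 11, stability_window = 30,
                            bootstrap_B = 1000, autocorrelation = TRUE,
                            make_figures = TRUE, seed = 1,
                            outdir = tempfile("coalrank_run_")) {
  if (is.null(synthetic) == is.null(inputs)) {
    abort("exactly one of 'synthetic' or 'inputs' must be given",
          "coalrank_config_error")
  }
  structure(list(synthetic = synthetic, inputs = inputs, elo = elo,
                 step = step, horizon = horizon,
                 conception_window = conception_window,
                 stability_window = stability_window,
                 bootstrap_B = bootstrap_B,
                 autocorrelation = autocorrelation,
                 make_figures = make_figures, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates generation (or validated ingest), Elo trajectories,
#' coalition metrics, covariates, dataset assembly, model fits,
#' likelihood-ratio tests, bootstrap prediction bands, figures and a
#' report. Every output carries the seed and full configuration; with a
#' fixed seed the numeric outputs are byte-identical across runs. Stage
#' failures name the stage; outputs already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the assembled tables, fits, LRTs,
#'   bootstrap objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("'config' must come from pipeline_config()",
          "coalrank_config_error")
  }
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- file.path(out, "config.json")
  jsonlite::write_json(
    list(seed = config$seed, step = config$step, horizon = config$horizon,
         conception_window = config$conception_window,
         stability_window = config$stability_window,
         bootstrap_B = config$bootstrap_B,
         autocorrelation = config$autocorrelation,
         elo = unclass(config$elo),
         synthetic = !is.null(config$synthetic),
         package_version = as.character(utils::packageVersion("coalrank")),
         r_version = R.version.string),
    cfg_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(config$synthetic)) {
    study <- stage("simulate", do.call(simulate_study, c(
      config$synthetic, list(elo = config$elo, seed = config$seed))))
    tabs <- list(interactions = study$interactions,
                 coalitions = study$coalitions,
                 presence = study$presence, focal = study$focal,
                 conceptions = study$conceptions)
    jsonlite::write_json(
      list(coalition = list(
             config = unclass(study$truth$coalition$config),
             events = study$truth$coalition$events),
           paternity = list(
             config = unclass(study$truth$paternity$config)),
           seed = config$seed),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    traj <- study$trajectories
  } else {
    tabs <- stage("validate", validate_inputs(config$inputs))
    traj <- NULL
  }
  for (nm in names(tabs)) {
    write_table_csv(tabs[[nm]], file.path(out, paste0(nm, ".csv")))
  }

  traj <- traj %||% stage("elo", elo_trajectories(
    tabs$interactions, tabs$presence, config$elo))
  write_table_csv(daily_ratings(traj), file.path(out, "elo_trajectories.csv"))

  if (nrow(tabs$coalitions) == 0) {
    stage("metrics", abort("no coalition events in input",
                           "coalrank_data_error"))
  }
  metrics <- stage("metrics", coalition_metrics(tabs$coalitions, traj))
  write_table_csv(metrics, file.path(out, "coalition_metrics.csv"))
  shares <- configuration_share_table(metrics$configuration)
  write_table_csv(shares, file.path(out, "configuration_shares.csv"))

  rank_tab <- stage("dataset", build_rank_dataset(
    tabs$coalitions, traj, focal = tabs$focal, step = config$step,
    horizon = config$horizon,
    stability_window = config$stability_window))
  pat_tab <- stage("dataset", build_paternity_dataset(
    tabs$conceptions, traj, window = config$conception_window,
    stability_window = config$stability_window))

  spec <- rank_model_spec()
  fits <- stage("fit", {
    if (config$autocorrelation) {
      first <- fit_rank_model(rank_tab, spec)
      # rows lost to missing controls get a neutral first-pass residual
      res <- rep(0, nrow(rank_tab))
      used <- as.integer(rownames(stats::model.frame(first$fit)))
      res[used] <- stats::residuals(first$fit)
      rank_tab <- add_autocorrelation_term(rank_tab, res)
    }
    rl <- rank_lrt(rank_tab, spec)
    pat_full <- fit_paternity_model(pat_tab)
    pat_null <- fit_paternity_model(pat_tab, include_rating = FALSE)
    list(rank = rl, paternity = list(
      full = pat_full, null = pat_null,
      lrt = likelihood_ratio_test(pat_full, pat_null)))
  })
  write_table_csv(rank_tab, file.path(out, "rank_dataset.csv"))
  write_table_csv(pat_tab, file.path(out, "paternity_dataset.csv"))
  fit_to_json(fits$rank$full, file.path(out, "fit_rank_full.json"))
  fit_to_json(fits$rank$null, file.path(out, "fit_rank_null.json"))
  fit_to_json(fits$paternity$full, file.path(out, "fit_paternity_full.json"))
  jsonlite::write_json(
    list(rank = unclass(fits$rank$lrt),
         paternity = unclass(fits$paternity$lrt)),
    file.path(out, "lrt.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  boots <- stage("bootstrap", {
    gap_grid <- role_time_grid(rank_tab, config$step, config$horizon)
    pat_grid <- paternity_grid(pat_tab)
    list(rank = bootstrap_predictions(fits$rank$full, gap_grid,
                                      B = config$bootstrap_B,
                                      seed = config$seed),
         paternity = bootstrap_predictions(fits$paternity$full, pat_grid,
                                           B = config$bootstrap_B,
                                           seed = config$seed,
                                           type = "response"))
  })
  write_table_csv(cbind(boots$rank$band),
                  file.path(out, "bootstrap_rank_band.csv"))
  write_table_csv(cbind(boots$paternity$band),
                  file.path(out, "bootstrap_paternity_band.csv"))

  if (config$make_figures) {
    stage("figures", pipeline_figures(out, fits, boots, rank_tab, pat_tab))
  }

  report <- list(seed = config$seed,
                 n_events = length(unique(metrics$event_id)),
                 configuration_shares = shares,
                 mean_participants = mean(metrics$n_participants),
                 rank_lrt = unclass(fits$rank$lrt),
                 paternity_lrt = unclass(fits$paternity$lrt),
                 paternity_slope = fits$paternity$full$coefficients$estimate[
                   fits$paternity$full$coefficients$term == "rating"])
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tables = tabs, trajectories = traj, metrics = metrics,
                 shares = shares, rank_dataset = rank_tab,
                 paternity_dataset = pat_tab, fits = fits,
                 bootstraps = boots, outdir = out))
}

role_time_grid <- function(rank_tab, step, horizon) {
  days <- seq(step, horizon, by = step)
  grid <- expand.grid(role = levels(rank_tab$role), days_since = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$role <- factor(grid$role, levels = levels(rank_tab$role))
  grid$days_z <- (grid$days_since - mean(rank_tab$days_since)) /
    stats::sd(rank_tab$days_since)
  grid$configuration <- factor(levels(rank_tab$configuration)[1],
                               levels = levels(rank_tab$configuration))
  for (v in c("feasibility_z", "rank0_z", "age_z", "aggr_z", "stability_z",
              "competition_z", "ac_z")) {
    grid[[v]] <- 0
  }
  grid$group <- sort(unique(as.character(rank_tab$group)))[1]
  grid
}

paternity_grid <- function(pat_tab) {
  grid <- data.frame(rating = seq(0, 1, length.out = 25))
  for (v in c("age_z", "stability_z", "competition_z")) grid[[v]] <- 0
  grid$male <- pat_tab$male[1]  # ignored at population level (re.form = NA)
  grid
}

pipeline_figures <- function(out, fits, boots, rank_tab, pat_tab) {
  # Fig 1 analog: predicted future rating vs feasibility by configuration
  # and role, feasibility restricted to each configuration's observed range.
  grids <- lapply(levels(rank_tab$configuration), function(cf) {
    obs <- rank_tab$feasibility_z[rank_tab$configuration == cf]
    if (!length(obs)) return(NULL)
    g <- expand.grid(role = levels(rank_tab$role),
                     feasibility_z = seq(min(obs), max(obs),
                                         length.out = 25),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g$configuration <- cf
    g
  })
  g1 <- do.call(rbind, grids[!vapply(grids, is.null, logical(1))])
  g1$role <- factor(g1$role, levels = levels(rank_tab$role))
  g1$configuration <- factor(g1$configuration,
                             levels = levels(rank_tab$configuration))
  for (v in c("days_z", "rank0_z", "age_z", "aggr_z", "stability_z",
              "competition_z", "ac_z")) {
    g1[[v]] <- 0
  }
  g1$group <- sort(unique(as.character(rank_tab$group)))[1]
  g1$pred <- stats::predict(fits$rank$full$fit, newdata = g1, re.form = NA)
  fz_mu <- mean(rank_tab$feasibility)
  fz_sd <- stats::sd(rank_tab$feasibility)
  g1$feasibility <- g1$feasibility_z * fz_sd + fz_mu
  p1 <- ggplot2::ggplot(g1, ggplot2::aes(x = .data$feasibility,
                                         y = .data$pred,
                                         colour = .data$role)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~configuration, scales = "free_x") +
    ggplot2::labs(x = "feasibility", y = "predicted future Elo rating") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out, "fig1_feasibility.pdf"), p1,
                  width = 9, height = 3.5)

  # Fig 2 analog: role x time-distance predictions with bootstrap curves
  band <- boots$rank$band
  p2 <- ggplot2::ggplot(band, ggplot2::aes(x = .data$days_since,
                                           y = .data$fit,
                                           colour = .data$role)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                      fill = .data$role),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "days since coalition",
                  y = "predicted future Elo rating") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out, "fig2_time.pdf"), p2,
                  width = 6, height = 4)

  # Fig 3 analog: siring probability vs standardized rating
  bp <- boots$paternity$band
  p3 <- ggplot2::ggplot(bp, ggplot2::aes(x = .data$rating, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_jitter(data = pat_tab,
                         ggplot2::aes(x = .data$rating, y = .data$sired),
                         width = 0, height = 0.03, alpha = 0.5) +
    ggplot2::labs(x = "standardized rating (conception window)",
                  y = "P(sire)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out, "fig3_paternity.pdf"), p3,
                  width = 6, height = 4)
  invisible(NULL)
}
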