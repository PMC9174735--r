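# Shared fixtures. Heavy simulated studies are cached across test files so
# the suite builds each condition once.

.coalrank_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .coalrank_cache)) {
    assign(key, force(expr), envir = .coalrank_cache)
  }
  get(key, envir = .coalrank_cache)
}

# study at the generator's default conditions (the conditions every
# qualitative recovery check runs under)
default_study <- function() cached("default_study", simulate_study(seed = 42))

default_rank_table <- function() cached("default_rank_table", {
  st <- default_study()
  build_rank_dataset(st$coalitions, st$trajectories, focal = st$focal)
})

default_rank_fit <- function() cached("default_rank_fit",
  suppressMessages(fit_rank_model(default_rank_table())))

# many-event study with zero injected effects (null generator)
null_study <- function() cached("null_study", simulate_study(
  pop_cfg = population_config(study_days = 600),
  coal_cfg = coalition_config(event_rate = 0.3, participant_effect = 0,
                              target_effect = 0),
  seed = 5))

toy_presence <- function(males = c("A", "B"), group = "G1",
                         entry = "2020-01-01", exit = "2020-12-31",
                         birth = "2008-06-01") {
  data.frame(male = males, group = group, entry = as.Date(entry),
             exit = as.Date(exit), birth_date = as.Date(birth),
             stringsAsFactors = FALSE)
}

toy_interaction <- function(date, winner, loser, group = "G1") {
  data.frame(date = as.Date(date), group = group, winner = winner,
             loser = loser, stringsAsFactors = FALSE)
}

# independent brute-force Elo replay used as the order-equivalence oracle
replay_rating <- function(interactions, presence, male, date, k = 100,
                          start = 1000) {
  r <- stats::setNames(rep(start, nrow(presence)), presence$male)
  ints <- interactions[order(as.integer(interactions$date),
                             seq_len(nrow(interactions))), ]
  ints <- ints[ints$date <= as.Date(date), , drop = FALSE]
  for (i in seq_len(nrow(ints))) {
    d <- r[[ints$winner[i]]] - r[[ints$loser[i]]]
    e <- 1 / (1 + 10^(-d / 400))
    r[[ints$winner[i]]] <- r[[ints$winner[i]]] + k * (1 - e)
    r[[ints$loser[i]]] <- r[[ints$loser[i]]] - k * (1 - e)
  }
  r[[male]]
}

# fixed design of realistic size for null simulation of the rank model
make_null_rank_design <- function(n_events = 128, n_males = 28, seed = 1) {
  set.seed(seed)
  males <- sprintf("M%02d", seq_len(n_males))
  rows <- lapply(seq_len(n_events), function(e) {
    mem <- sample(males, 3)
    data.frame(event_id = sprintf("E%03d", e), male = rep(mem, each = 12),
               role = rep(c("participant", "participant", "target"),
                          each = 12),
               configuration = sample(c("all-down", "bridging", "all-up"),
                                      1, prob = c(0.69, 0.19, 0.13)),
               feasibility = stats::rnorm(1),
               days_since = rep(seq(10, 120, 10), 3),
               group = sample(c("G1", "G2"), 1),
               rank0 = stats::rnorm(1, 1000, 150),
               age = stats::runif(1, 8, 20),
               aggr_rate = stats::rexp(1),
               stability = stats::runif(1, 0.8, 1),
               competition = sample(7:18, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$role <- factor(out$role, levels = c("participant", "target"))
  out$configuration <- factor(out$configuration,
                              levels = c("all-down", "bridging", "all-up"))
  out$feasibility_z <- as.numeric(scale(out$feasibility))
  out$days_z <- as.numeric(scale(out$days_since))
  out$rank0_z <- as.numeric(scale(out$rank0))
  out$age_z <- as.numeric(scale(out$age))
  out$aggr_z <- as.numeric(scale(out$aggr_rate))
  out$stability_z <- as.numeric(scale(out$stability))
  out$competition_z <- as.numeric(scale(out$competition))
  out
}

# response carrying only random structure + noise (no fixed effects)
simulate_null_response <- function(design, seed) {
  set.seed(seed)
  ev <- unique(design$event_id)
  ml <- unique(design$male)
  be <- stats::setNames(stats::rnorm(length(ev), 0, 60), ev)
  bm <- stats::setNames(stats::rnorm(length(ml), 0, 60), ml)
  1000 + be[design$event_id] + bm[design$male] +
    stats::rnorm(nrow(design), 0, 60)
}

# intercept-only random structure: the calibration spec for repeated fits
calibration_spec <- function() rank_model_spec(
  random = c("(1 | male)", "(1 | event_id)"),
  reductions = list(c("(1 | male)", "(1 | event_id)")))
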