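test_that("generation is fully deterministic under a fixed seed", {
  args <- list(pop_cfg = population_config(study_days = 200),
               coal_cfg = coalition_config(event_rate = 0.2), seed = 3)
  a <- do.call(simulate_study, args)
  b <- do.call(simulate_study, args)
  expect_identical(a$presence, b$presence)
  expect_identical(a$interactions, b$interactions)
  expect_identical(a$coalitions, b$coalitions)
  expect_identical(a$focal, b$focal)
  expect_identical(a$conceptions, b$conceptions)
  expect_identical(a$candidates, b$candidates)
})

test_that("zero noise parameters give constant strength series", {
  pop <- generate_population(population_config(strength_sd = 0,
                                               strength_ar1 = 0,
                                               study_days = 200, seed = 4))
  sds <- apply(pop$strength, 2, sd, na.rm = TRUE)
  expect_true(all(sds == 0, na.rm = TRUE))
})

test_that("adult male headcount stays inside the plausibility band", {
  pop <- default_study()$population
  M <- coalrank:::presence_matrix(pop)
  for (g in unique(pop$presence$group)) {
    counts <- rowSums(M[, pop$presence$group == g, drop = FALSE])
    expect_true(all(counts >= 7 & counts <= 18))
  }
  expect_error(population_config(adult_males_per_group = 25),
               "adult_males_per_group")
  expect_error(population_config(study_days = 100), "study_days")
})

test_that("contest outcomes are symmetric when strengths are equal", {
  pop <- generate_population(population_config(
    n_groups = 1, adult_males_per_group = 7, study_days = 500,
    migration_rate = 0, strength_sd = 0, strength_ar1 = 0, seed = 6))
  ints <- simulate_agonism(pop, encounter_rate = 1, tau = 1, seed = 6)
  expect_gt(nrow(ints), 10000)
  share <- mean(ints$winner < ints$loser)  # either pair member equally likely
  expect_lt(abs(share - 0.5), 3 * 0.5 / sqrt(nrow(ints)))
})

test_that("win probability follows the logistic contest model", {
  pop <- generate_population(population_config(
    n_groups = 1, adult_males_per_group = 7, study_days = 730,
    migration_rate = 0, strength_sd = 0, strength_ar1 = 0, seed = 8))
  focal_male <- pop$presence$male[1]
  pop$strength[, 1] <- pop$strength[, 1] + 1  # delta strength = tau
  ints <- simulate_agonism(pop, encounter_rate = 1, tau = 1, seed = 8)
  mine <- ints[ints$winner == focal_male | ints$loser == focal_male, ]
  n <- nrow(mine)
  expect_gt(n, 4000)
  p_hat <- mean(mine$winner == focal_male)
  p_true <- plogis(1)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("encounter_rate = 0 yields an empty interaction table", {
  pop <- generate_population(population_config(study_days = 200, seed = 2))
  ints <- simulate_agonism(pop, encounter_rate = 0, seed = 2)
  expect_equal(nrow(ints), 0)
  expect_named(ints, c("date", "group", "winner", "loser"))
  expect_error(simulate_agonism(pop, tau = 0), class = "coalrank_config_error")
})

test_that("zero injection leaves participant and target changes indistinguishable", {
  st <- null_study()
  co <- st$coalitions
  expect_gt(length(unique(co$event_id)), 200)
  changes <- lapply(seq_len(nrow(co)), function(i) {
    m <- co$male[i]
    p <- st$presence[st$presence$male == m, ]
    if (co$date[i] + 30 > p$exit) return(NULL)
    data.frame(role = co$role[i],
               change = rating_at(st$trajectories, m, co$date[i] + 30) -
                 rating_at(st$trajectories, m, co$date[i]))
  })
  changes <- do.call(rbind, changes)
  p <- wilcox.test(change ~ role, data = changes)$p.value
  expect_gt(p, 0.01)
})

test_that("realized configuration shares match the drawn mixture", {
  st <- null_study()  # mixture realization does not depend on injection
  met <- coalition_metrics(st$coalitions, st$trajectories)
  expect_gte(nrow(met), 300)
  shares <- configuration_share_table(met$configuration)
  expect_lt(abs(shares$percent[shares$configuration == "all-down"] - 69), 10)
  expect_lt(abs(shares$percent[shares$configuration == "bridging"] - 19), 10)
  expect_lt(abs(shares$percent[shares$configuration == "all-up"] - 13), 10)
  # and the classification recomputed from ratings equals the drawn label
  tru <- st$truth$coalition$events
  expect_equal(met$configuration,
               tru$configuration[match(met$event_id, tru$event_id)])
})

test_that("injected deficits decay linearly to half at the horizon midpoint", {
  pop <- generate_population(population_config(study_days = 300, seed = 2))
  ints <- simulate_agonism(pop, seed = 2)
  sim <- simulate_coalitions(pop, ints,
                             coalition_config(event_rate = 0.01,
                                              target_effect = 50,
                                              participant_effect = 0),
                             seed = 2)
  tru <- sim$truth$events
  # isolated targets only: overlapping perturbations add
  once <- names(which(table(tru$target) == 1))
  checked <- 0
  for (i in seq_len(nrow(tru))) {
    if (!tru$target[i] %in% once) next
    d0 <- as.integer(tru$date[i] - pop$days[1]) + 1L
    if (d0 + 60 > nrow(sim$perturbation)) next
    ratio <- unname(sim$perturbation[d0 + 60, tru$target[i]] /
                      sim$perturbation[d0, tru$target[i]])
    expect_equal(ratio, 0.5, tolerance = 1e-8)
    checked <- checked + 1
  }
  expect_gte(checked, 1)
})

test_that("default paternity settings yield 19 conception records", {
  st <- default_study()
  expect_equal(nrow(st$conceptions), 19)
  expect_true(all(table(st$candidates$infant) <= 12))
})

test_that("sire frequency is flat across rating deciles when the slope is zero", {
  d <- simulate_paternity_cohort(
    paternity_config(n_conceptions = 500, slope = 0, male_re_sd = 0,
                     n_males = 60), seed = 12)
  expect_gte(nrow(d), 5000)
  dec <- cut(d$rating, quantile(d$rating, 0:10 / 10), include.lowest = TRUE)
  p <- suppressWarnings(chisq.test(table(dec, d$sired)))$p.value
  expect_gt(p, 0.01)
})

test_that("binned sire fractions track the logistic curve", {
  cfg <- paternity_config(n_conceptions = 1000, slope = 2, intercept = -2,
                          male_re_sd = 0, n_males = 100)
  d <- simulate_paternity_cohort(cfg, seed = 13)
  bins <- cut(d$rating, seq(0, 1, by = 0.2), include.lowest = TRUE)
  for (b in levels(bins)) {
    sel <- bins == b
    n <- sum(sel)
    p_true <- mean(plogis(-2 + 2 * d$rating[sel]))
    p_hat <- mean(d$sired[sel])
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  }
})

test_that("generated tables pass the input validators unchanged", {
  st <- default_study()
  expect_no_warning(
    tabs <- validate_inputs(list(
      interactions = st$interactions, coalitions = st$coalitions,
      presence = st$presence, focal = st$focal,
      conceptions = st$conceptions)))
  expect_equal(nrow(tabs$interactions), nrow(st$interactions))
})

test_that("invalid generator configurations are rejected naming the field", {
  expect_error(coalition_config(mix = c("all-down" = 0.5, "bridging" = 0.4,
                                        "all-up" = 0.2)), "mix")
  expect_error(coalition_config(decay_horizon = 0), "decay_horizon")
  expect_error(coalition_config(target_effect = -1), "effects")
  expect_error(paternity_config(window = 10), "window")
  expect_error(paternity_config(n_conceptions = 0), "n_conceptions")
})
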