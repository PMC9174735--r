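test_that("comparing a model with itself gives chi-squared 0 and p = 1", {
  design <- make_null_rank_design(n_events = 20, n_males = 10, seed = 2)
  design$response <- simulate_null_response(design, 2)
  f <- suppressMessages(fit_rank_model(design, calibration_spec()))
  out <- likelihood_ratio_test(f, f)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 0)
  expect_equal(out$p, 1)
})

test_that("the LRT statistic equals twice the log-likelihood difference", {
  design <- make_null_rank_design(n_events = 20, n_males = 10, seed = 3)
  design$response <- simulate_null_response(design, 3)
  spec <- calibration_spec()
  full <- suppressMessages(fit_rank_model(design, spec))
  null <- suppressMessages(fit_rank_model(design, spec, null = TRUE))
  out <- likelihood_ratio_test(full, null)
  expect_equal(out$statistic,
               max(0, 2 * (as.numeric(logLik(full$fit)) -
                             as.numeric(logLik(null$fit)))))
  expect_equal(out$p, pchisq(out$statistic, out$df, lower.tail = FALSE))
})

test_that("LRT df equals an independent count of design-matrix columns", {
  design <- make_null_rank_design(n_events = 25, n_males = 10, seed = 4)
  design$response <- simulate_null_response(design, 4)
  spec <- calibration_spec()
  rl <- suppressMessages(rank_lrt(design, spec))
  mm_full <- model.matrix(
    ~ role * configuration * feasibility_z + role * days_z + rank0_z +
      age_z + aggr_z + stability_z + competition_z + group, design)
  mm_null <- model.matrix(
    ~ rank0_z + age_z + aggr_z + stability_z + competition_z + group,
    design)
  expect_equal(rl$lrt$df, ncol(mm_full) - ncol(mm_null))
  expect_equal(rl$lrt$df, 13)
})

test_that("a constant response raises an explicit error", {
  design <- make_null_rank_design(n_events = 10, n_males = 8, seed = 5)
  design$response <- 1000
  expect_error(fit_rank_model(design), class = "coalrank_data_error")
})

test_that("non-nested comparisons are rejected", {
  design <- make_null_rank_design(n_events = 20, n_males = 10, seed = 6)
  design$response <- simulate_null_response(design, 6)
  spec <- calibration_spec()
  full <- suppressMessages(fit_rank_model(design, spec))
  null <- suppressMessages(fit_rank_model(design, spec, null = TRUE))
  expect_error(likelihood_ratio_test(null, full),
               class = "coalrank_usage_error")
})

test_that("the paternity full-vs-null comparison has a single df", {
  d <- simulate_paternity_cohort(seed = 30)
  full <- suppressMessages(fit_paternity_model(d, controls = character()))
  null <- suppressMessages(fit_paternity_model(d, controls = character(),
                                               include_rating = FALSE))
  out <- likelihood_ratio_test(full, null)
  expect_equal(out$df, 1)
})

test_that("the LRT is invariant under affine predictor rescaling", {
  d <- simulate_paternity_cohort(paternity_config(n_conceptions = 40),
                                 seed = 31)
  lrt_of <- function(dd) {
    full <- suppressMessages(fit_paternity_model(dd, controls = character()))
    null <- suppressMessages(fit_paternity_model(dd, controls = character(),
                                                 include_rating = FALSE))
    likelihood_ratio_test(full, null)$statistic
  }
  d2 <- d
  d2$rating <- 10 * d$rating + 5
  expect_equal(lrt_of(d), lrt_of(d2), tolerance = 1e-4)
})

test_that("with no between-male variance the GLMM matches plain logistic regression", {
  d <- simulate_paternity_cohort(
    paternity_config(n_conceptions = 1500, male_re_sd = 0, n_males = 300),
    seed = 3)
  f1 <- suppressMessages(fit_paternity_model(d, controls = character()))
  f0 <- glm(sired ~ rating, binomial, d)
  expect_lt(max(abs(f1$coefficients$estimate - coef(f0))), 1e-3)
})

test_that("separated data raise a diagnostic error", {
  set.seed(1)
  d <- data.frame(infant = rep(sprintf("I%d", 1:10), each = 4),
                  male = rep(sprintf("M%d", 1:8), 5), rating = runif(40))
  d$sired <- as.integer(d$rating > 0.5)
  expect_error(
    suppressWarnings(suppressMessages(
      fit_paternity_model(d, controls = character()))),
    class = "coalrank_separation_error")
})

test_that("slope estimates centre on zero when the generator slope is zero", {
  est <- vapply(1:60, function(i) {
    d <- simulate_paternity_cohort(
      paternity_config(slope = 0, intercept = -2.4), seed = 4000 + i)
    f <- suppressMessages(fit_paternity_model(d, controls = character()))
    f$coefficients$estimate[f$coefficients$term == "rating"]
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * sd(est) / sqrt(length(est)))
})

test_that("bootstrap handles B = 1 and reports full-size curve sets", {
  set.seed(50)
  g <- rep(1:10, each = 12)
  d <- data.frame(y = 1 + 0.5 * runif(120) + rnorm(10, 0, 0.5)[g] +
                    rnorm(120, 0, 0.7),
                  x = runif(120), g = factor(g))
  fit <- lme4::lmer(y ~ x + (1 | g), data = d, REML = FALSE)
  wf <- coalrank:::wrap_fit(fit, "toy", "lmer-ML")
  grid <- data.frame(x = c(0, 1), g = "1")
  one <- bootstrap_predictions(wf, grid, B = 1, seed = 9)
  expect_equal(nrow(one$curves), 1)
  many <- bootstrap_predictions(wf, grid, B = 200, seed = 9)
  expect_equal(nrow(many$curves) + many$n_failed, 200)
  expect_true(all(many$band$lo <= many$band$hi))
})

test_that("bootstrap bands cover the truth in most replicates", {
  cover <- 0
  nrep <- 24
  for (r in seq_len(nrep)) {
    set.seed(100 + r)
    g <- rep(1:15, each = 20)
    x <- runif(300)
    y <- 2 + 1.5 * x + rnorm(15, 0, 0.8)[g] + rnorm(300, 0, 1)
    d <- data.frame(y, x, g = factor(g))
    fit <- lme4::lmer(y ~ x + (1 | g), data = d, REML = FALSE)
    wf <- coalrank:::wrap_fit(fit, "toy", "lmer-ML")
    bp <- bootstrap_predictions(wf, data.frame(x = 0.5, g = "1"), B = 250,
                                seed = r)
    truth <- 2 + 1.5 * 0.5
    cover <- cover + (bp$band$lo <= truth && truth <= bp$band$hi)
  }
  expect_gte(cover / nrep, 0.75)
})

test_that("the GLMM log-likelihood matches a direct integration oracle", {
  set.seed(4)
  nob <- 40
  dd <- data.frame(infant = rep(sprintf("I%02d", 1:nob), each = 3),
                   male = rep(c("A", "B", "C"), nob),
                   rating = runif(3 * nob))
  b <- rnorm(3, 0, 1)
  dd$sired <- rbinom(3 * nob, 1,
                     plogis(-1 + 1.5 * dd$rating +
                              b[match(dd$male, c("A", "B", "C"))]))
  ff <- suppressMessages(fit_paternity_model(dd, controls = character(),
                                             nAGQ = 25))
  beta <- ff$coefficients$estimate
  sig <- ff$varcomp$sdcor[1]
  ll_direct <- sum(vapply(split(dd, dd$male), function(g) {
    f <- function(u) vapply(u, function(ui) {
      exp(sum(dbinom(g$sired, 1,
                     plogis(beta[1] + beta[2] * g$rating + ui),
                     log = TRUE)) + dnorm(ui, 0, sig, log = TRUE))
    }, numeric(1))
    log(integrate(f, -10 * sig, 10 * sig, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_lt(abs(ff$logLik - ll_direct), 1e-3)
})
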