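test_that("a single contest between equal-rated males exchanges k/2 points", {
  pres <- toy_presence()
  ints <- toy_interaction("2020-02-01", "A", "B")
  for (es in c("logistic-400", "normal-cdf")) {
    tr <- elo_trajectories(ints, pres, elo_params(expected_score = es))
    expect_equal(rating_at(tr, c("A", "B"), as.Date("2020-03-01")),
                 c(1050, 950))
  }
})

test_that("update magnitude follows the closed-form expected score", {
  pres <- toy_presence()
  ints <- rbind(toy_interaction("2020-02-01", "A", "B"),
                toy_interaction("2020-02-02", "A", "B"))
  # after the first contest A=1050, B=950; second gain = k * (1 - E(100))
  tr <- elo_trajectories(ints, pres, elo_params())
  gain_log <- 100 * (1 - 1 / (1 + 10^(-100 / 400)))
  expect_equal(rating_at(tr, "A", as.Date("2020-02-02")), 1050 + gain_log)
  tr2 <- elo_trajectories(ints, pres, elo_params(expected_score = "normal-cdf"))
  gain_nc <- 100 * (1 - pnorm(100 / (200 * sqrt(2))))
  expect_equal(rating_at(tr2, "A", as.Date("2020-02-02")), 1050 + gain_nc)
})

test_that("an empty interaction table leaves every male at the start value", {
  pres <- toy_presence(c("A", "B", "C"))
  empty <- data.frame(date = as.Date(character()), group = character(),
                      winner = character(), loser = character())
  tr <- elo_trajectories(empty, pres)
  expect_equal(rating_at(tr, c("A", "B", "C"), as.Date("2020-06-01")),
               rep(1000, 3))
})

test_that("updates conserve the rating total (zero-sum)", {
  set.seed(21)
  males <- c("A", "B", "C", "D")
  pres <- toy_presence(males)
  n <- 80
  wl <- t(replicate(n, sample(males, 2)))
  ints <- toy_interaction(as.Date("2020-01-05") + sort(sample(1:300, n, TRUE)),
                          wl[, 1], wl[, 2])
  for (es in c("logistic-400", "normal-cdf")) {
    tr <- elo_trajectories(ints, pres, elo_params(expected_score = es))
    final <- rating_at(tr, males, as.Date("2020-12-01"))
    expect_equal(sum(final), 4 * 1000)
  }
})

test_that("sequential ratings match brute-force replay at arbitrary dates", {
  set.seed(33)
  males <- c("A", "B", "C", "D", "E")
  pres <- toy_presence(males)
  wl <- t(replicate(50, sample(males, 2)))
  ints <- toy_interaction(as.Date("2020-01-10") + sort(sample(0:200, 50, TRUE)),
                          wl[, 1], wl[, 2])
  tr <- elo_trajectories(ints, pres)
  for (q in 1:12) {
    d <- as.Date("2020-01-01") + sample(0:300, 1)
    m <- sample(males, 1)
    expect_equal(rating_at(tr, m, d), replay_rating(ints, pres, m, d))
  }
})

test_that("expected-score functions are symmetric, increasing and 0.5 at 0", {
  grid <- seq(-800, 800, by = 50)
  for (es in c("logistic-400", "normal-cdf")) {
    efun <- coalrank:::expected_score_fun(elo_params(expected_score = es))
    expect_equal(efun(0), 0.5)
    expect_equal(efun(grid) + efun(-grid), rep(1, length(grid)))
    expect_true(all(diff(efun(grid)) > 0))
    expect_true(all(efun(grid) > 0 & efun(grid) < 1))
  }
})

test_that("rating_at uses carry-forward and the post-update day convention", {
  pres <- toy_presence()
  ints <- toy_interaction("2020-03-01", "A", "B")
  tr <- elo_trajectories(ints, pres)
  expect_equal(rating_at(tr, "A", as.Date("2020-02-15")), 1000)
  expect_equal(rating_at(tr, "A", as.Date("2020-03-01")), 1050)  # day of update
  expect_equal(rating_at(tr, "A", as.Date("2020-07-01")), 1050)  # carry-forward
  expect_error(rating_at(tr, "A", as.Date("2021-02-01")),
               class = "coalrank_lookup_error")
})

test_that("interaction validation names the offending rows", {
  pres <- toy_presence()
  expect_error(
    elo_trajectories(toy_interaction("2020-02-01", "A", "A"), pres),
    class = "coalrank_data_error")
  expect_error(
    elo_trajectories(toy_interaction("2019-02-01", "A", "B"), pres),
    class = "coalrank_data_error")
})

test_that("future_ratings yields day 0 plus 12 future offsets by default", {
  pres <- toy_presence()
  tr <- elo_trajectories(toy_interaction("2020-02-01", "A", "B"), pres)
  fut <- future_ratings(tr, "A", as.Date("2020-03-01"))
  expect_equal(nrow(fut), 13)
  expect_equal(fut$offset, seq(0, 120, by = 10))
  expect_true(all(fut$present))
  # constant trajectory after the only contest: identical at all offsets
  expect_equal(unique(fut$rating), 1050)
})

test_that("future offsets after emigration are absent, not imputed", {
  pres <- toy_presence()
  pres$exit[pres$male == "A"] <- as.Date("2020-04-05")  # event + 35 days
  tr <- elo_trajectories(toy_interaction("2020-02-01", "A", "B"), pres)
  fut <- future_ratings(tr, "A", as.Date("2020-03-01"))
  expect_equal(fut$present, fut$offset <= 30)
  expect_true(all(is.na(fut$rating[fut$offset >= 40])))
  expect_error(future_ratings(tr, "A", as.Date("2020-03-01"), step = 0),
               class = "coalrank_config_error")
  expect_error(future_ratings(tr, "A", as.Date("2020-03-01"), step = 10,
                              horizon = 5),
               class = "coalrank_config_error")
})

test_that("standardization maps extremes to 0/1 and preserves order", {
  pres <- toy_presence(c("A", "B"))
  tr <- elo_trajectories(toy_interaction("2020-02-01", "A", "B"), pres)
  s <- standardize_ratings(tr, "G1", as.Date("2020-03-01"))
  expect_equal(s$s[order(s$male)], c(1, 0))

  # zero-sum makes {1050, 1000, 950}: linearity forces the midpoint
  pres3 <- toy_presence(c("A", "B", "C"))
  tr3 <- elo_trajectories(toy_interaction("2020-02-01", "A", "B"), pres3)
  s3 <- standardize_ratings(tr3, "G1", as.Date("2020-03-01"))
  expect_equal(s3$s[match(c("A", "C", "B"), s3$male)], c(1, 0.5, 0))
  expect_equal(order(s3$s), order(s3$rating))
})

test_that("standardization rejects degenerate inputs", {
  pres <- toy_presence("A")
  tr <- elo_trajectories(
    data.frame(date = as.Date(character()), group = character(),
               winner = character(), loser = character()), pres)
  expect_error(standardize_ratings(tr, "G1", as.Date("2020-03-01")),
               class = "coalrank_standardization_error")
  pres2 <- toy_presence(c("A", "B"))
  tr2 <- elo_trajectories(
    data.frame(date = as.Date(character()), group = character(),
               winner = character(), loser = character()), pres2)
  expect_error(standardize_ratings(tr2, "G1", as.Date("2020-03-01")),
               class = "coalrank_standardization_error")
})
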