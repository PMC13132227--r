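test_that("attraction updating obeys the memory limits", {
  expect_equal(update_attraction(0.7, 1, 0), 0.7)    # phi = 0: never updates
  expect_equal(update_attraction(0.7, 1, 1), 1)      # phi = 1: no memory
  expect_equal(update_attraction(0.4, 1, 0.25), 0.55)
  expect_error(update_attraction(0.4, 1, 1.2), "phi")
  # boundedness: payoffs in {0,1} keep attractions in [0,1]
  A <- 0.3
  set.seed(1)
  for (k in 1:50) {
    A <- update_attraction(A, sample(0:1, 1), runif(1))
    expect_true(A >= 0 && A <= 1)
  }
})

test_that("softmax choice probabilities behave across the sensitivity range", {
  expect_equal(individual_probs(c(0.9, 0.1), 0), c(0.5, 0.5))
  expect_equal(individual_probs(c(1, 0), 1),
               c(exp(1), 1) / (exp(1) + 1))
  expect_equal(individual_probs(c(0.4, 0.4), 7.3), c(0.5, 0.5))
  expect_error(individual_probs(c(1, 0), -1), "lambda")
  expect_equal(sum(individual_probs(runif(4), 2.7)), 1, tolerance = 1e-12)
})

test_that("frequency-dependent social probabilities follow N^f normalisation", {
  expect_equal(frequency_social_probs(c(9, 1), 1), c(0.9, 0.1))
  expect_equal(frequency_social_probs(c(3, 1), 2), c(0.9, 0.1))
  expect_equal(frequency_social_probs(c(4, 1), 0.5), c(2 / 3, 1 / 3))
  expect_null(frequency_social_probs(c(0, 0), 1))  # no-information sentinel
  expect_error(frequency_social_probs(c(1, 1), 0), "positive")
})

test_that("cue-biased probabilities weight same-roost demonstrations", {
  tal <- structure(list(N = c(red = 1, blue = 1), male = c(red = 0, blue = 0),
                        adult = c(red = 0, blue = 0),
                        same_roost = c(red = 1, blue = 0)),
                   class = "social_tally")
  expect_equal(cue_bias_social_probs(tal, log(3)), c(red = 0.75, blue = 0.25))
  # beta = 0 reduces to unbiased frequency dependence
  set.seed(2)
  for (k in 1:5) {
    N <- c(red = sample(0:5, 1), blue = sample(1:5, 1))
    same <- c(red = sample(0:N[["red"]], 1), blue = sample(0:N[["blue"]], 1))
    tal <- structure(list(N = N, male = N * 0, adult = N * 0, same_roost = same),
                     class = "social_tally")
    expect_equal(cue_bias_social_probs(tal, 0), frequency_social_probs(N, 1))
  }
  # beta -> +inf: all mass on the same-roost demonstrated option
  tal <- structure(list(N = c(red = 2, blue = 5), male = c(0, 0), adult = c(0, 0),
                        same_roost = c(red = 2, blue = 0)),
                   class = "social_tally")
  p <- cue_bias_social_probs(tal, 50)
  expect_equal(unname(p[1]), 1, tolerance = 1e-10)
  empty <- structure(list(N = c(red = 0, blue = 0), male = c(0, 0),
                          adult = c(0, 0), same_roost = c(0, 0)),
                     class = "social_tally")
  expect_null(cue_bias_social_probs(empty, 1))
})

test_that("category-restricted probabilities use only that demonstrator class", {
  tal <- structure(list(N = c(red = 2, blue = 5), male = c(red = 2, blue = 0),
                        adult = c(red = 0, blue = 0),
                        same_roost = c(red = 0, blue = 0)),
                   class = "social_tally")
  expect_equal(category_social_probs(tal, "male"), c(red = 1, blue = 0))
  expect_null(category_social_probs(tal, "adult"))      # fallback sentinel
  expect_equal(category_social_probs(tal, "everyone"),
               frequency_social_probs(tal$N, 1))
})

test_that("social windows are half-open, site-local and self-excluding", {
  roster <- make_roster(3)
  roster$sex_class <- c("male", "female", "female")
  roster$roost <- c("S1", "S1", "S2")
  ev <- data.frame(
    time = c(39, 41, 60, 90, 99.5, 100),
    site = c("S1", "S1", "S2", "S1", "S1", "S1"),
    individual_id = c("ID002", "ID003", "ID002", "ID001", "ID002", "ID003"),
    option = c("red", "red", "red", "red", "red", "blue"),
    success = c(1, 1, 1, 0, 1, 1))
  # focal ID001 at t = 100, site S1: row1 (t=39) just outside [40,100), row3
  # other site, row4 self, row6 at t = 100 excluded by the half-open window
  tal <- tally_social_window(ev, "ID001", 100, "S1", individuals = roster)
  expect_equal(tal$N, c(red = 2, blue = 0))
  expect_equal(tal$male, c(red = 0, blue = 0))      # both demonstrators female
  expect_equal(tal$same_roost, c(red = 1, blue = 0))  # only ID002 shares S1
  # successful-only filtering drops failed pickups
  tal2 <- tally_social_window(ev, "ID002", 100, "S1", individuals = roster,
                              demos = "successful-only")
  expect_equal(tal2$N, c(red = 1, blue = 0))
  expect_error(tally_social_window(ev[c(2, 1), ], "ID001", 100, "S1"), "sorted")
})

test_that("individual and social components combine as a convex mixture", {
  I <- c(0.5, 0.5)
  expect_equal(choice_probability(I, c(1, 0), 0), I)
  expect_equal(choice_probability(I, c(0.9, 0.1), 1), c(0.9, 0.1))
  expect_equal(choice_probability(I, c(1, 0), 0.2), c(0.6, 0.4))
  expect_equal(choice_probability(I, NULL, 0.7), I)  # sentinel -> individual
  expect_error(choice_probability(I, I, 1.5), "gamma")
})

test_that("the EWA log-likelihood matches the hand-worked two-choice case", {
  ind <- make_roster(1)
  ev <- data.frame(time = c(0, 100), site = "S1", individual_id = "ID001",
                   option = "red", success = c(1, 1))
  ll <- ewa_loglik(ev, ind, list(lambda = 2, phi = 0.3), "individual_only")
  expect_equal(as.numeric(ll), log(0.5) + log(exp(0.6) / (exp(0.6) + 1)),
               tolerance = 1e-9)
  expect_equal(as.numeric(ll), -1.1306, tolerance = 1e-4)
})

test_that("strategy likelihood identities hold on random data", {
  set.seed(33)
  roster <- make_roster(6)
  roster$roost <- rep(c("S1", "S2"), 3)
  roster$sex_class <- rep(c("male", "female"), each = 3)
  sched <- data.frame(individual_id = sample(rep(roster$id, 8)),
                      time = sort(runif(48, 0, 600)), site = "S1")
  ev <- simulate_choices(sched, roster, list(lambda = 2, phi = 0.3, gamma = 0.3,
                                             f = 1.5),
                         strategy = "frequency", seed = 5)
  # gamma = 0 in any social strategy equals the individual-only likelihood
  base <- ewa_loglik(ev, roster, list(lambda = 2, phi = 0.25), "individual_only")
  for (strat in c("frequency", "male_bias", "roost_bias"))
    expect_equal(as.numeric(ewa_loglik(ev, roster,
                                       list(lambda = 2, phi = 0.25, gamma = 0,
                                            f = 2, beta = 1), strat)),
                 as.numeric(base))
  # frequency with f = 1 equals cue bias with beta = 0
  p1 <- ewa_loglik(ev, roster, list(lambda = 2, phi = 0.25, gamma = 0.4, f = 1),
                   "frequency")
  p2 <- ewa_loglik(ev, roster, list(lambda = 2, phi = 0.25, gamma = 0.4, beta = 0),
                   "roost_bias")
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("R and compiled likelihood paths agree with the independent oracle", {
  set.seed(44)
  roster <- make_roster(8)
  roster$age_class <- rep(c("adult", "juvenile"), 4)
  roster$sex_class <- rep(c("male", "female"), each = 4)
  roster$roost <- rep(c("S1", "S2"), 4)
  roster$tutored_option[1] <- "red"
  sched <- data.frame(individual_id = sample(c(rep(roster$id, 6), rep("UNMARKED", 6))),
                      time = sort(runif(54, 0, 500)), site = "S1")
  ev <- simulate_choices(sched, roster,
                         list(lambda = 2.2, phi = 0.3, gamma = 0.25, f = 1.8,
                              beta = 0.4),
                         strategy = "frequency", seed = 6)
  params <- list(lambda = 2.2, phi = 0.3, gamma = 0.25, f = 1.8, beta = 0.4)
  for (strat in c("individual_only", "frequency", "male_bias", "age_bias",
                  "roost_bias")) {
    r_ll <- as.numeric(ewa_loglik(ev, roster, params, strat))
    expect_equal(r_ll, oracle_ewa_loglik(ev, roster, params, strat),
                 tolerance = 1e-10, label = strat)
    prep <- cultdiff:::ewa_prepare(ev, roster)
    dat <- cultdiff:::.ewa_cpp_data(prep, strat)
    th <- matrix(c(2.2, 0.3, 0.25, 1.8, 0.4), length(prep$choosers), 5,
                 byrow = TRUE)
    expect_equal(cultdiff:::ewa_loglik_grouped(dat, th)$loglik, r_ll,
                 tolerance = 1e-10, label = strat)
  }
})

test_that("choice simulation honours limits, seeds and first-choice laws", {
  roster <- make_roster(1, tutored = "red")
  sched <- data.frame(individual_id = "ID001", time = 1, site = "S1")
  # tutored attraction + large lambda -> tutored colour almost surely
  set.seed(9)
  first <- vapply(1:200, function(k)
    simulate_choices(sched, roster, list(lambda = 50, phi = 0.2, gamma = 0),
                     strategy = "individual_only")$option[1], character(1))
  expect_true(all(first == "red"))

  e1 <- simulate_choices(sched, roster, list(lambda = 2, phi = 0.2),
                         strategy = "individual_only", seed = 12)
  e2 <- simulate_choices(sched, roster, list(lambda = 2, phi = 0.2),
                         strategy = "individual_only", seed = 12)
  expect_identical(e1, e2)

  # isolated first choices follow the softmax of initial attractions
  roster2 <- make_roster(1, tutored = "red")
  set.seed(10)
  lam <- 1.3
  draws <- vapply(1:4000, function(k)
    simulate_choices(sched, roster2, list(lambda = lam, phi = 0.2),
                     strategy = "individual_only")$option[1], character(1))
  p_hat <- mean(draws == "red")
  p_true <- exp(lam) / (exp(lam) + 1)
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 4000))
})
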