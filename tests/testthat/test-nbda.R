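empty_net <- function(ids) {
  make_network(matrix(0, length(ids), length(ids), dimnames = list(ids, ids)))
}

test_that("order-of-acquisition likelihood matches hand-computed cases", {
  # asocial uniform null over 4 individuals: NLL = log 4! for any order
  ids <- c("A", "B", "C", "D")
  rec <- diffusion_record(list(list(site = "x", learners = sample(ids),
                                    risk_set = ids,
                                    seeded_informed = character())))
  expect_equal(as.numeric(oada_negloglik(rec, empty_net(ids), nbda_params(0))),
               log(24))

  # single informed hub with one unit-weight edge, s = 10:
  # first event P(B) = 11/12, second P(C) = 1
  ids <- c("A", "B", "C")
  sri <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sri["A", "B"] <- sri["B", "A"] <- 1
  rec <- diffusion_record(list(list(site = "x", learners = c("B", "C"),
                                    risk_set = ids, seeded_informed = "A")))
  expect_equal(as.numeric(oada_negloglik(rec, make_network(sri), nbda_params(10))),
               -log(11 / 12))
})

test_that("event probabilities define a distribution over complete orders", {
  set.seed(21)
  for (rep in 1:3) {
    n <- 5
    net <- random_network(n)
    s <- runif(1, 0, 8)
    seeded <- sample(net$ids, 1)
    naive <- setdiff(net$ids, seeded)
    orders <- oracle_all_orders(naive)
    total <- sum(vapply(orders, function(ord) {
      rec <- diffusion_record(list(list(site = "x", learners = ord,
                                        risk_set = net$ids,
                                        seeded_informed = seeded)))
      exp(-as.numeric(oada_negloglik(rec, net, nbda_params(s))))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-10)
    # the package's per-order probability equals the independent oracle
    ord <- orders[[7]]
    rec <- diffusion_record(list(list(site = "x", learners = ord,
                                      risk_set = net$ids,
                                      seeded_informed = seeded)))
    expect_equal(exp(-as.numeric(oada_negloglik(rec, net, nbda_params(s)))),
                 oracle_order_prob(ord, net, s, net$ids, seeded),
                 tolerance = 1e-12)
  }
})

test_that("likelihood is invariant to relabelling with symmetric structure", {
  set.seed(5)
  net <- random_network(5)
  seeded <- net$ids[1]
  ord <- sample(setdiff(net$ids, seeded))
  rec <- diffusion_record(list(list(site = "x", learners = ord,
                                    risk_set = net$ids, seeded_informed = seeded)))
  nll <- as.numeric(oada_negloglik(rec, net, nbda_params(3)))
  # relabel all individuals
  relab <- setNames(paste0("m", seq_along(net$ids)), net$ids)
  sri2 <- net$sri
  dimnames(sri2) <- list(relab[net$ids], relab[net$ids])
  rec2 <- diffusion_record(list(list(site = "x", learners = unname(relab[ord]),
                                     risk_set = unname(relab[net$ids]),
                                     seeded_informed = unname(relab[seeded]))))
  expect_equal(as.numeric(oada_negloglik(rec2, make_network(sri2), nbda_params(3))),
               nll)
})

test_that("stronger social transmission favours the informed hub's associate", {
  ids <- c("hub", "friend", "stranger")
  sri <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sri["hub", "friend"] <- sri["friend", "hub"] <- 0.8
  net <- make_network(sri)
  p_friend <- function(s) {
    rec <- diffusion_record(list(list(site = "x", learners = c("friend", "stranger"),
                                      risk_set = ids, seeded_informed = "hub")))
    exp(-attr(oada_negloglik(rec, net, nbda_params(s)), "per_event")[1])
  }
  probs <- vapply(c(0, 1, 5, 20), p_friend, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_equal(probs[1], 0.5)
})

test_that("diffusion simulator respects limits and is seed-reproducible", {
  ids <- c("hub", "friend", "loner")
  sri <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sri["hub", "friend"] <- sri["friend", "hub"] <- 1
  net <- make_network(sri)
  # s -> infinity: the hub's sole associate always learns first
  firsts <- vapply(1:30, function(k) {
    rec <- simulate_diffusion(net, nbda_params(1e8), risk_set = ids,
                              seeded_informed = "hub", seed = k)
    rec$diffusions[[1]]$learners[1]
  }, character(1))
  expect_true(all(firsts == "friend"))

  r1 <- simulate_diffusion(net, nbda_params(2), risk_set = ids,
                           seeded_informed = "hub", seed = 99)
  r2 <- simulate_diffusion(net, nbda_params(2), risk_set = ids,
                           seeded_informed = "hub", seed = 99)
  expect_identical(r1$diffusions, r2$diffusions)
  expect_error(simulate_diffusion(net, nbda_params(1), risk_set = character()),
               "empty")
})

test_that("asocial simulation yields uniform acquisition orders", {
  ids <- paste0("u", 1:4)
  net <- empty_net(ids)
  set.seed(17)
  orders <- vapply(1:5000, function(k) {
    rec <- simulate_diffusion(net, nbda_params(0), risk_set = ids)
    paste(rec$diffusions[[1]]$learners, collapse = "")
  }, character(1))
  tab <- table(orders)
  expect_equal(length(tab), 24)
  gof <- chisq.test(tab, p = rep(1 / 24, 24))
  expect_gt(gof$p.value, 0.01)
})

test_that("asocial-only fit reproduces the closed-form null likelihood", {
  set.seed(31)
  net <- random_network(6)
  seeded <- net$ids[1]
  rec <- simulate_diffusion(net, nbda_params(3), risk_set = net$ids,
                            seeded_informed = seeded, seed = 4)
  fit <- fit_oada(rec, net, social = FALSE)
  expect_equal(fit$logLik,
               -as.numeric(oada_negloglik(rec, net, nbda_params(0))))
  expect_equal(fit$k, 0L)
})

test_that("AICc table reproduces the weight formula and family sums", {
  mock_fit <- function(name, social, k, ll, n = 40)
    structure(list(name = name, social = social, k = k, logLik = ll,
                   n_events = n, converged = TRUE,
                   params = nbda_params(0), social_ilvs = character(),
                   asocial_ilvs = character()), class = "oada_fit")
  # equal likelihood and k -> equal weights
  tab <- aicc_model_table(list(mock_fit("a", TRUE, 1, -10),
                               mock_fit("b", FALSE, 1, -10)))
  expect_equal(tab$weight, c(0.5, 0.5))
  # dAICc of exactly 2 -> weight ratio e
  f1 <- mock_fit("a", TRUE, 1, -10)
  f2 <- mock_fit("b", FALSE, 1, -10 - 1)   # AICc difference = 2
  tab <- aicc_model_table(list(f1, f2))
  expect_equal(tab$weight[1] / tab$weight[2], exp(1), tolerance = 1e-12)
  # families partition the weights
  tab <- aicc_model_table(list(mock_fit("a", TRUE, 1, -10),
                               mock_fit("b", TRUE, 2, -9),
                               mock_fit("c", FALSE, 1, -11)))
  fam <- attr(tab, "family_weights")
  expect_equal(unname(fam["social"] + fam["asocial"]), 1)
  expect_equal(unname(fam["social"]), sum(tab$weight[tab$social]))
  # AICc undefined when n <= k + 1
  expect_error(aicc_model_table(list(mock_fit("a", TRUE, 1, -10, n = 2))),
               "AICc undefined")
})

test_that("percent-social estimates match per-event rate decomposition", {
  ids <- c("A", "B", "C")
  sri <- matrix(0, 3, 3, dimnames = list(ids, ids))
  sri["A", "B"] <- sri["B", "A"] <- 0.9
  net <- make_network(sri)
  rec <- diffusion_record(list(list(site = "x", learners = c("B", "C"),
                                    risk_set = ids, seeded_informed = "A")))
  # at s = 10: event 1 social fraction = 9/10, event 2 = 0
  fit <- structure(list(params = nbda_params(10), logLik = -1, k = 1,
                        n_events = 2, converged = TRUE, social = TRUE,
                        social_ilvs = character(), asocial_ilvs = character(),
                        name = "social"), class = "oada_fit")
  fit$logLik <- -as.numeric(oada_negloglik(rec, net, nbda_params(10)))
  ps <- percent_social(fit, rec, net)
  expect_equal(unname(ps$per_event), c(0.9, 0))
  expect_equal(ps$estimate, 45)
  asocial <- structure(c(fit, list()), class = "oada_fit")
  asocial$social <- FALSE
  expect_error(percent_social(asocial, rec, net), "social model")
  # s = 0 -> 0 percent
  fit0 <- fit
  fit0$params <- nbda_params(0)
  fit0$logLik <- -as.numeric(oada_negloglik(rec, net, nbda_params(0)))
  expect_equal(percent_social(fit0, rec, net)$estimate, 0)
})

test_that("diffusion CSV round trip preserves the record", {
  set.seed(8)
  net <- random_network(6)
  rec <- simulate_diffusion(net, nbda_params(2), risk_set = net$ids,
                            seeded_informed = net$ids[1], n_events = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diffusion(rec, path)
  back <- read_diffusion(path)
  expect_equal(back$diffusions[[1]]$learners, rec$diffusions[[1]]$learners)
  expect_setequal(back$diffusions[[1]]$risk_set, rec$diffusions[[1]]$risk_set)
  expect_setequal(back$diffusions[[1]]$seeded_informed,
                  rec$diffusions[[1]]$seeded_informed)
})

test_that("diffusion record invariants are enforced", {
  expect_error(diffusion_record(list(list(site = "x", learners = c("A", "A"),
                                          risk_set = c("A", "B")))),
               "twice")
  expect_error(diffusion_record(list(list(site = "x", learners = "Z",
                                          risk_set = c("A", "B")))),
               "outside the risk set")
  expect_error(diffusion_record(list(list(site = "x", learners = "A",
                                          risk_set = c("A", "B"),
                                          seeded_informed = "A"))),
               "seeded")
})
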