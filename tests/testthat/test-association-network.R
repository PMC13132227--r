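test_that("SRI worked examples match direct arithmetic", {
  # A,B together in 3 scans, A alone in 1, B alone in 2 -> 3/6
  scans <- data.frame(
    scan_id = c("s1", "s1", "s2", "s2", "s3", "s3", "s4", "s5", "s6"),
    individual_id = c("A", "B", "A", "B", "A", "B", "A", "B", "B"))
  net <- build_sri_network(scans)
  expect_equal(net$sri["A", "B"], 0.5)

  # always together -> 1
  scans2 <- data.frame(scan_id = rep(sprintf("s%d", 1:10), each = 2),
                       individual_id = rep(c("A", "B"), 10))
  expect_equal(build_sri_network(scans2)$sri["A", "B"], 1)

  # never together -> 0
  scans3 <- data.frame(scan_id = c("s1", "s2"), individual_id = c("A", "B"))
  expect_equal(build_sri_network(scans3)$sri["A", "B"], 0)
})

test_that("SRI matches brute-force set computation on random scan sets", {
  set.seed(101)
  for (rep in 1:5) {
    ids <- paste0("b", 1:8)
    scans <- do.call(rbind, lapply(1:30, function(k) {
      present <- sample(ids, sample(2:6, 1))
      data.frame(scan_id = paste0("s", k), individual_id = present)
    }))
    net <- build_sri_network(scans, ids = ids)
    for (pair in list(c("b1", "b2"), c("b3", "b7"), c("b5", "b8")))
      expect_equal(net$sri[pair[1], pair[2]],
                   oracle_sri(scans, pair[1], pair[2]))
    # symmetry and range
    expect_true(isSymmetric(net$sri))
    expect_true(all(net$sri >= 0 & net$sri <= 1))
    expect_true(all(diag(net$sri) == 0))
  }
})

test_that("scans not involving a dyad leave its SRI unchanged", {
  set.seed(7)
  scans <- do.call(rbind, lapply(1:20, function(k) {
    data.frame(scan_id = paste0("s", k),
               individual_id = sample(paste0("b", 1:6), sample(2:4, 1)))
  }))
  net1 <- build_sri_network(scans, ids = paste0("b", 1:8))
  extra <- data.frame(scan_id = "extra", individual_id = c("b7", "b8"))
  net2 <- build_sri_network(rbind(scans, extra), ids = paste0("b", 1:8))
  expect_equal(net1$sri["b1", "b2"], net2$sri["b1", "b2"])
})

test_that("SRI input validation catches malformed scans", {
  expect_error(build_sri_network(data.frame()), "non-empty")
  dup <- data.frame(scan_id = c("s1", "s1"), individual_id = c("A", "A"))
  expect_error(build_sri_network(dup), "duplicate individual")
  clash <- data.frame(scan_id = c("s1", "s1"), site = c("X", "Y"),
                      individual_id = c("A", "B"))
  expect_error(build_sri_network(clash), "reused")
  # roster individuals never scanned stay as isolated nodes
  ok <- data.frame(scan_id = c("s1", "s1"), individual_id = c("A", "B"))
  net <- build_sri_network(ok, ids = c("A", "B", "C"))
  expect_true("C" %in% net$ids)
  expect_equal(sum(net$sri["C", ]), 0)
})

test_that("movement rates equal the Jaccard overlap of attendance sets", {
  # n_ov = 2, n_A = 10, n_B = 12 -> 2/20
  att <- list(A = paste0("x", 1:10), B = c(paste0("x", 9:10), paste0("y", 1:10)))
  expect_equal(movement_rates(att)["A", "B"], 0.10)
  expect_equal(movement_rates(list(A = "a", B = "b"))["A", "B"], 0)
  expect_equal(movement_rates(list(A = letters[1:5], B = letters[1:5]))["A", "B"], 1)
  expect_error(movement_rates(list(A = character(), B = "b")), "A")

  set.seed(11)
  att <- lapply(setNames(1:4, paste0("S", 1:4)), function(i)
    sample(paste0("z", 1:30), sample(5:20, 1)))
  m <- movement_rates(att)
  expect_true(isSymmetric(unclass(m)))
  expect_equal(unname(diag(m)), rep(1, 4))
  for (a in 1:3) for (b in (a + 1):4) {
    inter <- length(intersect(att[[a]], att[[b]]))
    uni <- length(unique(c(att[[a]], att[[b]])))
    expect_equal(unname(m[a, b]), inter / uni)
  }
})

test_that("roost membership follows the two-of-three census rule with fallback", {
  counts <- data.frame(individual_id = c("i1", "i1", "i2", "i2", "i2", "i3"),
                       site = c("A", "B", "A", "B", "C", "A"),
                       count = c(2, 1, 1, 1, 1, 0))
  out <- assign_roost_membership(counts,
                                 marking_site = c(i2 = "B", i4 = "C"),
                                 ids = c("i1", "i2", "i3", "i4", "i5"))
  expect_equal(unname(out["i1"]), "A")       # >= 2 counts at A
  expect_equal(unname(out["i2"]), "B")       # fallback to marking site
  expect_equal(unname(out["i3"]), "unknown") # no counts, no marking
  expect_equal(unname(out["i4"]), "C")
  expect_equal(unname(out["i5"]), "unknown")

  clash <- data.frame(individual_id = c("i1", "i1"), site = c("A", "B"),
                      count = c(2, 2))
  expect_error(assign_roost_membership(clash), "two different sites")
  bad <- data.frame(individual_id = "i1", site = "A", count = 4)
  expect_error(assign_roost_membership(bad), "0..3")
})

test_that("edge-list round trip preserves the network", {
  set.seed(3)
  net <- random_network(6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(net, path)
  back <- read_edge_list(path, ids = net$ids)
  expect_equal(back$sri, net$sri)
})
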