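toy_seqs <- function() {
  data.frame(individual_id = c("a", "a", "b", "c"),
             site = c("S1", "S1", "S2", "S3"),
             unshell = c(1, 1, 0, 0),
             crack = c("tip", "tip", "seam", "hilum"),
             extract = c("nibble", "nibble", "split", "other"),
             duration_s = c(30, NA, 50, 70),
             stringsAsFactors = FALSE)
}

test_that("sequence encoding one-hots categories and normalises columns", {
  enc <- encode_sequences(toy_seqs())
  expect_equal(enc[1, ], enc[2, ])            # identical sequences
  expect_true(all(abs(colMeans(enc)) < 1e-12))
  sds <- apply(enc, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-12))
  # constant column contributes zeros
  s2 <- toy_seqs(); s2$unshell <- 1
  enc2 <- encode_sequences(s2)
  expect_equal(unname(enc2[, "unshell"]), rep(0, 4))
  # hand-built check on a 3-sequence toy: one-hot then z-score by column
  s3 <- data.frame(individual_id = c("x", "y", "z"), site = "S1",
                   unshell = c(1, 0, 0),
                   crack = c("tip", "tip", "seam"),
                   extract = c("nibble", "split", "split"))
  enc3 <- encode_sequences(s3)
  zs <- function(v) (v - mean(v)) / sd(v)
  expect_equal(unname(enc3[, "unshell"]), zs(c(1, 0, 0)))
  expect_equal(unname(enc3[, "tip"]), zs(c(1, 1, 0)))
  expect_equal(unname(enc3[, "seam"]), zs(c(0, 0, 1)))
  expect_equal(unname(enc3[, "nibble"]), zs(c(1, 0, 0)))
  expect_equal(unname(enc3[, "hilum"]), rep(0, 3))
  bad <- toy_seqs(); bad$crack[2] <- "sideways"
  expect_error(encode_sequences(bad), "row\\(s\\) 2")
})

test_that("dissimilarities are Euclidean, metric and symmetric", {
  enc <- encode_sequences(toy_seqs())
  D <- sequence_dissimilarity(enc)
  expect_equal(D[1, 2], 0)
  expect_equal(D[3, 4], sqrt(sum((enc[3, ] - enc[4, ])^2)))
  expect_true(isSymmetric(D))
  set.seed(14)
  M <- matrix(rnorm(60), 10, 6)
  D2 <- sequence_dissimilarity(M)
  for (k in 1:20) {
    ijk <- sample(10, 3)
    expect_lte(D2[ijk[1], ijk[3]],
               D2[ijk[1], ijk[2]] + D2[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("predictor matrices encode drivers as dissimilarities", {
  seqs <- toy_seqs()
  sites <- data.frame(site = c("S1", "S2", "S3"),
                      lat = c(-33.80, -33.81, -33.90),
                      lon = c(151.25, 151.26, 151.30))
  same <- build_predictor_matrix(seqs, "same_individual")
  expect_equal(same[1, 2], 0)
  expect_equal(same[1, 3], 1)
  D <- build_predictor_matrix(seqs, "site_distance", sites = sites)
  expect_equal(D[1, 2], 0)
  expect_equal(D[1, 3],
               geosphere::distHaversine(c(151.25, -33.80), c(151.26, -33.81)) / 1000)
  mm <- structure(matrix(c(1, .2, .05, .2, 1, .1, .05, .1, 1), 3, 3,
                         dimnames = list(c("S1", "S2", "S3"), c("S1", "S2", "S3"))),
                  class = c("movement_matrix", "matrix"))
  Mv <- build_predictor_matrix(seqs, "site_movement", movement = mm)
  expect_equal(Mv[1, 2], 0)            # same site
  expect_equal(Mv[1, 3], 0)            # m(S1,S2) = 0.2 is the max off-diagonal
  expect_equal(Mv[1, 4], 1 - 0.05 / 0.2)
  net <- make_network(matrix(c(0, .4, .4, 0), 2, 2,
                             dimnames = list(c("a", "b"), c("a", "b"))))
  A <- build_predictor_matrix(seqs, "association", network = net)
  expect_equal(A[1, 3], 0.6)
  expect_equal(A[1, 2], 0)           # same individual
  expect_true(is.na(A[1, 4]))        # c not in the network -> flagged missing
})

test_that("partial Mantel recovers self-correlation and degenerate controls fail", {
  set.seed(15)
  Dx <- random_dissimilarity(15)
  Dz <- random_dissimilarity(15)
  res <- partial_mantel(Dx, Dx, Dz, n_perm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$p, 1 / 200)
  expect_error(partial_mantel(Dx, Dz, Dz, n_perm = 99), "degenerate")
  expect_error(partial_mantel(Dx, Dz, random_dissimilarity(15), n_perm = 50),
               "99")
})

test_that("partial Mantel with a constant-like control reduces to simple Mantel", {
  set.seed(16)
  Dy <- random_dissimilarity(12)
  Dx <- random_dissimilarity(12)
  # control orthogonal by construction: use a matrix uncorrelated with both
  Dz <- random_dissimilarity(12)
  lt <- lower.tri(Dy)
  r_simple <- cor(Dx[lt], Dy[lt])
  r_partial <- partial_mantel(Dy, Dx, Dz, n_perm = 99, seed = 2)$r
  rxz <- cor(Dx[lt], Dz[lt]); ryz <- cor(Dy[lt], Dz[lt])
  expect_equal(r_partial, (r_simple - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)
  expect_equal(r_partial, oracle_partial_r(Dy, Dx, Dz), tolerance = 1e-12)
})

test_that("missing dyads are deleted pairwise before correlation", {
  set.seed(17)
  Dy <- random_dissimilarity(10)
  Dx <- random_dissimilarity(10)
  Dz <- random_dissimilarity(10)
  Dx_na <- Dx
  Dx_na[1, 2] <- Dx_na[2, 1] <- NA
  res <- partial_mantel(Dy, Dx_na, Dz, n_perm = 199, seed = 3)
  # oracle on the reduced triangle
  lt <- lower.tri(Dy)
  ok <- is.finite(Dx_na[lt])
  y <- Dy[lt][ok]; x <- Dx[lt][ok]; z <- Dz[lt][ok]
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(res$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-12)
})

test_that("partial Mantel agrees with vegan on complete matrices", {
  skip_if_not_installed("vegan")
  set.seed(18)
  Dy <- random_dissimilarity(14)
  Dx <- random_dissimilarity(14)
  Dz <- random_dissimilarity(14)
  ours <- partial_mantel(Dy, Dx, Dz, n_perm = 499, seed = 4)
  ref <- vegan::mantel.partial(as.dist(Dx), as.dist(Dy), as.dist(Dz),
                               permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
  # permutation p-values agree within Monte Carlo error
  expect_lt(abs(ours$p - ref$signif), 0.12)
})

test_that("contingency post hocs match closed-form chi-square results", {
  tab <- matrix(c(50, 0, 0, 50), 2, 2,
                dimnames = list(c("split", "nibble"), c("m", "f")))
  res <- contingency_posthoc(tab)
  expect_equal(attr(res, "omnibus")$chi_sq, 100)
  # identical group distributions -> adjusted p of 1
  tab2 <- matrix(c(30, 20, 10, 30, 20, 10), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  res2 <- contingency_posthoc(tab2)
  expect_true(all(res2$p_adj == 1))
  # textbook-style hand computation for one collapsed category
  tab3 <- matrix(c(20, 30, 40, 10), 2, 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  collapsed <- rbind(tab3[1, ], colSums(tab3[-1, , drop = FALSE]))
  expected <- outer(rowSums(collapsed), colSums(collapsed)) / sum(collapsed)
  chi_hand <- sum((collapsed - expected)^2 / expected)
  res3 <- contingency_posthoc(tab3)
  expect_equal(res3$chi_sq[1], chi_hand)
  expect_equal(res3$p_adj[1], min(1, res3$p[1] * 2))
  expect_error(contingency_posthoc(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})
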