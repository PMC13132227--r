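# In-code fixtures shared across test files.

make_network <- function(sri) {
  ids <- rownames(sri)
  structure(list(ids = ids, sri = sri, n_scans = NA_integer_),
            class = "assoc_network")
}

random_network <- function(n, density = 0.6) {
  ids <- paste0("n", seq_len(n))
  sri <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    w <- if (runif(1) < density) runif(1) else 0
    sri[i, j] <- sri[j, i] <- w
  }
  make_network(sri)
}

# two-community network: dense within blocks, sparse between
modular_network <- function(n_per_block = 30, p_within = 0.4, p_between = 0.02,
                            w_within = 0.3, w_between = 0.05) {
  n <- 2 * n_per_block
  ids <- paste0("n", seq_len(n))
  block <- rep(1:2, each = n_per_block)
  sri <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    same <- block[i] == block[j]
    p <- if (same) p_within else p_between
    if (runif(1) < p) {
      w <- runif(1, 0, if (same) w_within else w_between)
      sri[i, j] <- sri[j, i] <- w
    }
  }
  make_network(sri)
}

make_roster <- function(n, age = "adult", sex = "male", roost = "S1",
                        tutored = NA_character_) {
  data.frame(id = sprintf("ID%03d", seq_len(n)),
             age_class = rep(age, length.out = n),
             sex_class = rep(sex, length.out = n),
             roost = rep(roost, length.out = n),
             tutored_option = rep(tutored, length.out = n),
             stringsAsFactors = FALSE)
}

# small random symmetric dissimilarity matrix, zero diagonal
random_dissimilarity <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}
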