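## Opening-technique analysis: encode categorical opening sequences, compute
## Euclidean dissimilarities, build dyadic predictor matrices, and run
## partial Mantel permutation tests and contingency post hocs.

crack_levels <- function() c("tip", "seam", "hilum", "middle")
extract_levels <- function() c("nibble", "split", "other")

#' Read opening sequences from CSV
#'
#' Expects columns `individual_id,site,unshell,crack,extract` and optionally
#' `duration_s` (blank allowed). `unshell` is 0/1 or logical; `crack` one of
#' tip/seam/hilum/middle; `extract` one of nibble/split/other.
#'
#' @param path CSV file path.
#' @return validated data frame of opening sequences.
#' @export
read_openings <- function(path) {
  seqs <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "site", "unshell", "crack", "extract")
  if (!all(need %in% names(seqs)))
    stop("openings file must have columns ", paste(need, collapse = ","))
  validate_openings(seqs)
  seqs
}

validate_openings <- function(seqs) {
  bad <- which(!(seqs$crack %in% crack_levels()))
  if (length(bad))
    stop("unknown crack category in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(seqs$crack[bad]), collapse = ", "))
  bad <- which(!(seqs$extract %in% extract_levels()))
  if (length(bad))
    stop("unknown extract category in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(seqs$extract[bad]), collapse = ", "))
  if (!all(as.integer(seqs$unshell) %in% c(0L, 1L)))
    stop("unshell must be 0/1 or logical")
  invisible(seqs)
}

#' Read site coordinates from CSV
#'
#' Expects columns `site,lat,lon` (decimal degrees).
#' @param path CSV file path.
#' @return data frame of sites.
#' @export
read_sites <- function(path) {
  sites <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("site", "lat", "lon") %in% names(sites)))
    stop("sites file must have columns site,lat,lon")
  sites
}

#' Great-circle distances between sites in kilometres
#'
#' @param sites data frame with `site`, `lat`, `lon`.
#' @return symmetric site-by-site distance matrix (km).
#' @export
site_distances <- function(sites) {
  n <- nrow(sites)
  m <- matrix(0, n, n, dimnames = list(sites$site, sites$site))
  for (a in seq_len(n)) for (b in seq_len(n))
    m[a, b] <- geosphere::distHaversine(c(sites$lon[a], sites$lat[a]),
                                        c(sites$lon[b], sites$lat[b])) / 1000
  m
}

#' Encode opening sequences as a normalised numeric matrix
#'
#' `unshell` becomes 0/1, `crack` and `extract` become one-hot blocks, and
#' (optionally) duration is z-scored. Every column is then normalised to zero
#' mean and unit variance; columns constant across sequences become all-zero
#' and so contribute nothing to distances.
#'
#' @param seqs opening-sequence data frame (see [read_openings()]).
#' @param include_duration include the `duration_s` column (z-scored; missing
#'   durations are set to the mean)? Off by default since durations are
#'   typically coded for a subset only.
#' @return numeric matrix, one row per sequence.
#' @export
encode_sequences <- function(seqs, include_duration = FALSE) {
  if (nrow(seqs) < 2L) stop("need at least 2 sequences")
  validate_openings(seqs)
  onehot <- function(x, levels) {
    m <- sapply(levels, function(l) as.numeric(x == l))
    colnames(m) <- levels
    m
  }
  enc <- cbind(unshell = as.numeric(seqs$unshell),
               onehot(seqs$crack, crack_levels()),
               onehot(seqs$extract, extract_levels()))
  if (include_duration) {
    if (!"duration_s" %in% names(seqs))
      stop("include_duration = TRUE but no duration_s column")
    dur <- as.numeric(seqs$duration_s)
    dur[is.na(dur)] <- mean(dur, na.rm = TRUE)
    enc <- cbind(enc, duration = dur)
  }
  apply(enc, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
}

#' Pairwise Euclidean dissimilarities between encoded sequences
#'
#' @param encoded matrix from [encode_sequences()].
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
sequence_dissimilarity <- function(encoded) {
  if (!all(is.finite(encoded))) stop("encoded matrix must be finite")
  as.matrix(dist(encoded, method = "euclidean"))
}

#' Dyadic predictor matrices for the technique analysis
#'
#' Builds, over pairs of opening sequences, the dissimilarity matrix of one
#' putative driver of technique variation. All predictors are returned as
#' dissimilarities, so a positive Mantel correlation reads "similar sequences
#' go with similar / closer / better-connected pairs":
#' \describe{
#'   \item{same_individual}{0 if the two sequences are by the same
#'     individual, else 1.}
#'   \item{site_distance}{great-circle km between the sequences' sites.}
#'   \item{site_movement}{`1 - m / max(m)` with `m` the between-site movement
#'     rate and the maximum taken over distinct site pairs; same-site pairs
#'     are 0 (values clamped at 0).}
#'   \item{association}{`1 - SRI` between the two individuals; same-individual
#'     pairs are 0; dyads absent from the network are `NA` (flagged missing,
#'     excluded pairwise by [partial_mantel()]).}
#'   \item{relatedness}{`max(r) - r` between the two individuals;
#'     same-individual pairs are 0; missing dyads are `NA`.}
#' }
#'
#' @param seqs opening-sequence data frame.
#' @param kind predictor kind (see above).
#' @param sites site coordinate data frame (for `site_distance`).
#' @param movement `movement_matrix` (for `site_movement`).
#' @param network `assoc_network` (for `association`).
#' @param relatedness symmetric relatedness matrix with dimnames (for
#'   `relatedness`).
#' @return symmetric numeric matrix over sequences (zero diagonal), possibly
#'   containing `NA` for missing dyads.
#' @export
build_predictor_matrix <- function(seqs,
                                   kind = c("same_individual", "site_distance",
                                            "site_movement", "association",
                                            "relatedness"),
                                   sites = NULL, movement = NULL,
                                   network = NULL, relatedness = NULL) {
  kind <- match.arg(kind)
  n <- nrow(seqs)
  ids <- seqs$individual_id
  out <- switch(kind,
    same_individual = 1 - outer(ids, ids, "=="),
    site_distance = {
      if (is.null(sites)) stop("site_distance needs `sites`")
      miss <- setdiff(unique(seqs$site), sites$site)
      if (length(miss)) stop("site(s) missing coordinates: ", paste(miss, collapse = ", "))
      dk <- site_distances(sites)
      dk[cbind(rep(match(seqs$site, sites$site), n),
               rep(match(seqs$site, sites$site), each = n))]
    },
    site_movement = {
      if (is.null(movement)) stop("site_movement needs `movement`")
      miss <- setdiff(unique(seqs$site), rownames(movement))
      if (length(miss)) stop("site(s) missing from movement matrix: ",
                             paste(miss, collapse = ", "))
      off <- movement
      diag(off) <- NA
      mmax <- max(off, na.rm = TRUE)
      m <- movement[cbind(rep(match(seqs$site, rownames(movement)), n),
                          rep(match(seqs$site, rownames(movement)), each = n))]
      pmax(0, 1 - m / mmax)
    },
    association = {
      if (is.null(network)) stop("association needs `network`")
      idx <- match(ids, network$ids)
      v <- rep(NA_real_, n * n)
      known <- !is.na(idx)
      pair_known <- outer(known, known, "&")
      v[pair_known] <- 1 - network$sri[cbind(rep(idx, n), rep(idx, each = n))][pair_known]
      v[outer(ids, ids, "==")] <- 0
      v
    },
    relatedness = {
      if (is.null(relatedness)) stop("relatedness needs `relatedness`")
      idx <- match(ids, rownames(relatedness))
      off <- relatedness
      diag(off) <- NA
      rmax <- max(off, na.rm = TRUE)
      v <- rep(NA_real_, n * n)
      known <- !is.na(idx)
      pair_known <- outer(known, known, "&")
      v[pair_known] <- rmax - relatedness[cbind(rep(idx, n), rep(idx, each = n))][pair_known]
      v[outer(ids, ids, "==")] <- 0
      v
    })
  out <- matrix(out, n, n)
  diag(out) <- 0
  out
}

#' Partial Mantel permutation test
#'
#' Tests the correlation between two dissimilarity matrices while controlling
#' for a third. The statistic is the partial Pearson correlation of the
#' lower-triangle vectors,
#' \deqn{r_{xy \cdot z} = (r_{xy} - r_{xz} r_{yz}) /
#'   \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)},}
#' and the null distribution is generated by simultaneously permuting the
#' rows and columns of `D_y`. The p-value uses the add-one rule,
#' p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1) for `tail = "greater"`.
#' `NA` entries (missing dyads) are deleted pairwise from the triangle
#' vectors before each correlation.
#'
#' @param D_y response dissimilarity matrix (the one permuted).
#' @param D_x predictor dissimilarity matrix.
#' @param D_z control dissimilarity matrix.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @param tail `"greater"` (default; directional similarity hypothesis),
#'   `"less"`, or `"two-sided"`.
#' @param exhaustive enumerate all `n!` row permutations instead of sampling
#'   (only for small n; the p-value is then the exact fraction of
#'   permutations, identity included, at least as extreme as observed).
#' @return list with `r` (observed partial correlation), `p`, `n_perm`,
#'   `tail`.
#' @export
partial_mantel <- function(D_y, D_x, D_z, n_perm = 999, seed = NULL,
                           tail = c("greater", "less", "two-sided"),
                           exhaustive = FALSE) {
  tail <- match.arg(tail)
  D_y <- as.matrix(D_y); D_x <- as.matrix(D_x); D_z <- as.matrix(D_z)
  n <- nrow(D_y)
  if (!all(dim(D_x) == n) || !all(dim(D_z) == n))
    stop("matrices must be conformable and square")
  if (n_perm < 99) stop("use at least 99 permutations")
  lt <- lower.tri(D_y)
  x <- D_x[lt]; z <- D_z[lt]
  partial_r <- function(y) {
    ok <- is.finite(x) & is.finite(y) & is.finite(z)
    r_xy <- cor(x[ok], y[ok])
    r_xz <- cor(x[ok], z[ok])
    r_yz <- cor(y[ok], z[ok])
    if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
      stop("degenerate control matrix: |correlation with control| = 1")
    (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  }
  r_obs <- partial_r(D_y[lt])
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    perms <- .all_permutations(n)
    r_perm <- vapply(perms, function(p) partial_r(D_y[p, p][lt]), numeric(1))
    p <- switch(tail,
                greater = mean(r_perm >= r_obs - 1e-12),
                less = mean(r_perm <= r_obs + 1e-12),
                `two-sided` = mean(abs(r_perm) >= abs(r_obs) - 1e-12))
    return(list(r = r_obs, p = p, n_perm = length(perms), tail = tail))
  }
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    partial_r(D_y[p, p][lt])
  }, numeric(1))
  p <- switch(tail,
              greater = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
              less = (sum(r_perm <= r_obs) + 1) / (n_perm + 1),
              `two-sided` = (sum(abs(r_perm) >= abs(r_obs)) + 1) / (n_perm + 1))
  list(r = r_obs, p = p, n_perm = n_perm, tail = tail)
}

#' Chi-square post hoc tests on a category-by-group contingency table
#'
#' Runs the omnibus chi-square test (no continuity correction), then for each
#' category a 2-by-groups collapsed chi-square (that category versus all
#' others), with Bonferroni correction over categories.
#'
#' @param tab matrix of non-negative integer counts, categories in rows,
#'   groups in columns.
#' @param alpha significance level recorded alongside the adjusted p-values.
#' @return data frame with per-category `chi_sq`, `df`, `p`, `p_adj` and a
#'   `low_expected` flag (any expected cell < 1); the omnibus test result is
#'   attached as attribute `"omnibus"`.
#' @export
contingency_posthoc <- function(tab, alpha = 0.05) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  omnibus <- suppressWarnings(chisq.test(tab, correct = FALSE))
  ncat <- nrow(tab)
  rows <- lapply(seq_len(ncat), function(i) {
    collapsed <- rbind(tab[i, ], colSums(tab[-i, , drop = FALSE]))
    ct <- suppressWarnings(chisq.test(collapsed, correct = FALSE))
    low <- any(ct$expected < 1)
    if (low)
      warning("expected cell < 1 in post hoc for category ",
              rownames(tab)[i] %||% i)
    data.frame(category = rownames(tab)[i] %||% as.character(i),
               chi_sq = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value,
               p_adj = min(1, ct$p.value * ncat),
               low_expected = low, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "omnibus") <- list(chi_sq = unname(omnibus$statistic),
                               df = unname(omnibus$parameter),
                               p = omnibus$p.value)
  attr(out, "alpha") <- alpha
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- vector("list", factorial(n))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (s in .all_permutations(n - 1L)) {
      k <- k + 1L
      out[[k]] <- c(i, rest[s])
    }
  }
  out
}
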