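#' Build a weighted association network from group scans
#'
#' Constructs the simple ratio index (SRI) network under the
#' gambit-of-the-group assumption: every pair of individuals recorded in the
#' same scan is taken to be associating. For a dyad (i, j) the edge weight is
#'
#' \deqn{SRI_{ij} = x_{ij} / (x_{ij} + y_i + y_j)}
#'
#' where \eqn{x_{ij}} is the number of scans containing both individuals and
#' \eqn{y_i}, \eqn{y_j} the numbers of scans containing exactly one of them.
#' Scans from all observation periods are pooled, and the denominator counts
#' scans where at least one member was present anywhere in the shared
#' observation area (it is not stratified by site).
#'
#' @param scans data frame with columns `scan_id`, `individual_id` and
#'   optionally `site` and `datetime`; one row per individual per scan.
#' @param ids optional character roster. Individuals never scanned are kept as
#'   isolated nodes (all-zero rows) so that downstream diffusion analyses can
#'   include them in risk sets.
#' @param sites optional character vector of sites to retain before pooling
#'   (a period/site filter); default uses all scans.
#' @return An object of class `assoc_network`: a list with elements `ids` and
#'   `sri` (symmetric numeric matrix, zero diagonal, entries in \[0, 1\]).
#' @examples
#' scans <- data.frame(
#'   scan_id = c("s1", "s1", "s2", "s2", "s3", "s4"),
#'   individual_id = c("A", "B", "A", "B", "A", "B")
#' )
#' net <- build_sri_network(scans)
#' net$sri["A", "B"]  # 2 joint / 4 scans with either = 0.5
#' @export
build_sri_network <- function(scans, ids = NULL, sites = NULL) {
  if (!is.data.frame(scans) || nrow(scans) == 0L)
    stop("`scans` must be a non-empty data frame")
  required <- c("scan_id", "individual_id")
  missing_cols <- setdiff(required, names(scans))
  if (length(missing_cols))
    stop("`scans` is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.null(sites)) {
    if (!"site" %in% names(scans)) stop("site filter requested but `scans` has no `site` column")
    scans <- scans[scans$site %in% sites, , drop = FALSE]
    if (nrow(scans) == 0L) stop("no scans left after site filter")
  }
  scans$scan_id <- as.character(scans$scan_id)
  scans$individual_id <- as.character(scans$individual_id)
  if (anyDuplicated(scans[, c("scan_id", "individual_id")]))
    stop("duplicate individual within a scan (same scan_id, individual_id pair)")
  # a scan_id must refer to a single scan: one site, one time
  for (col in intersect(c("site", "datetime"), names(scans))) {
    n_distinct <- tapply(as.character(scans[[col]]), scans$scan_id,
                         function(x) length(unique(x)))
    if (any(n_distinct > 1L))
      stop("scan_id reused across different values of `", col, "`: ",
           paste(names(n_distinct)[n_distinct > 1L], collapse = ", "))
  }
  scanned_ids <- sort(unique(scans$individual_id))
  if (is.null(ids)) {
    ids <- scanned_ids
  } else {
    ids <- as.character(ids)
    if (anyDuplicated(ids)) stop("roster `ids` contains duplicates")
    extra <- setdiff(scanned_ids, ids)
    if (length(extra))
      stop("individuals in scans but not in roster: ", paste(extra, collapse = ", "))
  }
  scan_ids <- unique(scans$scan_id)
  inc <- matrix(0L, nrow = length(scan_ids), ncol = length(ids),
                dimnames = list(scan_ids, ids))
  inc[cbind(match(scans$scan_id, scan_ids), match(scans$individual_id, ids))] <- 1L
  joint <- crossprod(inc)                      # x_ij (diag = per-id scan count)
  n_i <- diag(joint)
  either <- outer(n_i, n_i, "+") - joint       # scans with at least one present
  sri <- ifelse(either > 0, joint / either, 0)
  diag(sri) <- 0
  structure(list(ids = ids, sri = sri, n_scans = length(scan_ids)),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  w <- x$sri[upper.tri(x$sri)]
  cat(sprintf(
    "Association network: %d individuals, %d scans\n  non-zero dyads: %d / %d, mean SRI (non-zero): %.3f\n",
    length(x$ids), x$n_scans, sum(w > 0), length(w),
    if (any(w > 0)) mean(w[w > 0]) else NA_real_))
  invisible(x)
}

#' Movement rates between roosting sites
#'
#' Computes the between-site movement rate
#' \deqn{m_{AB} = n_{ov} / (n_A + n_B - n_{ov})}
#' where \eqn{n_A} and \eqn{n_B} are the numbers of individuals recorded at
#' sites A and B over the experimental period and \eqn{n_{ov}} the number
#' recorded at both (the Jaccard overlap of the attendance sets). Individuals
#' that visit several sites contribute to every pairwise overlap they appear
#' in. By convention the diagonal is 1.
#'
#' @param attendance named list mapping each site to the character vector of
#'   individuals observed there at least once.
#' @return An object of class `movement_matrix`: symmetric site-by-site
#'   numeric matrix with entries in \[0, 1\] and unit diagonal.
#' @export
movement_rates <- function(attendance) {
  if (!is.list(attendance) || is.null(names(attendance)) || any(names(attendance) == ""))
    stop("`attendance` must be a named list of site attendance sets")
  empty <- names(attendance)[lengths(attendance) == 0L]
  if (length(empty))
    stop("empty attendance set for site(s): ", paste(empty, collapse = ", "))
  attendance <- lapply(attendance, function(x) unique(as.character(x)))
  sites <- names(attendance)
  m <- matrix(1, length(sites), length(sites), dimnames = list(sites, sites))
  if (length(sites) > 1L) {
    for (a in seq_len(length(sites) - 1L)) {
      for (b in seq(a + 1L, length(sites))) {
        n_ov <- length(intersect(attendance[[a]], attendance[[b]]))
        n_a <- length(attendance[[a]])
        n_b <- length(attendance[[b]])
        m[a, b] <- m[b, a] <- n_ov / (n_a + n_b - n_ov)
      }
    }
  }
  structure(m, class = c("movement_matrix", "matrix"))
}

#' Assign roost membership from census counts
#'
#' An individual is assigned to the roost where it was recorded in at least
#' two out of three pre-dawn roost counts. Individuals without such a site
#' fall back to their marking site; with neither, membership is `"unknown"`.
#'
#' @param roost_counts data frame with columns `individual_id`, `site`,
#'   `count` (number of censuses, 0--3, at which the individual was recorded
#'   at that site).
#' @param marking_site optional named character vector mapping individual ids
#'   to the site at which they were first marked.
#' @param ids optional character vector of individuals to assign; defaults to
#'   the union of ids in `roost_counts` and `marking_site`.
#' @return named character vector: site (or `"unknown"`) per individual.
#' @export
assign_roost_membership <- function(roost_counts, marking_site = NULL, ids = NULL) {
  stopifnot(is.data.frame(roost_counts),
            all(c("individual_id", "site", "count") %in% names(roost_counts)))
  if (any(roost_counts$count < 0 | roost_counts$count > 3 |
          roost_counts$count != round(roost_counts$count)))
    stop("census counts must be integers in 0..3")
  roost_counts$individual_id <- as.character(roost_counts$individual_id)
  if (is.null(ids))
    ids <- sort(unique(c(roost_counts$individual_id, names(marking_site))))
  out <- setNames(rep("unknown", length(ids)), ids)
  hits <- roost_counts[roost_counts$count >= 2, , drop = FALSE]
  if (nrow(hits)) {
    n_sites <- tapply(hits$site, hits$individual_id, function(x) length(unique(x)))
    clash <- names(n_sites)[n_sites > 1L]
    if (length(clash))
      stop("individual(s) with >=2 counts at two different sites (overlapping censuses?): ",
           paste(clash, collapse = ", "))
    out[hits$individual_id] <- as.character(hits$site)
  }
  if (!is.null(marking_site)) {
    fallback <- intersect(names(marking_site), names(out)[out == "unknown"])
    out[fallback] <- as.character(marking_site[fallback])
  }
  out
}

#' Read group scans from CSV
#'
#' Expects columns `scan_id,datetime,site,individual_id` (one row per
#' individual per scan); `datetime` may be ISO-8601 or numeric seconds.
#'
#' @param path CSV file path.
#' @return data frame of scans.
#' @export
read_scans <- function(path) {
  scans <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("scan_id", "individual_id")
  if (!all(need %in% names(scans)))
    stop("scans file must have columns scan_id and individual_id")
  scans
}

#' Read the individual roster from CSV
#'
#' Expects columns `id,age_class,sex_class,roost,tutored_option`. Age classes
#' must be in \{adult, juvenile, unknown\}, sex classes in
#' \{male, female, unknown\} (unknown is a modelled level, not missing data).
#'
#' @param path CSV file path.
#' @return data frame roster with validated factors as character columns.
#' @export
read_individuals <- function(path) {
  ind <- read.csv(path, stringsAsFactors = FALSE)
  validate_individuals(ind)
  ind
}

validate_individuals <- function(ind) {
  need <- c("id", "age_class", "sex_class", "roost", "tutored_option")
  miss <- setdiff(need, names(ind))
  if (length(miss))
    stop("individuals table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ind$id))
    stop("duplicate individual ids: ",
         paste(unique(ind$id[duplicated(ind$id)]), collapse = ", "))
  bad_age <- setdiff(unique(ind$age_class), c("adult", "juvenile", "unknown"))
  if (length(bad_age)) stop("invalid age_class value(s): ", paste(bad_age, collapse = ", "))
  bad_sex <- setdiff(unique(ind$sex_class), c("male", "female", "unknown"))
  if (length(bad_sex)) stop("invalid sex_class value(s): ", paste(bad_sex, collapse = ", "))
  invisible(ind)
}

#' Write an association network as an edge list CSV
#'
#' @param net `assoc_network` object.
#' @param path output CSV path; columns `id_i,id_j,sri`.
#' @param keep_zero keep never-associating dyads? Default drops them.
#' @export
write_edge_list <- function(net, path, keep_zero = FALSE) {
  stopifnot(inherits(net, "assoc_network"))
  idx <- which(upper.tri(net$sri), arr.ind = TRUE)
  edges <- data.frame(id_i = net$ids[idx[, 1]], id_j = net$ids[idx[, 2]],
                      sri = net$sri[idx])
  if (!keep_zero) edges <- edges[edges$sri > 0, , drop = FALSE]
  write.csv(edges, path, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list CSV back into an association network
#'
#' @param path CSV with columns `id_i,id_j,sri`.
#' @param ids optional roster; ids absent from the edge list become isolated
#'   nodes.
#' @return `assoc_network` object.
#' @export
read_edge_list <- function(path, ids = NULL) {
  edges <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id_i", "id_j", "sri") %in% names(edges)))
    stop("edge list must have columns id_i,id_j,sri")
  if (is.null(ids)) ids <- sort(unique(c(edges$id_i, edges$id_j)))
  sri <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  sri[cbind(match(edges$id_i, ids), match(edges$id_j, ids))] <- edges$sri
  sri[cbind(match(edges$id_j, ids), match(edges$id_i, ids))] <- edges$sri
  structure(list(ids = ids, sri = sri, n_scans = NA_integer_),
            class = "assoc_network")
}
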