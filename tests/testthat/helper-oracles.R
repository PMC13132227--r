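# Independent oracle implementations, deliberately written as plain
# brute-force code separate from the package's computational paths.

# probability of one complete acquisition order under the diffusion model,
# computed with naive per-event loops
oracle_order_prob <- function(order, net, s, risk, seeded) {
  informed <- risk %in% seeded
  names(informed) <- risk
  prob <- 1
  for (learner in order) {
    rates <- c()
    for (id in setdiff(risk, names(informed)[informed])) {
      conn <- 0
      for (j in risk[informed[risk]]) {
        if (id %in% net$ids && j %in% net$ids) conn <- conn + net$sri[id, j]
      }
      rates[id] <- s * conn + 1
    }
    prob <- prob * rates[[learner]] / sum(rates)
    informed[learner] <- TRUE
  }
  prob
}

oracle_all_orders <- function(items) {
  if (length(items) <= 1) return(list(items))
  out <- list()
  for (i in seq_along(items))
    for (rest in oracle_all_orders(items[-i]))
      out[[length(out) + 1]] <- c(items[i], rest)
  out
}

# step-by-step EWA log-likelihood recomputation: explicit window scans and
# probability arithmetic, no shared helpers with the package
oracle_ewa_loglik <- function(events, individuals, params, strategy,
                              window = 60) {
  A <- matrix(0, nrow(individuals), 2,
              dimnames = list(individuals$id, c("red", "blue")))
  for (i in seq_len(nrow(individuals)))
    if (!is.na(individuals$tutored_option[i]))
      A[i, individuals$tutored_option[i]] <- 1
  get_par <- function(p, id) if (length(p) == 1) p else p[[id]]
  ll <- 0
  for (i in seq_len(nrow(events))) {
    id <- events$individual_id[i]
    if (!(id %in% individuals$id)) next
    lam <- get_par(params$lambda, id); phi <- get_par(params$phi, id)
    e_red <- exp(lam * A[id, "red"]); e_blue <- exp(lam * A[id, "blue"])
    I <- c(red = e_red, blue = e_blue) / (e_red + e_blue)
    P <- I
    if (strategy != "individual_only") {
      gam <- get_par(params$gamma, id)
      n <- c(red = 0, blue = 0); n_cat <- c(red = 0, blue = 0)
      my_roost <- individuals$roost[match(id, individuals$id)]
      for (j in seq_len(nrow(events))) {
        if (j == i) next
        if (events$site[j] != events$site[i]) next
        dt <- events$time[i] - events$time[j]
        if (dt <= 0 || dt > window) next
        if (events$individual_id[j] == id) next
        opt <- events$option[j]
        n[opt] <- n[opt] + 1
        m <- match(events$individual_id[j], individuals$id)
        if (!is.na(m)) {
          if (strategy == "male_bias" && individuals$sex_class[m] == "male")
            n_cat[opt] <- n_cat[opt] + 1
          if (strategy == "age_bias" && individuals$age_class[m] == "adult")
            n_cat[opt] <- n_cat[opt] + 1
          if (strategy == "roost_bias" && individuals$roost[m] == my_roost &&
              individuals$roost[m] != "unknown")
            n_cat[opt] <- n_cat[opt] + 1
        }
      }
      S <- NULL
      if (strategy == "frequency" && sum(n) > 0) {
        fv <- get_par(params$f, id)
        S <- n^fv / sum(n^fv)
      } else if (strategy %in% c("male_bias", "age_bias") && sum(n_cat) > 0) {
        S <- n_cat / sum(n_cat)
      } else if (strategy == "roost_bias" && sum(n) > 0) {
        bv <- get_par(params$beta, id)
        w <- n_cat * exp(bv) + (n - n_cat)
        S <- w / sum(w)
      }
      if (!is.null(S)) P <- (1 - gam) * I + gam * S
    }
    ll <- ll + log(max(P[[events$option[i]]], 1e-12))
    A[id, events$option[i]] <-
      (1 - phi) * A[id, events$option[i]] + phi * events$success[i]
  }
  ll
}

# WAIC by direct formula on a draws-by-observations log-likelihood matrix
oracle_waic <- function(ll) {
  lppd <- sum(log(colMeans(exp(ll))))
  pwaic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - pwaic), pwaic = pwaic, lppd = lppd)
}

# brute-force SRI from a scan table
oracle_sri <- function(scans, a, b) {
  scan_ids <- unique(scans$scan_id)
  both <- either <- 0
  for (s in scan_ids) {
    present <- scans$individual_id[scans$scan_id == s]
    in_a <- a %in% present; in_b <- b %in% present
    if (in_a && in_b) both <- both + 1
    if (in_a || in_b) either <- either + 1
  }
  if (either == 0) 0 else both / either
}

# partial correlation of lower triangles, written independently
oracle_partial_r <- function(Dy, Dx, Dz) {
  lt <- lower.tri(Dy)
  y <- Dy[lt]; x <- Dx[lt]; z <- Dz[lt]
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}
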