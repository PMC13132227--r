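#' Construct a diffusion record for order-of-acquisition analysis
#'
#' A diffusion record holds, for each experimental site, the order in which
#' naive individuals first performed the target behaviour, together with the
#' risk set (everyone available to learn at that site) and the individuals
#' already informed when the diffusion started (trained demonstrators, and
#' knowledgeable movers arriving from another site).
#'
#' @param diffusions list; each element a list with fields `site` (scalar id),
#'   `learners` (character, acquisition order), `risk_set` (character) and
#'   `seeded_informed` (character, possibly empty).
#' @return object of class `diffusion_record`.
#' @export
diffusion_record <- function(diffusions) {
  stopifnot(is.list(diffusions), length(diffusions) >= 1L)
  for (d in diffusions) {
    if (!all(c("site", "learners", "risk_set") %in% names(d)))
      stop("each diffusion needs fields site, learners, risk_set")
    if (is.null(d$seeded_informed)) d$seeded_informed <- character()
    if (anyDuplicated(d$learners))
      stop("site ", d$site, ": an individual learns twice within one diffusion")
    if (!all(d$learners %in% d$risk_set))
      stop("site ", d$site, ": learner(s) outside the risk set: ",
           paste(setdiff(d$learners, d$risk_set), collapse = ", "))
    if (length(intersect(d$seeded_informed, d$learners)))
      stop("site ", d$site, ": seeded individual(s) recorded as learners: ",
           paste(intersect(d$seeded_informed, d$learners), collapse = ", "))
  }
  diffusions <- lapply(diffusions, function(d) {
    d$seeded_informed <- if (is.null(d$seeded_informed)) character() else
      as.character(d$seeded_informed)
    d$learners <- as.character(d$learners)
    d$risk_set <- as.character(d$risk_set)
    d
  })
  structure(list(diffusions = diffusions), class = "diffusion_record")
}

#' @export
print.diffusion_record <- function(x, ...) {
  for (d in x$diffusions)
    cat(sprintf("site %s: %d learners / %d at risk (%d seeded informed)\n",
                d$site, length(d$learners), length(d$risk_set),
                length(d$seeded_informed)))
  invisible(x)
}

#' Number of acquisition events in a diffusion record
#' @param record `diffusion_record`.
#' @return integer count of learning events across all diffusions.
#' @export
n_acquisition_events <- function(record) {
  stopifnot(inherits(record, "diffusion_record"))
  sum(vapply(record$diffusions, function(d) length(d$learners), integer(1)))
}

#' Individual-level variable design matrix
#'
#' Codes sex as -0.5 (female), 0.5 (male), 0 (unknown) and age as -0.5
#' (juvenile), 0.5 (adult), 0 (unknown), so that coefficients express
#' symmetric contrasts and unknown-class individuals sit at the baseline.
#'
#' @param individuals roster data frame (see [read_individuals()]).
#' @return numeric matrix with rownames = ids and columns `sex`, `age`.
#' @export
ilv_design <- function(individuals) {
  validate_individuals(individuals)
  sex <- c(female = -0.5, male = 0.5, unknown = 0)[individuals$sex_class]
  age <- c(juvenile = -0.5, adult = 0.5, unknown = 0)[individuals$age_class]
  x <- cbind(sex = unname(sex), age = unname(age))
  rownames(x) <- individuals$id
  x
}

#' Parameters of an order-of-acquisition diffusion model
#'
#' @param s social transmission rate (>= 0), scaled relative to the baseline
#'   asocial rate (which cancels from the order-of-acquisition likelihood).
#' @param gamma_social named coefficients of individual-level variables on the
#'   social learning rate.
#' @param beta_asocial named coefficients on the asocial learning rate.
#' @return list of class `nbda_params`.
#' @export
nbda_params <- function(s = 0, gamma_social = NULL, beta_asocial = NULL) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s < 0)
    stop("`s` must be a single non-negative number")
  structure(list(s = s,
                 gamma_social = gamma_social,
                 beta_asocial = beta_asocial),
            class = "nbda_params")
}

# linear predictor exp(coef . x_i) for the ids given; 1 when no coefficients
.rate_multiplier <- function(coefs, ilvs, ids) {
  if (is.null(coefs) || length(coefs) == 0L) return(setNames(rep(1, length(ids)), ids))
  if (is.null(ilvs)) stop("ILV coefficients supplied but no ILV design matrix")
  miss <- setdiff(ids, rownames(ilvs))
  if (length(miss)) stop("ids missing from ILV design: ", paste(miss, collapse = ", "))
  x <- ilvs[ids, names(coefs), drop = FALSE]
  setNames(exp(drop(x %*% coefs)), ids)
}

#' Negative log-likelihood of an order-of-acquisition diffusion model
#'
#' At each acquisition event the probability that naive individual i is the
#' next learner is proportional to its total learning rate
#' \deqn{R_i = e^{\Gamma x_i}\, s \sum_j a_{ij} z_j + e^{B x_i}}
#' where \eqn{a_{ij}} is the association (SRI) between i and j, \eqn{z_j}
#' indicates that j is informed, \eqn{\Gamma} and \eqn{B} are coefficients of
#' individual-level variables on the social and asocial rates, and the
#' baseline asocial rate cancels from the order likelihood. Each event
#' contributes \eqn{-\log(R_{learner}/\sum_{naive} R)}; informed status is
#' updated after each event and contributions are summed over diffusions.
#'
#' @param record `diffusion_record`.
#' @param net `assoc_network` covering (at least) all non-isolated individuals;
#'   ids absent from the network are treated as isolated (no connections).
#' @param params `nbda_params`.
#' @param ilvs optional ILV design matrix from [ilv_design()].
#' @return scalar negative log-likelihood. Attribute `"per_event"` carries the
#'   per-event negative log probabilities.
#' @export
oada_negloglik <- function(record, net, params, ilvs = NULL) {
  stopifnot(inherits(record, "diffusion_record"), inherits(net, "assoc_network"),
            inherits(params, "nbda_params"))
  per_event <- numeric(0)
  for (d in record$diffusions) {
    ids <- d$risk_set
    soc_mult <- .rate_multiplier(params$gamma_social, ilvs, ids)
    aso_mult <- .rate_multiplier(params$beta_asocial, ilvs, ids)
    a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    known <- intersect(ids, net$ids)
    a[known, known] <- net$sri[known, known]
    informed <- ids %in% d$seeded_informed
    naive <- !informed
    for (learner in d$learners) {
      li <- match(learner, ids)
      if (is.na(li) || !naive[li])
        stop("learner ", learner, " not naive in risk set at its event")
      conn <- drop(a[, informed, drop = FALSE] %*% rep(1, sum(informed)))
      rate <- soc_mult * params$s * conn + aso_mult
      denom <- sum(rate[naive])
      if (denom <= 0)
        stop("all-zero learning rates at event where ", learner, " learned")
      per_event <- c(per_event, -log(rate[li] / denom))
      informed[li] <- TRUE
      naive[li] <- FALSE
    }
  }
  structure(sum(per_event), per_event = per_event)
}

#' Fit an order-of-acquisition diffusion model by maximum likelihood
#'
#' Fits the model of [oada_negloglik()] with the social transmission rate
#' log-parameterised (so the constraint s >= 0 is implicit) and multiple
#' deterministic starting values to avoid boundary local optima. Asocial
#' models fix s = 0.
#'
#' @param record `diffusion_record`.
#' @param net `assoc_network`.
#' @param ilvs ILV design matrix (required if any ILV set is non-empty).
#' @param social logical; include the social transmission term?
#' @param social_ilvs,asocial_ilvs character vectors naming ILV columns acting
#'   on the social / asocial rate (social ILVs require `social = TRUE`).
#' @param n_start number of optimisation starts over a fixed log-s grid.
#' @return object of class `oada_fit` with elements `params`, `logLik`, `k`
#'   (free parameters), `n_events`, `converged`, `social`, `name`.
#' @export
fit_oada <- function(record, net, ilvs = NULL, social = TRUE,
                     social_ilvs = character(), asocial_ilvs = character(),
                     n_start = 5L) {
  stopifnot(inherits(record, "diffusion_record"))
  if (!social && length(social_ilvs))
    stop("social ILVs require a social model")
  n_events <- n_acquisition_events(record)
  k <- as.integer(social) + length(social_ilvs) + length(asocial_ilvs)
  if (n_events < k)
    warning("fewer acquisition events (", n_events, ") than free parameters (",
            k, "); estimates may be unidentifiable")
  make_params <- function(theta) {
    i <- 0L
    s <- 0
    if (social) { i <- i + 1L; s <- exp(theta[i]) }
    g <- NULL
    if (length(social_ilvs)) {
      g <- setNames(theta[i + seq_along(social_ilvs)], social_ilvs)
      i <- i + length(social_ilvs)
    }
    b <- NULL
    if (length(asocial_ilvs))
      b <- setNames(theta[i + seq_along(asocial_ilvs)], asocial_ilvs)
    nbda_params(s = s, gamma_social = g, beta_asocial = b)
  }
  objective <- function(theta) {
    nll <- try(as.numeric(oada_negloglik(record, net, make_params(theta), ilvs)),
               silent = TRUE)
    if (inherits(nll, "try-error") || !is.finite(nll)) 1e10 else nll
  }
  if (k == 0L) {
    nll <- as.numeric(oada_negloglik(record, net, nbda_params(0), ilvs))
    fit <- list(par = numeric(0), value = nll, convergence = 0L)
  } else {
    s_grid <- log(c(0.01, 0.5, 2, 10, 50, 250, 1000))
    n_start <- max(1L, min(n_start, length(s_grid)))
    starts <- lapply(seq_len(n_start), function(j) {
      theta0 <- rep(0, k)
      if (social) theta0[1] <- s_grid[j]
      theta0
    })
    fits <- lapply(starts, function(theta0)
      optim(theta0, objective, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)))
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }
  structure(list(params = make_params(fit$par),
                 logLik = -fit$value,
                 k = k,
                 n_events = n_events,
                 converged = (fit$convergence == 0L),
                 social = social,
                 social_ilvs = social_ilvs,
                 asocial_ilvs = asocial_ilvs,
                 name = paste0(if (social) "social" else "asocial",
                               if (length(social_ilvs))
                                 paste0("+soc(", paste(social_ilvs, collapse = ","), ")") else "",
                               if (length(asocial_ilvs))
                                 paste0("+aso(", paste(asocial_ilvs, collapse = ","), ")") else "")),
            class = "oada_fit")
}

#' @export
print.oada_fit <- function(x, ...) {
  cat(sprintf("OADA fit [%s]: logLik = %.3f, k = %d, s = %.4g%s\n",
              x$name, x$logLik, x$k, x$params$s,
              if (!x$converged) " (NOT converged)" else ""))
  invisible(x)
}

#' Fit every combination of ILVs with and without social transmission
#'
#' Builds the full candidate set: social on/off crossed with every subset of
#' the ILVs entering the social rate (social models only) and the asocial
#' rate.
#'
#' @inheritParams fit_oada
#' @param ilv_names character vector of ILV columns to consider (default all
#'   columns of `ilvs`; use `character()` for the two null models only).
#' @return list of `oada_fit` objects.
#' @export
fit_oada_all <- function(record, net, ilvs = NULL,
                         ilv_names = colnames(ilvs)) {
  if (is.null(ilv_names)) ilv_names <- character()
  subsets <- function(x) {
    out <- list(character())
    for (k in seq_along(x))
      out <- c(out, combn(x, k, simplify = FALSE))
    out
  }
  fits <- list()
  for (aso in subsets(ilv_names)) {
    fits[[length(fits) + 1L]] <-
      fit_oada(record, net, ilvs, social = FALSE, asocial_ilvs = aso)
    for (soc in subsets(ilv_names))
      fits[[length(fits) + 1L]] <-
        fit_oada(record, net, ilvs, social = TRUE,
                 social_ilvs = soc, asocial_ilvs = aso)
  }
  fits
}

#' AICc model comparison table for diffusion fits
#'
#' Computes AICc = 2k - 2 lnL + 2k(k+1)/(n - k - 1) with n the total number
#' of acquisition events, Akaike weights, and summed weights for the social
#' and asocial model families.
#'
#' @param fits list of `oada_fit` objects fitted to the same data.
#' @param n_events number of acquisition events; defaults to the fits' shared
#'   value.
#' @return data frame sorted by AICc with columns `model`, `social`, `k`,
#'   `logLik`, `AICc`, `dAICc`, `weight`; attribute `"family_weights"` holds
#'   the social/asocial summed weights.
#' @export
aicc_model_table <- function(fits, n_events = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "oada_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n_events")
  if (length(unique(ns)) != 1L)
    stop("fits were not computed on identical data (n_events differ)")
  if (is.null(n_events)) n_events <- ns[1]
  k <- vapply(fits, `[[`, numeric(1), "k")
  if (any(n_events <= k + 1))
    stop("AICc undefined: n_events <= k + 1 for model(s) ",
         paste(vapply(fits, `[[`, character(1), "name")[n_events <= k + 1],
               collapse = ", "))
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  aicc <- 2 * k - 2 * ll + 2 * k * (k + 1) / (n_events - k - 1)
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w <- w / sum(w)
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "name"),
                    social = vapply(fits, `[[`, logical(1), "social"),
                    k = k, logLik = ll, AICc = aicc, dAICc = d, weight = w,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  attr(tab, "family_weights") <- c(social = sum(tab$weight[tab$social]),
                                   asocial = sum(tab$weight[!tab$social]))
  tab
}

# mean social fraction over observed events at given parameter values
.social_fraction_mean <- function(record, net, params, ilvs) {
  fracs <- numeric(0)
  for (d in record$diffusions) {
    ids <- d$risk_set
    soc_mult <- .rate_multiplier(params$gamma_social, ilvs, ids)
    aso_mult <- .rate_multiplier(params$beta_asocial, ilvs, ids)
    a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    known <- intersect(ids, net$ids)
    a[known, known] <- net$sri[known, known]
    informed <- ids %in% d$seeded_informed
    for (learner in d$learners) {
      li <- match(learner, ids)
      conn <- sum(a[li, informed])
      social <- soc_mult[li] * params$s * conn
      asocial <- aso_mult[li]
      fracs <- c(fracs, social / (social + asocial))
      informed[li] <- TRUE
    }
  }
  fracs
}

#' Estimated percentage of learning events due to social transmission
#'
#' For every observed acquisition event, the fitted model splits the learner's
#' total rate into its social and asocial terms; the social fraction of event
#' e is \eqn{social_e / (social_e + asocial_e)}. The estimate is the mean over
#' events (in percent). The confidence interval re-evaluates that mean at the
#' bounds of a profile-likelihood interval for s (other parameters
#' re-optimised at each fixed s).
#'
#' @param fit fitted social `oada_fit`.
#' @param record,net,ilvs the data the model was fitted to.
#' @param level confidence level for the profile interval (default 0.95).
#' @return list with `estimate` (percent), `ci` (length-2 percent vector),
#'   `per_event` (per-event social fractions) and `s_ci`.
#' @export
percent_social <- function(fit, record, net, ilvs = NULL, level = 0.95) {
  stopifnot(inherits(fit, "oada_fit"))
  if (!fit$social) stop("percent_social requires a social model fit")
  fracs <- .social_fraction_mean(record, net, fit$params, ilvs)
  est <- 100 * mean(fracs)
  crit <- qchisq(level, df = 1) / 2
  profile_nll <- function(s) {
    coef_names <- c(fit$social_ilvs, fit$asocial_ilvs)
    if (!length(coef_names)) {
      p <- nbda_params(s, fit$params$gamma_social, fit$params$beta_asocial)
      return(list(nll = as.numeric(oada_negloglik(record, net, p, ilvs)), params = p))
    }
    obj <- function(th) {
      g <- if (length(fit$social_ilvs))
        setNames(th[seq_along(fit$social_ilvs)], fit$social_ilvs) else NULL
      b <- if (length(fit$asocial_ilvs))
        setNames(th[length(fit$social_ilvs) + seq_along(fit$asocial_ilvs)],
                 fit$asocial_ilvs) else NULL
      as.numeric(oada_negloglik(record, net, nbda_params(s, g, b), ilvs))
    }
    o <- optim(rep(0, length(coef_names)), obj, method = "BFGS")
    g <- if (length(fit$social_ilvs))
      setNames(o$par[seq_along(fit$social_ilvs)], fit$social_ilvs) else NULL
    b <- if (length(fit$asocial_ilvs))
      setNames(o$par[length(fit$social_ilvs) + seq_along(fit$asocial_ilvs)],
               fit$asocial_ilvs) else NULL
    list(nll = o$value, params = nbda_params(s, g, b))
  }
  nll_hat <- min(-fit$logLik, profile_nll(fit$params$s)$nll)
  dev <- function(s) profile_nll(s)$nll - nll_hat - crit
  s_hat <- max(fit$params$s, 1e-12)
  # lower bound: walk down geometrically until the profile crosses
  s_lo <- 0
  if (dev(0) > 0) {
    lo <- s_hat
    while (dev(lo) < 0 && lo > 1e-10) lo <- lo / 10
    s_lo <- if (dev(lo) < 0) 0 else
      uniroot(dev, c(lo, s_hat), tol = 1e-8)$root
  }
  # upper bound: expand until the profile crosses, cap at a very large s
  s_cap <- max(1e6, s_hat * 1e4)
  s_hi <- if (dev(s_cap) <= 0) Inf else
    uniroot(dev, c(s_hat, s_cap), tol = 1e-6)$root
  frac_at <- function(s) {
    if (!is.finite(s)) s <- s_cap
    p <- profile_nll(s)$params
    100 * mean(.social_fraction_mean(record, net, p, ilvs))
  }
  ci <- sort(c(frac_at(s_lo), frac_at(s_hi)))
  list(estimate = est, ci = ci, per_event = fracs, s_ci = c(s_lo, s_hi))
}

#' Simulate a diffusion through an association network
#'
#' Generative mirror of the order-of-acquisition likelihood: starting from the
#' seeded informed individuals, the next learner is repeatedly drawn from the
#' naive risk set with probability proportional to its total learning rate
#' (see [oada_negloglik()]), until `n_events` individuals have learned or
#' no naive individual remains.
#'
#' @param net `assoc_network`.
#' @param params `nbda_params` (s >= 0).
#' @param risk_set character ids available at the site.
#' @param seeded_informed character ids informed at the start (subset of
#'   `risk_set`); they transmit but never appear as learners.
#' @param ilvs optional ILV design matrix.
#' @param n_events stop after this many learning events (default: all naive
#'   individuals learn).
#' @param site site label for the record.
#' @param seed optional integer seed for reproducibility.
#' @return `diffusion_record` with a single diffusion. Attribute
#'   `"social_fraction"` holds the realised per-event social fractions of the
#'   drawn learners (generative ground truth for percent-social recovery).
#' @export
simulate_diffusion <- function(net, params, risk_set, seeded_informed = character(),
                               ilvs = NULL, n_events = NULL, site = "sim",
                               seed = NULL) {
  stopifnot(inherits(net, "assoc_network"), inherits(params, "nbda_params"))
  risk_set <- as.character(risk_set)
  if (!length(risk_set)) stop("empty risk set")
  if (!all(seeded_informed %in% risk_set))
    stop("seeded_informed must be a subset of the risk set")
  if (!is.null(seed)) set.seed(seed)
  ids <- risk_set
  soc_mult <- .rate_multiplier(params$gamma_social, ilvs, ids)
  aso_mult <- .rate_multiplier(params$beta_asocial, ilvs, ids)
  a <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  known <- intersect(ids, net$ids)
  a[known, known] <- net$sri[known, known]
  informed <- ids %in% seeded_informed
  max_events <- sum(!informed)
  if (is.null(n_events)) n_events <- max_events
  n_events <- min(n_events, max_events)
  learners <- character(0)
  fracs <- numeric(0)
  while (length(learners) < n_events) {
    naive <- which(!informed)
    conn <- drop(a[naive, informed, drop = FALSE] %*% rep(1, sum(informed)))
    social <- soc_mult[naive] * params$s * conn
    asocial <- aso_mult[naive]
    rate <- social + asocial
    pick <- naive[sample.int(length(naive), 1L, prob = rate)]
    j <- match(pick, naive)
    fracs <- c(fracs, social[j] / rate[j])
    learners <- c(learners, ids[pick])
    informed[pick] <- TRUE
  }
  rec <- diffusion_record(list(list(site = site, learners = learners,
                                    risk_set = ids,
                                    seeded_informed = as.character(seeded_informed))))
  attr(rec, "social_fraction") <- fracs
  rec
}

#' Read diffusion data from CSV
#'
#' Expects columns `site,event_index,individual_id,status` with status one of
#' `learner`, `seeded`, `present_only`. Learners are ordered by `event_index`
#' within site; `seeded` rows mark individuals informed at the diffusion's
#' start; `present_only` rows complete the risk set.
#'
#' @param path CSV file path.
#' @return `diffusion_record`.
#' @export
read_diffusion <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "event_index", "individual_id", "status")
  if (!all(need %in% names(df)))
    stop("diffusion file must have columns ", paste(need, collapse = ","))
  bad <- setdiff(unique(df$status), c("learner", "seeded", "present_only"))
  if (length(bad)) stop("invalid status value(s): ", paste(bad, collapse = ", "))
  diffusions <- lapply(split(df, df$site), function(d) {
    learners <- d[d$status == "learner", , drop = FALSE]
    learners <- learners[order(learners$event_index), , drop = FALSE]
    list(site = d$site[1],
         learners = learners$individual_id,
         risk_set = unique(d$individual_id),
         seeded_informed = unique(d$individual_id[d$status == "seeded"]))
  })
  diffusion_record(unname(diffusions))
}

#' Write a diffusion record to CSV
#'
#' Inverse of [read_diffusion()].
#' @param record `diffusion_record`.
#' @param path output CSV path.
#' @export
write_diffusion <- function(record, path) {
  stopifnot(inherits(record, "diffusion_record"))
  rows <- do.call(rbind, lapply(record$diffusions, function(d) {
    others <- setdiff(d$risk_set, c(d$learners, d$seeded_informed))
    data.frame(site = d$site,
               event_index = c(seq_along(d$learners),
                               rep(0L, length(d$seeded_informed) + length(others))),
               individual_id = c(d$learners, d$seeded_informed, others),
               status = c(rep("learner", length(d$learners)),
                          rep("seeded", length(d$seeded_informed)),
                          rep("present_only", length(others))),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
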