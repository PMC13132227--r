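## Hierarchical Bayesian fitting of the EWA strategy models.
##
## Each of lambda (log link), phi (logit), gamma (logit), f (log) and beta
## (identity) gets a group-level mean per observed (age x sex) cell plus a
## zero-centred individual offset with its own scale; cells with no choosers
## are dropped from the design. Priors: Normal(0, 1) on cell means (link
## scale), offsets Normal(0, sigma_p) with sigma_p ~ Exponential(1).

.ewa_active <- function(strategy) {
  switch(strategy,
         individual_only = c(0L, 1L),
         frequency = c(0L, 1L, 2L, 3L),
         male_bias = c(0L, 1L, 2L),
         age_bias = c(0L, 1L, 2L),
         roost_bias = c(0L, 1L, 2L, 4L))
}

.ewa_par_names <- c("lambda", "phi", "gamma", "f", "beta")

.ewa_linkinv <- function(par_name, x) {
  switch(par_name,
         lambda = exp(pmin(x, 30)),
         f = exp(pmin(x, 30)),
         phi = stats::plogis(x),
         gamma = stats::plogis(x),
         beta = x)
}

# prep (from ewa_prepare) -> data list for the compiled sampler
.ewa_cpp_data <- function(prep, strategy) {
  n_ind <- length(prep$choosers)
  tab <- tabulate(prep$chooser_idx, nbins = n_ind)
  cmat <- function(type) matrix(prep$counts[, type, ], ncol = prep$n_options)
  list(ptr = as.integer(c(0L, cumsum(tab))),
       choice = as.integer(prep$choice),
       payoff = as.numeric(prep$payoff),
       N = cmat("N"), male = cmat("male"), adult = cmat("adult"),
       same = cmat("same_roost"),
       A0 = prep$A0,
       strategy = match(strategy, ewa_strategies()) - 1L)
}

# split-chain R-hat and a truncated-autocorrelation effective sample size
.rhat <- function(mat_by_chain) {
  half <- lapply(mat_by_chain, function(m) {
    n <- floor(nrow(m) / 2)
    list(m[seq_len(n), , drop = FALSE], m[n + seq_len(n), , drop = FALSE])
  })
  chains <- do.call(c, lapply(half, function(h) h))
  apply_cols <- function(f) vapply(seq_len(ncol(chains[[1]])), function(j) {
    f(lapply(chains, function(m) m[, j]))
  }, numeric(1))
  apply_cols(function(xs) {
    n <- length(xs[[1]])
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, var, numeric(1))
    B <- n * var(means)
    W <- mean(vars)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  })
}

.ess <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac < 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  max(1, n / (1 + 2 * sum(ac)))
}

#' Fit a hierarchical EWA strategy model by MCMC
#'
#' Samples the posterior of the group-level (age x sex cell) means, individual
#' offsets and offset scales of the active EWA parameters for the chosen
#' strategy, using an adaptive Metropolis-within-Gibbs sampler over the
#' compiled likelihood. Because window tallies depend only on the observed
#' data, the likelihood factorises over individuals and all block updates use
#' exact conditional ratios.
#'
#' @param events time-sorted event data frame (see [read_events()]).
#' @param individuals roster.
#' @param strategy one of `individual_only`, `frequency`, `male_bias`,
#'   `age_bias`, `roost_bias`.
#' @param window social window in seconds (default 60).
#' @param demos demonstrations counted in windows (`"all"` pickups or
#'   `"successful-only"`).
#' @param chains,warmup,samples MCMC configuration. Defaults (2 chains,
#'   500/500) are a reduced setting suitable for simulation studies; increase
#'   to 4 chains and 1000/1000 for final inference.
#' @param seed integer seed; chain c uses `seed + 1000 * (c - 1)`.
#' @param prior_only if `TRUE` the likelihood is dropped and the fit samples
#'   the prior (prior predictive check).
#' @param init_sd standard deviation of the random initialisation of cell
#'   means on the link scale.
#' @param thin full update sweeps per stored draw (warmup runs
#'   `warmup * thin` adaptation sweeps); raises the effective sample size per
#'   stored draw at negligible cost since the likelihood kernel is compiled.
#' @param priors list with `mu_sd` (sd of the Normal prior on link-scale cell
#'   means, default 1) and `sigma_rate` (rate of the Exponential prior on the
#'   individual-offset scales, default 1).
#' @return object of class `ewa_fit`: draws (all chains stacked, columns
#'   named `mu_<par>[<cell>]`, `sigma_<par>`, `off_<par>[<id>]`), pointwise
#'   log-likelihood matrix in event-time order, cell labels, diagnostics
#'   (R-hat, effective sample size), and the configuration. R-hat > 1.05 on
#'   any group-level parameter triggers a warning and `diagnostics$flagged`.
#' @export
fit_ewa <- function(events, individuals, strategy = ewa_strategies(),
                    window = 60, demos = c("all", "successful-only"),
                    chains = 2L, warmup = 500L, samples = 500L, seed = 1L,
                    prior_only = FALSE, init_sd = 0.5, thin = 10L,
                    priors = list(mu_sd = 1, sigma_rate = 1)) {
  strategy <- match.arg(strategy)
  demos <- match.arg(demos)
  prep <- ewa_prepare(events, individuals, window = window, demos = demos)
  if (!length(prep$choosers)) stop("no marked choosers in `events`")
  active <- .ewa_active(strategy)
  par_names <- .ewa_par_names[active + 1L]
  cell_label <- paste(prep$age, prep$sex, sep = ":")
  cells <- sort(unique(cell_label))
  cell_of <- match(cell_label, cells)
  dat <- .ewa_cpp_data(prep, strategy)
  col_names <- c(
    unlist(lapply(par_names, function(p) sprintf("mu_%s[%s]", p, cells))),
    sprintf("sigma_%s", par_names),
    unlist(lapply(par_names, function(p) sprintf("off_%s[%s]", p, prep$choosers))))
  runs <- lapply(seq_len(chains), function(ch) {
    set.seed(seed + 1000L * (ch - 1L))
    ewa_mcmc(dat, as.integer(cell_of - 1L), length(cells),
             as.integer(active), as.integer(warmup), as.integer(samples),
             prior_only, init_sd, as.integer(thin),
             priors$mu_sd %||% 1, priors$sigma_rate %||% 1)
  })
  draws <- do.call(rbind, lapply(runs, `[[`, "draws"))
  colnames(draws) <- col_names
  chain_id <- rep(seq_len(chains), each = samples)
  ord_back <- order(prep$event_order)
  pointwise <- if (prior_only) NULL else
    do.call(rbind, lapply(runs, `[[`, "pointwise"))[, ord_back, drop = FALSE]
  group_cols <- seq_len(length(par_names) * length(cells) + length(par_names))
  rhat <- .rhat(lapply(runs, `[[`, "draws"))
  names(rhat) <- col_names
  ess <- vapply(group_cols, function(j) .ess(draws[, j]), numeric(1))
  names(ess) <- col_names[group_cols]
  flagged <- any(rhat[group_cols] > 1.05, na.rm = TRUE)
  if (flagged)
    warning("R-hat > 1.05 for: ",
            paste(names(rhat[group_cols])[rhat[group_cols] > 1.05], collapse = ", "))
  structure(list(strategy = strategy, draws = draws, chain = chain_id,
                 pointwise = pointwise, par_names = par_names, cells = cells,
                 choosers = prep$choosers, cell_of = cell_of,
                 n_events = length(prep$choice),
                 diagnostics = list(rhat = rhat, ess = ess, flagged = flagged),
                 config = list(window = window, demos = demos, chains = chains,
                               warmup = warmup, samples = samples, seed = seed,
                               prior_only = prior_only)),
            class = "ewa_fit")
}

#' @export
print.ewa_fit <- function(x, ...) {
  cat(sprintf("EWA fit [%s]: %d choosers, %d events, %d chains x %d draws%s\n",
              x$strategy, length(x$choosers), x$n_events,
              x$config$chains, x$config$samples,
              if (isTRUE(x$diagnostics$flagged)) "  ** convergence flagged **" else ""))
  invisible(x)
}

#' Extract natural-scale cell-mean draws for one EWA parameter
#'
#' Applies the parameter's inverse link to the posterior draws of the
#' group-level cell means.
#'
#' @param fit `ewa_fit`.
#' @param par parameter name (`lambda`, `phi`, `gamma`, `f`, `beta`).
#' @return draws matrix with one column per (age:sex) cell.
#' @export
extract_cell_draws <- function(fit, par) {
  stopifnot(inherits(fit, "ewa_fit"))
  if (!par %in% fit$par_names)
    stop("parameter ", par, " is not active in strategy ", fit$strategy)
  cols <- sprintf("mu_%s[%s]", par, fit$cells)
  out <- .ewa_linkinv(par, fit$draws[, cols, drop = FALSE])
  colnames(out) <- fit$cells
  out
}

.waic_parts <- function(pointwise) {
  # pointwise: draws x events matrix of log-likelihoods
  n <- ncol(pointwise)
  mx <- apply(pointwise, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(pointwise, 2, mx)))) # log mean exp
  p_i <- apply(pointwise, 2, var)
  waic_i <- -2 * (lppd_i - p_i)
  list(waic = sum(waic_i), se = sqrt(n * var(waic_i)),
       pwaic = sum(p_i), lppd = sum(lppd_i), pointwise = waic_i)
}

#' WAIC from an EWA fit
#'
#' Widely applicable information criterion, WAIC = -2(lppd - pWAIC), from the
#' pointwise posterior log-likelihood draws; pWAIC is the summed pointwise
#' posterior variance of the log-likelihood.
#'
#' @param fit `ewa_fit` (not prior-only).
#' @return list with `waic`, `se`, `pwaic`, `lppd` and the per-event WAIC
#'   contributions.
#' @export
ewa_waic <- function(fit) {
  stopifnot(inherits(fit, "ewa_fit"))
  if (is.null(fit$pointwise)) stop("fit has no pointwise log-likelihood (prior only?)")
  .waic_parts(fit$pointwise)
}

#' WAIC comparison table across strategy models
#'
#' Mirrors the standard WAIC comparison layout: WAIC, its standard error,
#' differences to the best model with paired-difference standard errors,
#' effective number of parameters, and Akaike-style weights.
#'
#' @param fits named list of `ewa_fit` objects sharing the same event set.
#' @return data frame (sorted by WAIC) with columns `model`, `WAIC`, `SE`,
#'   `dWAIC`, `dSE`, `pWAIC`, `weight`.
#' @export
waic_table <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "ewa_fit")))
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, `[[`, character(1), "strategy")
  n_ev <- vapply(fits, function(f) ncol(f$pointwise), integer(1))
  if (length(unique(n_ev)) != 1L)
    stop("fits have mismatched pointwise lengths (different event sets)")
  parts <- lapply(fits, ewa_waic)
  waic <- vapply(parts, `[[`, numeric(1), "waic")
  best <- which.min(waic)
  d <- waic - waic[best]
  dse <- vapply(seq_along(parts), function(m) {
    if (m == best) return(NA_real_)
    dd <- parts[[m]]$pointwise - parts[[best]]$pointwise
    sqrt(length(dd) * var(dd))
  }, numeric(1))
  w <- exp(-d / 2)
  w <- w / sum(w)
  tab <- data.frame(model = names(fits),
                    WAIC = waic,
                    SE = vapply(parts, `[[`, numeric(1), "se"),
                    dWAIC = d, dSE = dse,
                    pWAIC = vapply(parts, `[[`, numeric(1), "pwaic"),
                    weight = w, stringsAsFactors = FALSE)
  tab <- tab[order(tab$WAIC), ]
  rownames(tab) <- NULL
  tab
}

#' Posterior summaries of EWA group-level parameters
#'
#' Natural-scale per-cell summaries of the group-level means: posterior mean,
#' sd, central credible interval, and -- for parameters named in
#' `thresholds` -- the proportion of posterior mass above the threshold
#' (default: conformity exponent f > 1).
#'
#' @param fit `ewa_fit`.
#' @param prob credible-interval mass (default 0.9).
#' @param thresholds named numeric vector of natural-scale thresholds.
#' @return data frame with one row per (parameter, cell).
#' @export
posterior_summary <- function(fit, prob = 0.9, thresholds = c(f = 1)) {
  stopifnot(inherits(fit, "ewa_fit"))
  a <- (1 - prob) / 2
  rows <- lapply(fit$par_names, function(p) {
    dr <- extract_cell_draws(fit, p)
    data.frame(parameter = p, cell = colnames(dr),
               mean = colMeans(dr),
               sd = apply(dr, 2, sd),
               lower = apply(dr, 2, quantile, probs = a),
               upper = apply(dr, 2, quantile, probs = 1 - a),
               prop_above = if (p %in% names(thresholds))
                 colMeans(dr > thresholds[[p]]) else NA_real_,
               threshold = if (p %in% names(thresholds))
                 thresholds[[p]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
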