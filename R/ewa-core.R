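## Experience-weighted attraction (EWA) building blocks.
##
## The model combines, per choice, an individual component (softmax over
## reinforcement-updated attraction scores) and a social component (function
## of the demonstrations observed in the preceding time window), weighted by
## gamma. Internals are K-option generic; the packaged I/O assumes the
## two-option (red/blue) task.

#' Option labels of the two-choice task
#' @return character vector `c("red", "blue")`.
#' @export
ewa_options <- function() c("red", "blue")

#' Names of the implemented EWA strategy models
#' @return character vector of the five strategy names.
#' @export
ewa_strategies <- function()
  c("individual_only", "frequency", "male_bias", "age_bias", "roost_bias")

#' Update an attraction score with a realised payoff
#'
#' \eqn{A' = (1 - \phi) A + \phi \pi}. Only the chosen option's attraction is
#' updated. With payoffs in \{0, 1\}, \eqn{\phi \in [0, 1]} and initial
#' attractions in \[0, 1\], attractions remain in \[0, 1\]. \eqn{\phi = 0}
#' means the individual never updates its initial state; \eqn{\phi = 1} means
#' no memory beyond the latest payoff.
#'
#' @param A current attraction score (scalar).
#' @param payoff realised payoff (1 = successful opening, 0 otherwise).
#' @param phi recent-experience weight in \[0, 1\].
#' @return updated attraction score.
#' @export
update_attraction <- function(A, payoff, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || is.na(phi) || phi < 0 || phi > 1)
    stop("`phi` must be a single number in [0, 1]")
  (1 - phi) * A + phi * payoff
}

#' Individual-component choice probabilities (softmax of attractions)
#'
#' \eqn{I_k = \exp(\lambda A_k) / \sum_m \exp(\lambda A_m)}. \eqn{\lambda = 0}
#' gives uniform choice; large \eqn{\lambda} approaches deterministic choice
#' of the highest attraction.
#'
#' @param A numeric attraction vector (one entry per option).
#' @param lambda sensitivity, >= 0.
#' @return probability vector summing to 1.
#' @export
individual_probs <- function(A, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0)
    stop("`lambda` must be a single non-negative number")
  z <- lambda * A
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Frequency-dependent social probabilities
#'
#' \eqn{S_k = N_k^f / \sum_m N_m^f}, where \eqn{N_k} counts demonstrations of
#' option k in the social window. f > 1 is conformist (disproportionate
#' copying of the majority), f = 1 unbiased, f < 1 anti-conformist.
#'
#' @param N non-negative demonstration counts per option.
#' @param f frequency-dependence exponent, > 0.
#' @return probability vector, or `NULL` (the "no social information"
#'   sentinel) when no demonstrations were observed.
#' @export
frequency_social_probs <- function(N, f) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0)
    stop("`f` must be a single positive number")
  if (any(N < 0)) stop("counts must be non-negative")
  if (sum(N) == 0) return(NULL)
  w <- N^f
  w / sum(w)
}

#' Cue-biased social probabilities (e.g., same-roost bias)
#'
#' Each observed demonstration is weighted \eqn{e^\beta} if the demonstrator
#' carries the cue (same roost as the focal individual) and 1 otherwise; the
#' reference (cue-absent) category weight is fixed to 1 so that \eqn{\beta}
#' is identified. Option probabilities are the normalised summed weights.
#' \eqn{\beta = 0} reduces to unbiased frequency dependence (f = 1).
#'
#' @param tally `social_tally` from [tally_social_window()].
#' @param beta cue-bias strength (any real).
#' @param cue which cue count to use; currently `"same_roost"`.
#' @return probability vector or `NULL` sentinel when the window was empty.
#' @export
cue_bias_social_probs <- function(tally, beta, cue = "same_roost") {
  stopifnot(inherits(tally, "social_tally"))
  cue <- match.arg(cue)
  if (sum(tally$N) == 0) return(NULL)
  cued <- tally[[cue]]
  w <- cued * exp(beta) + (tally$N - cued)
  w / sum(w)
}

#' Demonstrator-category social probabilities (male- or adult-biased copying)
#'
#' Unbiased frequency dependence (f = 1) computed on demonstrations by the
#' given demonstrator category only.
#'
#' @param tally `social_tally`.
#' @param category `"male"`, `"adult"`, or `"everyone"` (= plain frequency).
#' @return probability vector or `NULL` sentinel when the category produced
#'   no demonstrations in the window.
#' @export
category_social_probs <- function(tally, category = c("male", "adult", "everyone")) {
  stopifnot(inherits(tally, "social_tally"))
  category <- match.arg(category)
  N <- switch(category, male = tally$male, adult = tally$adult,
              everyone = tally$N)
  if (sum(N) == 0) return(NULL)
  N / sum(N)
}

#' Tally demonstrations in the social window preceding a choice
#'
#' Counts all demonstrations at the focal individual's site with time in the
#' half-open window \[t - window, t), excluding the focal's own events and
#' including events by unmarked individuals. Category counts (male, adult,
#' same-roost) require the roster; unmarked demonstrators count towards the
#' totals but not towards any category.
#'
#' @param events time-sorted data frame with columns `time` (numeric
#'   seconds), `site`, `individual_id`, `option`, `success`.
#' @param focal id of the choosing individual.
#' @param time time of the focal's choice.
#' @param site site of the focal's choice.
#' @param window window length in seconds (default 60).
#' @param individuals optional roster for category counts.
#' @param focal_roost roost of the focal (for same-roost counts); looked up
#'   from `individuals` when omitted.
#' @param demos count `"all"` pickups, or `"successful-only"`.
#' @param options option labels (default red/blue).
#' @return object of class `social_tally`: list with per-option counts `N`
#'   (total), `male`, `adult`, `same_roost`.
#' @export
tally_social_window <- function(events, focal, time, site, window = 60,
                                individuals = NULL, focal_roost = NULL,
                                demos = c("all", "successful-only"),
                                options = ewa_options()) {
  demos <- match.arg(demos)
  if (is.unsorted(events$time)) stop("`events` must be sorted by time")
  sel <- events$site == site & events$time >= time - window &
    events$time < time & events$individual_id != focal
  if (demos == "successful-only") sel <- sel & events$success == 1
  ev <- events[sel, , drop = FALSE]
  zero <- setNames(numeric(length(options)), options)
  tally <- list(N = zero, male = zero, adult = zero, same_roost = zero)
  if (nrow(ev)) {
    cnt <- table(factor(ev$option, levels = options))
    tally$N[] <- as.numeric(cnt)
    if (!is.null(individuals)) {
      m <- match(ev$individual_id, individuals$id)
      sexes <- ifelse(is.na(m), "unknown", individuals$sex_class[m])
      ages <- ifelse(is.na(m), "unknown", individuals$age_class[m])
      roosts <- ifelse(is.na(m), "unknown", individuals$roost[m])
      if (is.null(focal_roost)) {
        fm <- match(focal, individuals$id)
        focal_roost <- if (is.na(fm)) "unknown" else individuals$roost[fm]
      }
      opt <- factor(ev$option, levels = options)
      tally$male[] <- as.numeric(table(opt[sexes == "male"]))
      tally$adult[] <- as.numeric(table(opt[ages == "adult"]))
      tally$same_roost[] <- as.numeric(
        table(opt[roosts == focal_roost & roosts != "unknown"]))
    }
  }
  structure(tally, class = "social_tally")
}

#' Combine individual and social components into choice probabilities
#'
#' \eqn{P = (1 - \gamma) I + \gamma S}. When the social component is the
#' no-information sentinel (`NULL`), the choice probability equals the
#' individual component (equivalent to \eqn{\gamma = 0} for that event).
#'
#' @param I individual-component probability vector.
#' @param S social-component probability vector or `NULL` sentinel.
#' @param gamma social-information weight in \[0, 1\].
#' @return probability vector.
#' @export
choice_probability <- function(I, S, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("`gamma` must be a single number in [0, 1]")
  if (is.null(S)) return(I)
  (1 - gamma) * I + gamma * S
}

# per-individual parameter lookup: scalar recycled, or named vector
.param_for <- function(p, id) {
  if (is.null(p)) stop("missing EWA parameter for strategy")
  if (length(p) == 1L && is.null(names(p))) return(unname(p))
  if (is.null(names(p)) || !(id %in% names(p)))
    stop("no parameter value for individual ", id)
  unname(p[[id]])
}

.initial_attractions <- function(individuals, options = ewa_options()) {
  A <- matrix(0, nrow = nrow(individuals), ncol = length(options),
              dimnames = list(individuals$id, options))
  tut <- which(!is.na(individuals$tutored_option) &
                 individuals$tutored_option %in% options)
  if (length(tut))
    A[cbind(tut, match(individuals$tutored_option[tut], options))] <- 1
  A
}

.social_component <- function(tally, strategy, gamma, f, beta) {
  switch(strategy,
         individual_only = NULL,
         frequency = frequency_social_probs(tally$N, f),
         male_bias = category_social_probs(tally, "male"),
         age_bias = category_social_probs(tally, "adult"),
         roost_bias = cue_bias_social_probs(tally, beta))
}

#' Log-likelihood of observed choices under an EWA strategy model
#'
#' Iterates the events in time order, maintaining per-individual attraction
#' scores and tallying the social window before each choice, and sums the log
#' probability assigned to each marked individual's observed option. Events
#' by unmarked individuals update social windows but contribute no likelihood
#' terms and no attraction state.
#'
#' @param events time-sorted event data frame (`time`, `site`,
#'   `individual_id`, `option`, `success`); unmarked individuals carry the id
#'   `"UNMARKED"` or any id absent from the roster.
#' @param individuals roster (see [read_individuals()]); tutored individuals
#'   start with attraction 1 for the tutored option, all others at 0.
#' @param params list with per-individual (named vector) or shared (scalar)
#'   values of `lambda`, `phi` and, as the strategy requires, `gamma`, `f`,
#'   `beta`.
#' @param strategy one of `individual_only`, `frequency`, `male_bias`,
#'   `age_bias`, `roost_bias`.
#' @param window social window length in seconds.
#' @param demos demonstrations counted in windows: all pickups, or successful
#'   ones only.
#' @return scalar log-likelihood with attribute `"pointwise"` (per marked
#'   event) and `"n_marked"`. Probabilities are floored at 1e-12 with a
#'   warning if an observed choice had (numerically) zero probability.
#' @export
ewa_loglik <- function(events, individuals, params,
                       strategy = ewa_strategies(), window = 60,
                       demos = c("all", "successful-only")) {
  strategy <- match.arg(strategy)
  demos <- match.arg(demos)
  validate_individuals(individuals)
  if (is.unsorted(events$time)) stop("`events` must be sorted by time")
  options <- ewa_options()
  A <- .initial_attractions(individuals, options)
  pointwise <- numeric(0)
  floored <- FALSE
  needs_gamma <- strategy != "individual_only"
  for (i in seq_len(nrow(events))) {
    id <- events$individual_id[i]
    if (!(id %in% individuals$id)) next
    lambda <- .param_for(params$lambda, id)
    phi <- .param_for(params$phi, id)
    I <- individual_probs(A[id, ], lambda)
    if (needs_gamma) {
      gamma <- .param_for(params$gamma, id)
      tally <- tally_social_window(events, id, events$time[i], events$site[i],
                                   window = window, individuals = individuals,
                                   demos = demos, options = options)
      S <- .social_component(tally, strategy, gamma,
                             f = if (strategy == "frequency")
                               .param_for(params$f, id) else 1,
                             beta = if (strategy == "roost_bias")
                               .param_for(params$beta, id) else 0)
      P <- choice_probability(I, S, gamma)
    } else {
      P <- I
    }
    p_obs <- P[[events$option[i]]]
    if (p_obs < 1e-12) { p_obs <- 1e-12; floored <- TRUE }
    pointwise <- c(pointwise, log(p_obs))
    A[id, events$option[i]] <-
      update_attraction(A[id, events$option[i]], events$success[i], phi)
  }
  if (floored)
    warning("an observed choice had ~zero model probability; floored at 1e-12")
  structure(sum(pointwise), pointwise = pointwise, n_marked = length(pointwise))
}

#' Simulate a stream of two-option choices under an EWA strategy
#'
#' Generative mirror of [ewa_loglik()]: walks a solve schedule in time order,
#' draws each marked individual's option from its current choice
#' probabilities, draws opening success as Bernoulli(`p_success`), and
#' updates attractions with the realised payoff. Unmarked individuals copy
#' the recent window frequency (or choose uniformly with an empty window) and
#' carry no attraction state.
#'
#' @param schedule time-sorted data frame (`individual_id`, `time`, `site`)
#'   of solve opportunities.
#' @param individuals roster.
#' @param params,strategy,window,demos as in [ewa_loglik()].
#' @param p_success probability that a pickup ends in a successful opening.
#' @param seed optional integer seed.
#' @return event data frame (`time`, `site`, `individual_id`, `option`,
#'   `success`).
#' @export
simulate_choices <- function(schedule, individuals, params,
                             strategy = ewa_strategies(), p_success = 0.9,
                             window = 60, demos = c("all", "successful-only"),
                             seed = NULL) {
  strategy <- match.arg(strategy)
  demos <- match.arg(demos)
  validate_individuals(individuals)
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(schedule$time)) stop("`schedule` must be sorted by time")
  stopifnot(p_success >= 0, p_success <= 1)
  options <- ewa_options()
  A <- .initial_attractions(individuals, options)
  n <- nrow(schedule)
  events <- data.frame(time = schedule$time, site = schedule$site,
                       individual_id = schedule$individual_id,
                       option = character(n), success = integer(n),
                       stringsAsFactors = FALSE)
  needs_gamma <- strategy != "individual_only"
  for (i in seq_len(n)) {
    id <- events$individual_id[i]
    marked <- id %in% individuals$id
    # rows >= i have time >= t and fall outside the half-open window [t-60, t)
    prior <- events
    if (marked) {
      I <- individual_probs(A[id, ], .param_for(params$lambda, id))
      if (needs_gamma) {
        tally <- tally_social_window(prior, id, events$time[i], events$site[i],
                                     window = window, individuals = individuals,
                                     demos = demos, options = options)
        S <- .social_component(tally, strategy, NULL,
                               f = if (strategy == "frequency")
                                 .param_for(params$f, id) else 1,
                               beta = if (strategy == "roost_bias")
                                 .param_for(params$beta, id) else 0)
        P <- choice_probability(I, S, .param_for(params$gamma, id))
      } else {
        P <- I
      }
    } else {
      tally <- tally_social_window(prior, id, events$time[i], events$site[i],
                                   window = window, options = options)
      S <- frequency_social_probs(tally$N, 1)
      P <- if (is.null(S)) rep(1 / length(options), length(options)) else S
    }
    k <- sample.int(length(options), 1L, prob = P)
    success <- rbinom(1L, 1L, p_success)
    events$option[i] <- options[k]
    events$success[i] <- success
    if (marked) {
      phi <- .param_for(params$phi, id)
      A[id, k] <- update_attraction(A[id, k], success, phi)
    }
  }
  events
}

#' Read choice events from CSV
#'
#' Expects columns `time` (numeric seconds or ISO-8601 datetime), `site`,
#' `individual_id` (or `UNMARKED`), `option` (`red`/`blue`), `success`
#' (0/1). Rows are returned sorted by time.
#'
#' @param path CSV file path.
#' @return event data frame with numeric `time`.
#' @export
read_events <- function(path) {
  ev <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "site", "individual_id", "option", "success")
  if (!all(need %in% names(ev)))
    stop("events file must have columns ", paste(need, collapse = ","))
  if (is.character(ev$time)) {
    num <- suppressWarnings(as.numeric(ev$time))
    t <- as.numeric(strptime(ev$time, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
    t2 <- as.numeric(strptime(ev$time, format = "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
    t[is.na(t)] <- t2[is.na(t)]
    bad <- is.na(num) & is.na(t)
    if (any(bad))
      stop("non-ISO timestamp(s) in events at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    ev$time <- if (anyNA(num)) t - min(t) else num
  }
  bad <- setdiff(unique(ev$option), ewa_options())
  if (length(bad)) stop("invalid option value(s): ", paste(bad, collapse = ", "))
  if (!all(ev$success %in% c(0, 1))) stop("success must be 0/1")
  ev[order(ev$time), , drop = FALSE]
}

# Flatten events + roster into index form for the compiled likelihood and
# sampler: per marked event, chooser index, option index, payoff, and the
# four per-option window counts (total / male / adult / same-roost relative
# to the chooser). Counts depend only on the observed data, so they are
# computed once here.
ewa_prepare <- function(events, individuals, window = 60,
                        demos = c("all", "successful-only")) {
  demos <- match.arg(demos)
  validate_individuals(individuals)
  if (is.unsorted(events$time)) stop("`events` must be sorted by time")
  options <- ewa_options()
  marked_rows <- which(events$individual_id %in% individuals$id)
  choosers <- sort(unique(events$individual_id[marked_rows]))
  n_ev <- length(marked_rows)
  chooser_idx <- integer(n_ev); choice <- integer(n_ev); payoff <- numeric(n_ev)
  counts <- array(0, dim = c(n_ev, 4L, length(options)),
                  dimnames = list(NULL, c("N", "male", "adult", "same_roost"),
                                  options))
  for (e in seq_len(n_ev)) {
    i <- marked_rows[e]
    id <- events$individual_id[i]
    tal <- tally_social_window(events, id, events$time[i], events$site[i],
                               window = window, individuals = individuals,
                               demos = demos, options = options)
    counts[e, "N", ] <- tal$N
    counts[e, "male", ] <- tal$male
    counts[e, "adult", ] <- tal$adult
    counts[e, "same_roost", ] <- tal$same_roost
    chooser_idx[e] <- match(id, choosers)
    choice[e] <- match(events$option[i], options)
    payoff[e] <- events$success[i]
  }
  ord <- order(chooser_idx, seq_len(n_ev))  # group by chooser, keep time order
  ri <- match(choosers, individuals$id)
  A0 <- .initial_attractions(individuals[ri, , drop = FALSE], options)
  list(choosers = choosers,
       chooser_idx = chooser_idx[ord],
       choice = choice[ord],
       payoff = payoff[ord],
       counts = counts[ord, , , drop = FALSE],
       event_order = marked_rows[ord],
       A0 = A0,
       age = individuals$age_class[ri],
       sex = individuals$sex_class[ri],
       n_options = length(options))
}
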