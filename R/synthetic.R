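## Synthetic study generator. Emulates the structure of a multi-roost,
## two-option cultural diffusion experiment with known ground truth: a
## population of marked individuals across five roosting communities (three
## "main" sites with social data, two secondary), fluid foraging subgroups
## sampled by group scans, trained demonstrators seeding diffusions that
## spread along network ties, colour-choice streams generated under EWA
## dynamics with age-dependent conformity, and opening sequences with
## individual consistency plus site-level profiles that drift with distance.

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the scale and structure of a multi-roost urban parrot
#' study: five roosting sites at real inter-site distances of 1.5--10 km
#' (three main sites where social data and diffusions are recorded, two
#' secondary), 100 individuals per roost, 864 group scans, two trained
#' demonstrators per seeded roost (one roost seeded on red, one on blue, one
#' control), diffusion under social transmission rate `s = 5`, and EWA
#' choice streams with lambda 2.5, phi 0.22, gamma 0.15 and a conformist
#' juvenile bias (f 2.0 for juveniles, 1.0 for adults and unknowns).
#'
#' @param n_per_roost individuals per roost.
#' @param n_scans number of group scans at the main sites.
#' @param mean_group_size target mean foraging-subgroup size per scan.
#' @param movement_scale e-folding distance (km) of the between-roost
#'   movement propensity, `exp(-d / movement_scale)`.
#' @param scan_mixing multiplier on the movement propensity when sampling
#'   scan membership away from the home roost; keeps the association network
#'   modular (group scans mostly catch home-roost birds) while site
#'   attendance over the whole experiment remains fluid.
#' @param sociability_sd log-normal sd of per-individual gregariousness in
#'   scan membership; produces the heavy-tailed weighted degrees typical of
#'   fission-fusion foraging networks.
#' @param n_demonstrators trained demonstrators per seeded roost.
#' @param s generative social transmission rate for the diffusions.
#' @param learner_fraction fraction of each risk set that acquires the
#'   behaviour.
#' @param lambda,phi,gamma,f_juvenile,f_adult,beta generative EWA group
#'   means (natural scale); `f_adult` is also used for unknown-age birds.
#' @param offset_sd individual-offset standard deviation on the link scale.
#' @param p_success probability a pickup ends in a successful opening.
#' @param n_sessions experimental days; `session_length` seconds per daily
#'   session.
#' @param solves_per_session mean solves per informed individual per session.
#' @param attendance_prob probability an informed individual attends a
#'   session.
#' @param unmarked_fraction fraction of additional solve events by unmarked
#'   birds.
#' @param opening_prob probability an individual contributes opening
#'   sequences.
#' @param gradient_scale strength of the site-level technique gradient on
#'   the logit scale.
#' @param technique_ind_sd individual-consistency sd of technique
#'   propensities (logit scale).
#' @param seed master seed; all generators derive their streams from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_roost = 100, n_scans = 864,
                             mean_group_size = 25, movement_scale = 2,
                             scan_mixing = 0.3, sociability_sd = 0.6,
                             n_demonstrators = 2, s = 5,
                             learner_fraction = 0.65,
                             lambda = 2.5, phi = 0.22, gamma = 0.15,
                             f_juvenile = 2.0, f_adult = 1.0, beta = 0,
                             offset_sd = 0.3, p_success = 0.9,
                             n_sessions = 10, session_length = 7200,
                             solves_per_session = 3, attendance_prob = 0.8,
                             unmarked_fraction = 0.1,
                             opening_prob = 0.4, gradient_scale = 1.5,
                             technique_ind_sd = 1.0,
                             seed = 1L) {
  sites <- data.frame(
    site = c("BA", "CG", "NB", "MA", "BG"),
    lat = c(-33.828494, -33.841444, -33.817167, -33.796200, -33.864776),
    lon = c(151.253983, 151.252889, 151.221694, 151.282786, 151.220025),
    main = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  # demographic cell proportions follow a field study roster (n = 338 with
  # printed cells); unknown classes are modelled levels, not missing data
  cell_counts <- c("adult:male" = 78, "juvenile:male" = 21, "unknown:male" = 17,
                   "adult:female" = 55, "juvenile:female" = 16,
                   "unknown:female" = 5, "adult:unknown" = 0,
                   "juvenile:unknown" = 44, "unknown:unknown" = 102)
  structure(list(
    sites = sites,
    main_sites = sites$site[sites$main],
    cell_probs = cell_counts / sum(cell_counts),
    n_per_roost = n_per_roost, n_scans = n_scans,
    mean_group_size = mean_group_size, movement_scale = movement_scale,
    scan_mixing = scan_mixing, sociability_sd = sociability_sd,
    n_demonstrators = n_demonstrators,
    demo_colours = c(CG = "red", BA = "blue"),  # NB stays control
    s = s, learner_fraction = learner_fraction,
    lambda = lambda, phi = phi, gamma = gamma,
    f_juvenile = f_juvenile, f_adult = f_adult, beta = beta,
    offset_sd = offset_sd, p_success = p_success,
    n_sessions = n_sessions, session_length = session_length,
    solves_per_session = solves_per_session,
    attendance_prob = attendance_prob,
    unmarked_fraction = unmarked_fraction,
    opening_prob = opening_prob, gradient_scale = gradient_scale,
    technique_ind_sd = technique_ind_sd,
    session_offsets_h = c(NB = 7, CG = 10.5, BA = 13.5),
    seed = as.integer(seed)), class = "synthetic_config")
}

# between-roost movement propensity from inter-site distance
.movement_propensity <- function(cfg) {
  d <- site_distances(cfg$sites)
  p <- exp(-d / cfg$movement_scale)
  diag(p) <- 1
  p
}

#' Generate a synthetic individual roster
#'
#' Assigns ids, age/sex cells (multinomial over the configured proportions,
#' unknown classes included), home roosts, and trained demonstrators with
#' their tutored colour (adults at each seeded roost; one roost red, one
#' blue, the third main roost an unseeded control).
#'
#' @param cfg `synthetic_config`.
#' @param seed optional override of the roster stream seed.
#' @return roster data frame (`id,age_class,sex_class,roost,tutored_option`).
#' @export
generate_population <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  rosters <- lapply(cfg$sites$site, function(rs) {
    cells <- sample(names(cfg$cell_probs), cfg$n_per_roost, replace = TRUE,
                    prob = cfg$cell_probs)
    parts <- strsplit(cells, ":", fixed = TRUE)
    data.frame(id = sprintf("%s%03d", rs, seq_len(cfg$n_per_roost)),
               age_class = vapply(parts, `[[`, character(1), 1L),
               sex_class = vapply(parts, `[[`, character(1), 2L),
               roost = rs, tutored_option = NA_character_,
               stringsAsFactors = FALSE)
  })
  roster <- do.call(rbind, rosters)
  for (rs in names(cfg$demo_colours)) {
    adults <- which(roster$roost == rs & roster$age_class == "adult")
    if (length(adults) < cfg$n_demonstrators)
      adults <- which(roster$roost == rs)
    demos <- adults[seq_len(cfg$n_demonstrators)]
    roster$tutored_option[demos] <- cfg$demo_colours[[rs]]
  }
  roster
}

#' Generate synthetic group scans
#'
#' Each scan samples one main site and a fluid foraging subgroup: every
#' individual joins with a probability proportional to 1 at its home roost
#' and to the distance-decayed movement propensity elsewhere, scaled so the
#' expected subgroup size matches the configuration. The resulting SRI
#' network is modular, with denser within-roost ties.
#'
#' @param cfg `synthetic_config`.
#' @param roster from [generate_population()].
#' @param seed optional override of the scan stream seed.
#' @return scans data frame (`scan_id,datetime,site,individual_id`).
#' @export
generate_scans <- function(cfg, roster, seed = cfg$seed + 1L) {
  set.seed(seed)
  prop <- .movement_propensity(cfg)
  scan_sites <- rep(cfg$main_sites, length.out = cfg$n_scans)
  greg <- exp(rnorm(nrow(roster), 0, cfg$sociability_sd))
  t0 <- as.POSIXct("2019-07-08 09:00:00", tz = "UTC")
  out <- vector("list", cfg$n_scans)
  for (k in seq_len(cfg$n_scans)) {
    s <- scan_sites[k]
    w <- greg * ifelse(roster$roost == s, 1,
                       cfg$scan_mixing * prop[roster$roost, s])
    p <- pmin(0.95, cfg$mean_group_size * w / sum(w))
    present <- roster$id[runif(nrow(roster)) < p]
    if (length(present) < 2L)
      present <- unique(c(present, sample(roster$id[roster$roost == s], 2L)))
    out[[k]] <- data.frame(
      scan_id = sprintf("scan%04d", k),
      datetime = format(t0 + (k - 1L) * 600, "%Y-%m-%dT%H:%M:%S"),
      site = s, individual_id = present, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# per-individual natural-scale EWA parameters: cell means + N(0, sd) offsets
.ewa_truth_params <- function(cfg, roster) {
  n <- nrow(roster)
  off <- function() rnorm(n, 0, cfg$offset_sd)
  f_mean <- ifelse(roster$age_class == "juvenile", log(cfg$f_juvenile),
                   log(cfg$f_adult))
  list(lambda = setNames(exp(log(cfg$lambda) + off()), roster$id),
       phi = setNames(plogis(qlogis(cfg$phi) + off()), roster$id),
       gamma = setNames(plogis(qlogis(cfg$gamma) + off()), roster$id),
       f = setNames(exp(f_mean + off()), roster$id),
       beta = setNames(cfg$beta + off(), roster$id))
}

#' Generate the synthetic diffusion experiment (acquisition + choices)
#'
#' Simulates, per main site, who attends, the order of acquisition through
#' the association network (seeded by the trained demonstrators; already
#' knowledgeable movers from previously run sites enter later diffusions as
#' informed on arrival), and then a 10-day stream of two-option solve events:
#' informed individuals attend daily sessions, solve in temporal bouts
#' (several birds feeding at the dispenser within the same minute, so social
#' windows carry demonstrations), and choose colours under the generative
#' EWA frequency-dependent dynamics. A configurable fraction of extra events
#' comes from unmarked birds.
#'
#' @param cfg `synthetic_config`.
#' @param roster from [generate_population()].
#' @param net `assoc_network` from [build_sri_network()] on the synthetic
#'   scans.
#' @param seed optional override of the experiment stream seed.
#' @return list with `record` (`diffusion_record` over the main sites),
#'   `events` (time-sorted event data frame), `attendance` (site -> ids),
#'   and `truth` (generative parameters, per-event social fractions of the
#'   acquisition draws, realised percent-social).
#' @export
generate_experiment <- function(cfg, roster, net, seed = cfg$seed + 2L) {
  set.seed(seed)
  prop <- .movement_propensity(cfg)
  # site attendance over the experimental period
  attendance <- lapply(cfg$sites$site, function(s) {
    p <- ifelse(roster$roost == s, 0.9, 0.6 * prop[roster$roost, s])
    roster$id[runif(nrow(roster)) < p]
  })
  names(attendance) <- cfg$sites$site

  params <- nbda_params(s = cfg$s)
  informed_anywhere <- character(0)
  diffusions <- list()
  social_fraction <- list()
  site_order <- c(names(cfg$demo_colours), setdiff(cfg$main_sites, names(cfg$demo_colours)))
  for (s in site_order) {
    risk <- attendance[[s]]
    demos <- roster$id[!is.na(roster$tutored_option) & roster$roost == s]
    risk <- unique(c(risk, demos))
    seeded <- unique(c(demos, intersect(risk, informed_anywhere)))
    if (!length(seeded) && length(informed_anywhere)) {
      # a knowledgeable mover introduces the behaviour at the control roost
      mover <- sample(informed_anywhere, 1L)
      risk <- unique(c(risk, mover))
      seeded <- mover
      attendance[[s]] <- risk
    }
    n_naive <- length(setdiff(risk, seeded))
    rec <- simulate_diffusion(net, params, risk_set = risk,
                              seeded_informed = seeded,
                              n_events = round(cfg$learner_fraction * n_naive),
                              site = s)
    diffusions[[s]] <- rec$diffusions[[1]]
    social_fraction[[s]] <- attr(rec, "social_fraction")
    informed_anywhere <- unique(c(informed_anywhere, seeded,
                                  rec$diffusions[[1]]$learners))
  }
  record <- diffusion_record(unname(diffusions))

  # map acquisition order onto learning sessions 1..(n_sessions - 2)
  truth_params <- .ewa_truth_params(cfg, roster)
  schedule <- list()
  learn_span <- max(1L, cfg$n_sessions - 2L)
  for (s in cfg$main_sites) {
    d <- diffusions[[s]]
    learners <- d$learners
    learn_session <- ceiling(seq_along(learners) / length(learners) * learn_span)
    names(learn_session) <- learners
    seeded <- d$seeded_informed
    base_h <- cfg$session_offsets_h[[s]]
    for (day in seq_len(cfg$n_sessions)) {
      t_base <- (day - 1) * 86400 + base_h * 3600
      informed <- c(seeded, learners[learn_session <= day])
      if (!length(informed)) next
      new_learners <- learners[learn_session == day]
      attending <- informed[runif(length(informed)) < cfg$attendance_prob]
      attending <- unique(c(attending, new_learners))
      n_solves <- 1L + rpois(length(attending), cfg$solves_per_session - 1)
      total <- sum(n_solves)
      n_bouts <- max(1L, round(total / 6))
      centers <- sort(runif(n_bouts, 120, cfg$session_length - 120))
      times <- centers[sample.int(n_bouts, total, replace = TRUE)] +
        rnorm(total, 0, 15)
      n_unmarked <- round(cfg$unmarked_fraction * total)
      if (n_unmarked > 0)
        times <- c(times, centers[sample.int(n_bouts, n_unmarked, replace = TRUE)] +
                     rnorm(n_unmarked, 0, 15))
      times <- pmin(pmax(times, 0), cfg$session_length)
      ids <- c(rep(attending, n_solves), rep("UNMARKED", max(0L, n_unmarked)))
      # a new learner's first solve is its acquisition event
      ord <- order(times)
      schedule[[length(schedule) + 1L]] <-
        data.frame(individual_id = ids[ord], time = t_base + times[ord],
                   site = s, stringsAsFactors = FALSE)
    }
  }
  schedule <- do.call(rbind, schedule)
  schedule <- schedule[order(schedule$time), , drop = FALSE]
  # strictly increasing times keep window semantics unambiguous
  schedule$time <- schedule$time + seq_len(nrow(schedule)) * 1e-4
  events <- simulate_choices(schedule, roster, truth_params,
                             strategy = "frequency",
                             p_success = cfg$p_success)
  pct_social <- 100 * mean(unlist(social_fraction))
  list(record = record, events = events, attendance = attendance,
       truth = list(s = cfg$s, params = truth_params,
                    social_fraction = social_fraction,
                    percent_social = pct_social,
                    cell_means = list(
                      lambda = cfg$lambda, phi = cfg$phi, gamma = cfg$gamma,
                      f_juvenile = cfg$f_juvenile, f_adult = cfg$f_adult)))
}

#' Generate synthetic opening sequences
#'
#' Sites carry technique-frequency profiles that drift along the main
#' geographic axis (so between-site dissimilarity grows with distance), and
#' each individual draws consistent personal propensities around its home
#' site's profile; repeat observations per individual span 1--17 with a
#' median around 3.
#'
#' @param cfg `synthetic_config`.
#' @param roster from [generate_population()].
#' @param seed optional override of the openings stream seed.
#' @return openings data frame
#'   (`individual_id,site,unshell,crack,extract,duration_s`).
#' @export
generate_openings <- function(cfg, roster, seed = cfg$seed + 3L) {
  set.seed(seed)
  # 1-d site gradient: scaled projection onto the principal geographic axis
  d <- site_distances(cfg$sites)
  z <- cmdscale(d, k = 1)[, 1]
  z <- 2 * (z - min(z)) / (max(z) - min(z)) - 1
  names(z) <- cfg$sites$site
  dir_crack <- c(tip = 1, seam = -1, hilum = 0.5, middle = -0.5)
  dir_extract <- c(nibble = 1, split = -1, other = 0)
  base_crack <- c(tip = 0.4, seam = 0, hilum = -0.2, middle = -0.6)
  base_extract <- c(nibble = 0.5, split = 0, other = -0.8)
  softmax <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  keep <- roster$id[runif(nrow(roster)) < cfg$opening_prob]
  rows <- lapply(keep, function(id) {
    rs <- roster$roost[match(id, roster$id)]
    u_crack <- base_crack + cfg$gradient_scale * z[[rs]] * dir_crack +
      rnorm(4, 0, cfg$technique_ind_sd)
    u_extract <- base_extract + cfg$gradient_scale * z[[rs]] * dir_extract +
      rnorm(3, 0, cfg$technique_ind_sd)
    p_unshell <- plogis(0.2 + 0.8 * cfg$gradient_scale * z[[rs]] +
                          rnorm(1, 0, cfg$technique_ind_sd))
    n_open <- min(17L, 1L + rpois(1, 2.2))
    data.frame(individual_id = id, site = rs,
               unshell = as.integer(runif(n_open) < p_unshell),
               crack = sample(crack_levels(), n_open, TRUE, softmax(u_crack)),
               extract = sample(extract_levels(), n_open, TRUE, softmax(u_extract)),
               duration_s = round(rgamma(n_open, shape = 4, rate = 1 / 20)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator with streams derived from the master seed and
#' (optionally) writes `individuals.csv`, `scans.csv`, `diffusion.csv`,
#' `events.csv`, `openings.csv`, `sites.csv` and the ground-truth sidecar
#' `truth.json` to a directory.
#'
#' @param cfg `synthetic_config`.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return (invisibly when writing) list with all generated objects:
#'   `roster`, `scans`, `network`, `record`, `events`, `openings`,
#'   `attendance`, `truth`, `sites`.
#' @export
simulate_all <- function(cfg = synthetic_config(), out_dir = NULL) {
  roster <- generate_population(cfg)
  scans <- generate_scans(cfg, roster)
  net <- build_sri_network(scans, ids = roster$id)
  exp_out <- generate_experiment(cfg, roster, net)
  openings <- generate_openings(cfg, roster)
  bundle <- list(roster = roster, scans = scans, network = net,
                 record = exp_out$record, events = exp_out$events,
                 openings = openings, attendance = exp_out$attendance,
                 truth = exp_out$truth, sites = cfg$sites)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(roster, file.path(out_dir, "individuals.csv"), row.names = FALSE)
    write.csv(scans, file.path(out_dir, "scans.csv"), row.names = FALSE)
    write_diffusion(exp_out$record, file.path(out_dir, "diffusion.csv"))
    write.csv(exp_out$events, file.path(out_dir, "events.csv"), row.names = FALSE)
    write.csv(openings, file.path(out_dir, "openings.csv"), row.names = FALSE)
    write.csv(cfg$sites[, c("site", "lat", "lon")],
              file.path(out_dir, "sites.csv"), row.names = FALSE)
    truth <- exp_out$truth
    truth$params <- lapply(truth$params, function(p) as.list(p))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(bundle))
  }
  bundle
}

#' Simulate a single-site EWA recovery study
#'
#' Focused generator for parameter-recovery experiments: a balanced roster
#' of juveniles and adults of both sexes at one site, a bout-structured
#' solve schedule (so social windows carry a few demonstrations), and
#' choices drawn under the frequency-dependent EWA strategy with
#' individual offsets around the configured cell means.
#'
#' @param n_ind number of individuals (split evenly over the 4 age-sex
#'   cells).
#' @param choices_per_ind solves per individual.
#' @param lambda,phi,gamma,f_juvenile,f_adult natural-scale group means.
#' @param offset_sd individual-offset sd on the link scale.
#' @param p_success probability of a successful opening.
#' @param bout_size mean number of solves per temporal bout.
#' @param seed integer seed.
#' @return list with `events`, `individuals`, and `truth` (link-scale cell
#'   means named as the fitted parameters, for coverage checks).
#' @export
simulate_ewa_study <- function(n_ind = 60, choices_per_ind = 30,
                               lambda = 2.5, phi = 0.22, gamma = 0.15,
                               f_juvenile = 2.0, f_adult = 1.0,
                               offset_sd = 0.3, p_success = 0.9,
                               bout_size = 6, seed = 1L) {
  set.seed(seed)
  ages <- rep(c("juvenile", "adult"), length.out = n_ind)
  sexes <- rep(c("male", "male", "female", "female"), length.out = n_ind)
  # two roosting communities foraging at the one site, so roost-biased
  # copying is a distinct competitor strategy in model-comparison runs
  roosts <- rep(c("R1", "R2"), length.out = n_ind)
  individuals <- data.frame(id = sprintf("ID%03d", seq_len(n_ind)),
                            age_class = ages, sex_class = sexes,
                            roost = roosts, tutored_option = NA_character_,
                            stringsAsFactors = FALSE)
  off <- function() rnorm(n_ind, 0, offset_sd)
  f_mu <- ifelse(ages == "juvenile", log(f_juvenile), log(f_adult))
  params <- list(lambda = setNames(exp(log(lambda) + off()), individuals$id),
                 phi = setNames(plogis(qlogis(phi) + off()), individuals$id),
                 gamma = setNames(plogis(qlogis(gamma) + off()), individuals$id),
                 f = setNames(exp(f_mu + off()), individuals$id))
  n_total <- n_ind * choices_per_ind
  n_bouts <- ceiling(n_total / bout_size)
  centers <- sort(runif(n_bouts, 0, n_bouts * 180))
  assignment <- sample(rep(seq_len(n_bouts), length.out = n_total))
  times <- centers[assignment] + rnorm(n_total, 0, 15)
  ids <- sample(rep(individuals$id, choices_per_ind))
  ord <- order(times)
  schedule <- data.frame(individual_id = ids[ord],
                         time = times[ord] + seq_len(n_total) * 1e-4,
                         site = "S1", stringsAsFactors = FALSE)
  events <- simulate_choices(schedule, individuals, params,
                             strategy = "frequency", p_success = p_success)
  truth <- c("mu_lambda" = log(lambda), "mu_phi" = qlogis(phi),
             "mu_gamma" = qlogis(gamma),
             "mu_f[juvenile]" = log(f_juvenile),
             "mu_f[adult]" = log(f_adult))
  list(events = events, individuals = individuals, truth = truth,
       params = params)
}
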