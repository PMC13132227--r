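## End-to-end orchestration: input validation and the staged analysis run
## (network -> diffusion analysis -> EWA -> techniques), returning a single
## machine-readable report.

#' Validate an input bundle
#'
#' Checks schemas, referential integrity (every event / opening / diffusion
#' individual is in the roster or `UNMARKED`) and time monotonicity for a set
#' of input files, collecting row-level messages.
#'
#' @param paths named list of file paths; recognised names: `individuals`
#'   (required), `scans`, `events`, `diffusion`, `openings`, `sites`.
#' @param stop_on_error abort with the first collected error instead of
#'   returning the report?
#' @return object of class `validation_report`: list with `ok` and a
#'   data frame `issues` (`file`, `message`).
#' @export
validate_inputs <- function(paths, stop_on_error = FALSE) {
  issues <- data.frame(file = character(), message = character(),
                       stringsAsFactors = FALSE)
  note <- function(file, msg)
    issues <<- rbind(issues, data.frame(file = file, message = msg,
                                        stringsAsFactors = FALSE))
  grab <- function(name, reader) {
    if (is.null(paths[[name]])) return(NULL)
    if (!file.exists(paths[[name]])) {
      note(name, paste0("file not found: ", paths[[name]]))
      return(NULL)
    }
    tryCatch(reader(paths[[name]]),
             error = function(e) { note(name, conditionMessage(e)); NULL })
  }
  individuals <- grab("individuals", read_individuals)
  if (is.null(paths$individuals)) note("individuals", "individuals path is required")
  roster_ids <- if (!is.null(individuals)) individuals$id else character()
  check_ids <- function(name, ids, allow_unmarked = FALSE) {
    ok <- ids %in% roster_ids | (allow_unmarked & ids == "UNMARKED")
    if (any(!ok))
      note(name, paste0("unknown individual id(s) at row(s) ",
                        paste(utils::head(which(!ok), 5), collapse = ", "), ": ",
                        paste(utils::head(unique(ids[!ok]), 5), collapse = ", ")))
  }
  scans <- grab("scans", read_scans)
  if (!is.null(scans) && length(roster_ids))
    check_ids("scans", scans$individual_id)
  events <- grab("events", read_events)
  if (!is.null(events)) {
    if (length(roster_ids)) check_ids("events", events$individual_id, TRUE)
    if (is.unsorted(events$time)) note("events", "times are not monotone")
  }
  record <- grab("diffusion", read_diffusion)
  if (!is.null(record) && length(roster_ids))
    check_ids("diffusion",
              unlist(lapply(record$diffusions, `[[`, "risk_set")))
  openings <- grab("openings", read_openings)
  if (!is.null(openings) && length(roster_ids))
    check_ids("openings", openings$individual_id)
  sites <- grab("sites", read_sites)
  if (!is.null(sites) && !is.null(openings)) {
    miss <- setdiff(unique(openings$site), sites$site)
    if (length(miss))
      note("openings", paste0("site(s) without coordinates: ",
                              paste(miss, collapse = ", ")))
  }
  report <- structure(list(ok = nrow(issues) == 0L, issues = issues),
                      class = "validation_report")
  if (stop_on_error && !report$ok)
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s", issues$file, issues$message), collapse = "\n"))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("All inputs valid.\n")
  else {
    cat("Input validation FAILED:\n")
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  [%s] %s\n", x$issues$file[i], x$issues$message[i]))
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes the staged analysis on an input bundle (either file paths or a
#' pre-loaded bundle as returned by [simulate_all()]): association network
#' and movement rates, order-of-acquisition diffusion analysis with AICc
#' model comparison and percent-social estimation, EWA strategy fits with
#' WAIC comparison and posterior summaries, and the opening-technique partial
#' Mantel tests. Stages can be toggled; every stochastic stage records its
#' seed in the report.
#'
#' @param bundle either a named list of file paths (validated with
#'   [validate_inputs()]) or an in-memory bundle from [simulate_all()].
#' @param stages character subset of `c("network", "nbda", "ewa",
#'   "techniques")`.
#' @param strategies strategies to fit in the EWA stage.
#' @param ewa_config list of MCMC settings passed to [fit_ewa()]
#'   (`chains`, `warmup`, `samples`).
#' @param mantel_perms permutations for the Mantel tests.
#' @param seed master seed.
#' @param out optional path; if given, the report is written there as JSON.
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(bundle,
                         stages = c("network", "nbda", "ewa", "techniques"),
                         strategies = ewa_strategies(),
                         ewa_config = list(chains = 2, warmup = 500, samples = 500),
                         mantel_perms = 999,
                         seed = 1L, out = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  from_paths <- !is.null(bundle$individuals) && is.character(bundle$individuals) &&
    length(bundle$individuals) == 1L
  if (from_paths) {
    validate_inputs(bundle, stop_on_error = TRUE)
    bundle <- list(
      roster = read_individuals(bundle$individuals),
      scans = if (!is.null(bundle$scans)) read_scans(bundle$scans),
      record = if (!is.null(bundle$diffusion)) read_diffusion(bundle$diffusion),
      events = if (!is.null(bundle$events)) read_events(bundle$events),
      openings = if (!is.null(bundle$openings)) read_openings(bundle$openings),
      sites = if (!is.null(bundle$sites)) read_sites(bundle$sites))
  }
  report <- list(seed = seed, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 package_version = as.character(utils::packageVersion("cultdiff")),
                 stages = stages, warnings = character())
  warn <- function(msg) report$warnings <<- c(report$warnings, msg)

  net <- bundle$network
  if ("network" %in% stages) {
    if (is.null(net)) {
      if (is.null(bundle$scans)) stop("network stage needs scans")
      net <- build_sri_network(bundle$scans, ids = bundle$roster$id)
    }
    w <- net$sri[upper.tri(net$sri)]
    report$network <- list(n_individuals = length(net$ids),
                           n_scans = net$n_scans,
                           n_nonzero_dyads = sum(w > 0),
                           mean_nonzero_sri = mean(w[w > 0]))
    if (!is.null(bundle$attendance)) {
      mm <- movement_rates(bundle$attendance)
      report$network$movement <- as.data.frame(as.table(unclass(mm)))
    }
  }

  if ("nbda" %in% stages) {
    if (is.null(net) || is.null(bundle$record))
      stop("nbda stage needs a network and diffusion data")
    ilvs <- ilv_design(bundle$roster)
    fits <- fit_oada_all(bundle$record, net, ilvs)
    tab <- aicc_model_table(fits)
    fam <- attr(tab, "family_weights")
    soc_fits <- fits[vapply(fits, `[[`, logical(1), "social")]
    best_social <- soc_fits[[which.max(vapply(soc_fits, `[[`, numeric(1), "logLik"))]]
    ps <- percent_social(best_social, bundle$record, net, ilvs)
    report$nbda <- list(model_table = tab, family_weights = as.list(fam),
                        s_hat = best_social$params$s,
                        percent_social = ps$estimate,
                        percent_social_ci = ps$ci)
  }

  if ("ewa" %in% stages) {
    if (is.null(bundle$events)) stop("ewa stage needs events")
    fits <- list()
    for (strat in strategies) {
      fits[[strat]] <- fit_ewa(bundle$events, bundle$roster, strat,
                               chains = ewa_config$chains,
                               warmup = ewa_config$warmup,
                               samples = ewa_config$samples,
                               seed = seed)
      if (isTRUE(fits[[strat]]$diagnostics$flagged))
        warn(paste0("EWA fit ", strat, ": R-hat > 1.05"))
    }
    report$ewa <- list(waic = waic_table(fits),
                       summaries = lapply(fits, posterior_summary))
  }

  if ("techniques" %in% stages) {
    if (is.null(bundle$openings)) stop("techniques stage needs openings")
    enc <- encode_sequences(bundle$openings)
    D_y <- sequence_dissimilarity(enc)
    D_id <- build_predictor_matrix(bundle$openings, "same_individual")
    res <- list()
    if (!is.null(bundle$sites)) {
      D_dist <- build_predictor_matrix(bundle$openings, "site_distance",
                                       sites = bundle$sites)
      res$distance <- partial_mantel(D_y, D_dist, D_id, n_perm = mantel_perms,
                                     seed = seed)
    }
    if (!is.null(bundle$attendance)) {
      mm <- movement_rates(bundle$attendance)
      D_mov <- build_predictor_matrix(bundle$openings, "site_movement",
                                      movement = mm)
      res$movement <- partial_mantel(D_y, D_mov, D_id, n_perm = mantel_perms,
                                     seed = seed + 1L)
    }
    if (!is.null(net)) {
      D_soc <- build_predictor_matrix(bundle$openings, "association",
                                      network = net)
      res$association <- partial_mantel(D_y, D_soc, D_id, n_perm = mantel_perms,
                                        seed = seed + 2L)
    }
    ctrl <- if (!is.null(bundle$sites))
      build_predictor_matrix(bundle$openings, "site_distance", sites = bundle$sites)
    else matrix(1, nrow(D_y), ncol(D_y)) - diag(nrow(D_y))
    res$individual <- partial_mantel(D_y, D_id, ctrl, n_perm = mantel_perms,
                                     seed = seed + 3L)
    report$techniques <- lapply(res, function(r) r[c("r", "p", "n_perm")])
  }

  report <- structure(report, class = "run_report")
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), out, auto_unbox = TRUE, digits = NA,
                         force = TRUE, dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, ") stages: ",
      paste(x$stages, collapse = ", "), "\n", sep = "")
  if (!is.null(x$nbda))
    cat(sprintf("  NBDA: social family weight %.3f, %%ST %.1f\n",
                x$nbda$family_weights$social, x$nbda$percent_social))
  if (!is.null(x$ewa))
    cat("  EWA best model: ", x$ewa$waic$model[1], "\n", sep = "")
  if (!is.null(x$techniques))
    for (nm in names(x$techniques))
      cat(sprintf("  Mantel %s: r = %.4f, p = %.4f\n", nm,
                  x$techniques[[nm]]$r, x$techniques[[nm]]$p))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
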