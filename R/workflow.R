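# allowed configuration schema: nested named lists of known keys
workflow_schema <- function() list(
  seed = NULL, outdir = NULL, stages = NULL,
  variant = list(feedback_erk_to_ras = NULL, ligand = NULL),
  design = list(cell_lines = NULL, media = NULL, observables = NULL,
                tc_times = NULL, tc_egf = NULL, cetux_doses = NULL,
                dr_egf = NULL, dr_time = NULL, egf_doses = NULL,
                egf_time = NULL, replicates = NULL),
  truth = list(specificity = NULL, xi_magnitude = NULL, sigma_rel = NULL,
               scaling_sdlog = NULL),
  estimation = list(n_starts = NULL, margin = NULL, free_kinetic = NULL,
                    free_xi_cell = NULL, maxiter = NULL,
                    profile_scalings = NULL),
  selection = list(n_starts = NULL, top_n = NULL, free_kinetic = NULL),
  uncertainty = list(params = NULL, levels = NULL),
  predictions = list(experiments = NULL, knockdown_retained = NULL,
                     inhibitor_doses = NULL, long_term_minutes = NULL))

validate_config <- function(cfg, schema = workflow_schema(), path = "") {
  if (!is.list(cfg)) return(invisible(TRUE))
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg))
    if (is.list(schema[[k]]))
      validate_config(cfg[[k]], schema[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

#' Run the modeling workflow from a configuration
#'
#' Orchestrates generate -> fit -> select -> profile -> predict as requested
#' by \code{stages}. Every stage is seeded from the configuration seed;
#' artifacts (PEtab-style tables, waterfall and selection tables, profile
#' curves, prediction responses) are written under \code{outdir} together
#' with the resolved configuration and a JSON-lines log. A stage failure
#' halts downstream stages; artifacts of completed stages are retained.
#'
#' @param config path to a YAML file or a named list. Unknown keys are
#'   rejected with the offending key named.
#' @param outdir overrides the configured output directory.
#' @return invisibly, a list with the per-stage results.
#' @export
run_workflow <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_config(cfg)
  defaults <- list(seed = 1, outdir = "egfrsig_run",
                   stages = c("generate", "fit"),
                   variant = list(feedback_erk_to_ras = FALSE, ligand = "EGF"),
                   design = list(), truth = list(),
                   estimation = list(n_starts = 20, margin = 0.1,
                                     free_kinetic = c("k_degR", "k_int",
                                                      "k_erkOff", "k_aktOff"),
                                     free_xi_cell = character(),
                                     maxiter = 200,
                                     profile_scalings = FALSE),
                   selection = list(n_starts = 10, top_n = 100,
                                    free_kinetic = character()),
                   uncertainty = list(params = NULL,
                                      levels = c(0.90, 0.95, 0.99)),
                   predictions = list(experiments = "met-inhibitor",
                                      knockdown_retained = 0.2,
                                      inhibitor_doses = c(0, 0.1, 1, 10),
                                      long_term_minutes = 480))
  cfg <- utils::modifyList(defaults, cfg)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(cfg$outdir, "resolved_config.yaml"))
  logfile <- file.path(cfg$outdir, "log.jsonl")
  log_line <- function(...) {
    rec <- list(..., time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logfile, append = TRUE, sep = "")
  }
  wr <- function(x, f) utils::write.table(
    x, file.path(cfg$outdir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  res <- list()
  log_line(stage = "start", seed = cfg$seed,
           version = as.character(utils::packageVersion("egfrsig")))

  truth <- do.call(default_truth, c(list(seed = cfg$seed), cfg$truth))
  design <- do.call(pathway_design, cfg$design)

  if ("generate" %in% cfg$stages) {
    t0 <- proc.time()[3]
    res$dataset <- generate_dataset(truth, design, seed = cfg$seed)
    write_petab_tables(res$dataset, file.path(cfg$outdir, "petab"))
    yaml::write_yaml(list(seed = truth$seed,
                          specificity = truth$specificity,
                          xi_cell = as.list(truth$fc$cell_line),
                          xi_medium = as.list(truth$fc$medium),
                          sigma_rel = truth$sigma_rel),
                     file.path(cfg$outdir, "petab", "truth.yaml"))
    log_line(stage = "generate", status = "ok",
             n = nrow(res$dataset$measurements),
             seconds = round(proc.time()[3] - t0, 2))
  }

  if ("fit" %in% cfg$stages) {
    t0 <- proc.time()[3]
    if (is.null(res$dataset))
      res$dataset <- read_petab_tables(file.path(cfg$outdir, "petab"))
    est <- cfg$estimation
    prob <- pathway_problem(res$dataset,
                            free_kinetic = est$free_kinetic,
                            free_xi_cell = est$free_xi_cell,
                            profile_scalings = isTRUE(est$profile_scalings))
    res$fit <- fit_pathway(prob, n_starts = est$n_starts, seed = cfg$seed,
                           control = list(maxiter = est$maxiter))
    cc <- classify_convergence(res$fit, est$margin)
    wr(cbind(res$fit$results, label = cc$label), "waterfall.tsv")
    best <- coef(res$fit)
    wr(data.frame(parameterId = names(best), estimate = unname(best)),
       "best_parameters.tsv")
    log_line(stage = "fit", status = "ok", best_nll = res$fit$best_nll,
             seconds = round(proc.time()[3] - t0, 2))
  }

  if ("select" %in% cfg$stages) {
    t0 <- proc.time()[3]
    if (is.null(res$dataset))
      res$dataset <- read_petab_tables(file.path(cfg$outdir, "petab"))
    sel <- cfg$selection
    fits <- fit_hypotheses(res$dataset, n_starts = sel$n_starts,
                           seed = cfg$seed,
                           free_kinetic = sel$free_kinetic)
    res$selection <- rank_models(fits)
    wr(res$selection$table, "selection.tsv")
    log_line(stage = "select", status = "ok", best = res$selection$best,
             seconds = round(proc.time()[3] - t0, 2))
  }

  if ("profile" %in% cfg$stages) {
    t0 <- proc.time()[3]
    if (is.null(res$fit)) stop("profile stage requires the fit stage")
    pars <- cfg$uncertainty$params
    free <- res$fit$problem$free
    dyn <- free$pid[free$kind %in% c("kinetic", "xi_cell", "xi_medium")]
    if (is.null(pars) || identical(pars, "all")) pars <- dyn
    res$profiles <- lapply(pars, function(p)
      profile_likelihood(res$fit, p, levels = cfg$uncertainty$levels))
    names(res$profiles) <- pars
    curves <- do.call(rbind, lapply(res$profiles, function(pr)
      cbind(parameter = pr$param, pr$grid)))
    cis <- do.call(rbind, lapply(res$profiles, function(pr)
      cbind(parameter = pr$param, pr$ci,
            identifiable = pr$identifiable)))
    wr(curves, "profiles.tsv"); wr(cis, "profile_ci.tsv")
    fm <- fim(res$fit)
    wr(data.frame(eigenvalue = fm$eigenvalues,
                  normalized = fm$normalized), "fim_spectrum.tsv")
    log_line(stage = "profile", status = "ok",
             identifiable = sum(vapply(res$profiles, `[[`, TRUE,
                                       "identifiable")),
             sloppy = fm$sloppy,
             seconds = round(proc.time()[3] - t0, 2))
  }

  if ("predict" %in% cfg$stages) {
    t0 <- proc.time()[3]
    prd <- cfg$predictions
    base <- param_values(truth$params)
    th_hs <- resolve_parameters(base, truth$fc, "Hs746T", "FM")
    th_mk <- resolve_parameters(base, truth$fc, "MKN1", "FM")
    res$predictions <- list()
    for (ex in prd$experiments) {
      out <- switch(ex,
        "met-inhibitor" = {
          sim <- simulate_met_inhibitor(th_hs, doses = prd$inhibitor_doses)
          data.frame(experiment = ex, dose = sim$doses, sim$normalized)
        },
        "met-kd" = , "egfr-kd" = {
          target <- if (ex == "met-kd") "k_synM" else "k_synR"
          cl <- if (ex == "met-kd") "Hs746T" else "MKN1"
          th <- if (ex == "met-kd") th_hs else th_mk
          net <- build_network(pathway_variant(cl))
          obs <- pathway_observables(net)[c("obs_pEGFR", "obs_pERK",
                                            "obs_pAKT")]
          do.call(rbind, lapply(c(1, prd$knockdown_retained), function(fr) {
            co <- pathway_condition(ligand_dose = 5,
                                    knockdown = stats::setNames(list(fr),
                                                                target),
                                    timepoints = c(0, 5, 60))
            om <- observable_matrix(simulate_condition(net, th, co), obs)
            data.frame(experiment = ex, retained = fr,
                       time = c(0, 5, 60), om)
          }))
        },
        "areg" = {
          sim <- simulate_areg(th_mk)
          data.frame(experiment = ex, time = sim$times,
                     arm = rep(c("AREG", "AREG+cetuximab"),
                               each = length(sim$times)),
                     rbind(sim$ligand_only, sim$ligand_plus_cetuximab))
        },
        "long-term" = {
          net <- build_network(pathway_variant("MKN1"))
          obs <- pathway_observables(net)[c("obs_pEGFR", "obs_pERK",
                                            "obs_pAKT")]
          tms <- seq(0, prd$long_term_minutes, by = 30)
          co <- pathway_condition(ligand_dose = 30, timepoints = tms)
          om <- observable_matrix(simulate_condition(net, th_mk, co), obs)
          data.frame(experiment = ex, time = tms, om)
        },
        "pi3k-wt" = {
          net <- build_network(pathway_variant("MKN1"))
          obs <- pathway_observables(net)["obs_pAKT"]
          run <- function(th, cet) {
            co <- pathway_condition(ligand_dose = 30, cetuximab_dose = cet,
                                    timepoints = c(0, 60))
            observable_matrix(simulate_condition(net, th, co), obs)[2, 1]
          }
          data.frame(experiment = ex,
                     genotype = c("mutant", "wildtype"),
                     pAKT_untreated = c(run(th_mk, 0),
                                        run(swap_pi3k_wildtype(th_mk), 0)),
                     pAKT_cetuximab = c(run(th_mk, 10),
                                        run(swap_pi3k_wildtype(th_mk), 10)))
        },
        stop("unknown prediction experiment: ", ex))
      res$predictions[[ex]] <- out
      wr(out, paste0("predict_", gsub("[^a-z0-9]", "_", ex), ".tsv"))
    }
    log_line(stage = "predict", status = "ok",
             seconds = round(proc.time()[3] - t0, 2))
  }

  log_line(stage = "done", status = "ok")
  invisible(res)
}
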