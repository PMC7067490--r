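#' Ground-truth parameterization for synthetic studies
#'
#' The default truth mirrors the selected cell-line-specificity structure:
#' only the EGFR turnover module (internalization, degradation, recycling)
#' differs between cell lines, plus the expression difference of 2.5-fold
#' higher EGFR synthesis in MKN1 than Hs746T. Base parameters are the package
#' defaults (MKN1, rich medium); the seed fixes the stochastic observation
#' layer (scaling factors, noise draws) of datasets generated from this truth.
#'
#' @param seed integer seed stored with the truth.
#' @param specificity character vector of modules whose parameters truly
#'   differ between cell lines (default \code{"egfr_turnover"}); \code{NULL}
#'   or empty for no module differences.
#' @param xi_magnitude absolute log-fold-change magnitude for truly different
#'   module parameters (default \code{log(3)}; signs alternate across the
#'   module's parameters).
#' @param sigma_rel noise SD as a fraction of each observable's simulated
#'   dynamic range (default 0.10).
#' @param scaling_sdlog log-normal SD of the per-(observable, gel) scaling
#'   factors (default 0.2).
#' @return object of class \code{synthetic_truth}.
#' @export
default_truth <- function(seed = 1, specificity = "egfr_turnover",
                          xi_magnitude = log(3), sigma_rel = 0.10,
                          scaling_sdlog = 0.2) {
  params <- default_parameters()
  xi_cell <- c(k_synR = -log(2.5))  # Hs746T expresses 2.5x less EGFR
  for (mod in specificity) {
    pn <- module_xi_parameters(mod)
    xi_cell[pn] <- xi_magnitude * (-1)^(seq_along(pn) - 1)
  }
  structure(list(params = params,
                 fc = fold_change_spec(cell_line = xi_cell,
                                       medium = c(k_synR = -log(2)),
                                       params = params),
                 specificity = specificity,
                 xi_magnitude = xi_magnitude,
                 sigma_rel = sigma_rel, scaling_sdlog = scaling_sdlog,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Experimental design for synthetic immunoblot datasets
#'
#' Emulates the study layout: an EGF time course, a cetuximab dose response
#' at fixed EGF, and an EGF dose response, for each cell line and medium, with
#' replicate blots. Each (cell line, medium, series) is one experiment (gel)
#' with its own scaling factor per observable.
#'
#' @param cell_lines subset of \code{c("MKN1", "Hs746T")}.
#' @param media subset of \code{c("FM", "HM")}.
#' @param observables observable ids measured (pMMET/MET only meaningful for
#'   Hs746T and are dropped automatically for MKN1).
#' @param tc_times time-course grid (min) at \code{tc_egf} ng/ml EGF.
#' @param tc_egf time-course EGF dose (ng/ml).
#' @param cetux_doses cetuximab dose-response doses (ug/ml; 0 added as
#'   control) at \code{dr_egf} ng/ml EGF, sampled at \code{dr_time} min.
#' @param egf_doses EGF dose-response doses (ng/ml) at \code{egf_time} min;
#'   \code{NULL} disables the series.
#' @param inhibitor_doses MET inhibitor time-course doses (a.u.) on the
#'   \code{tc_times} grid, for mutant-MET cell lines; \code{NULL} disables
#'   the series.
#' @param replicates biological replicates per design point (default 3).
#' @return object of class \code{pathway_design} with \code{conditions} and
#'   a measurement \code{skeleton}.
#' @export
pathway_design <- function(cell_lines = c("MKN1", "Hs746T"),
                           media = "FM",
                           observables = c("obs_EGFR", "obs_pEGFR",
                                           "obs_pERK", "obs_pAKT"),
                           tc_times = c(0, 5, 15, 30, 60, 120, 240),
                           tc_egf = 30,
                           cetux_doses = c(0.05, 0.1, 1, 10, 50),
                           dr_egf = 30, dr_time = 60,
                           egf_doses = c(5, 30, 100), egf_time = 15,
                           inhibitor_doses = NULL,
                           replicates = 3) {
  stopifnot(replicates >= 1)
  conds <- list(); skel <- list()
  add_cond <- function(cid, cl, med, egf, cet, inh = 0) {
    conds[[cid]] <<- data.frame(
      condition_id = cid, cell_line = cl, medium = med,
      ligand_dose = egf, cetuximab_dose = cet, inhibitor_dose = inh,
      kd_target = NA_character_, kd_fraction = NA_real_,
      stringsAsFactors = FALSE)
  }
  add_meas <- function(cid, cl, times, series) {
    eid <- paste(cl, conds[[cid]]$medium, series, sep = "_")
    obs <- observables
    if (cl != "Hs746T") obs <- setdiff(obs, c("obs_MET", "obs_pMMET"))
    for (o in obs) for (t in times) for (r in seq_len(replicates))
      skel[[length(skel) + 1L]] <<- data.frame(
        condition_id = cid, observable_id = o, time = t, replicate = r,
        experiment_id = eid, stringsAsFactors = FALSE)
  }
  for (cl in cell_lines) for (med in media) {
    cid <- paste(cl, med, "tc", sep = "_")
    add_cond(cid, cl, med, tc_egf, 0)
    add_meas(cid, cl, tc_times, "tc")
    if (!is.null(cetux_doses)) {
      for (cd in c(0, cetux_doses)) {
        cid <- paste(cl, med, "cet", cd, sep = "_")
        add_cond(cid, cl, med, dr_egf, cd)
        add_meas(cid, cl, dr_time, "drC")
      }
    }
    if (!is.null(egf_doses)) {
      for (ed in egf_doses) {
        cid <- paste(cl, med, "egf", ed, sep = "_")
        add_cond(cid, cl, med, ed, 0)
        add_meas(cid, cl, egf_time, "drE")
      }
    }
    if (!is.null(inhibitor_doses) && cl == "Hs746T") {
      for (id in inhibitor_doses) {
        cid <- paste(cl, med, "inh", id, sep = "_")
        add_cond(cid, cl, med, 0, 0, inh = id)
        add_meas(cid, cl, tc_times, "inh")
      }
    }
  }
  structure(list(conditions = do.call(rbind, c(conds,
                                               make.row.names = FALSE)),
                 skeleton = do.call(rbind, c(skel, make.row.names = FALSE)),
                 replicates = replicates),
            class = "pathway_design")
}

#' Generate a synthetic immunoblot dataset
#'
#' Simulates every design condition from the pre-equilibrated steady state of
#' the truth parameterization, applies per-(observable, gel) scaling factors
#' (log-normal around 1), sets each observable's noise SD to
#' \code{sigma_rel} times its scaled dynamic range within the experiment, and
#' adds independent Gaussian noise if enabled. Reproducible end-to-end from
#' (truth, design, seed).
#'
#' @param truth \code{synthetic_truth}.
#' @param design \code{pathway_design}.
#' @param noise add measurement noise (default TRUE).
#' @param seed RNG seed for scalings and noise.
#' @return \code{pathway_dataset} with the true sigma table, and attributes
#'   \code{truth}, \code{scalings} (true factors) and \code{inventory}
#'   (data-point counts per cell line and observable).
#' @export
generate_dataset <- function(truth, design, noise = TRUE, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(design, "pathway_design"))
  set.seed(seed)
  m <- design$skeleton
  cond <- design$conditions
  base <- param_values(truth$params)

  # simulate unscaled observable values per record
  f <- numeric(nrow(m))
  ck <- cond[match(m$condition_id, cond$condition_id), ]
  for (cl in unique(cond$cell_line)) {
    inh <- any(cond$inhibitor_dose[cond$cell_line == cl] > 0, na.rm = TRUE)
    net <- build_network(pathway_variant(cl, inhibitor_enabled = inh))
    obs <- pathway_observables(net)
    for (med in unique(cond$medium[cond$cell_line == cl])) {
      theta <- resolve_parameters(base, truth$fc, cl, med)
      pe <- preequilibrate(net, theta)
      sel_c <- cond$cell_line == cl & cond$medium == med
      for (cid in cond$condition_id[sel_c]) {
        rows <- which(m$condition_id == cid)
        if (!length(rows)) next
        times <- sort(unique(m$time[rows]))
        crow <- cond[cond$condition_id == cid, ]
        kd <- NULL
        if (!is.null(crow$kd_target) && !is.na(crow$kd_target))
          kd <- stats::setNames(list(crow$kd_fraction), crow$kd_target)
        co <- pathway_condition(ligand_dose = crow$ligand_dose,
                                cetuximab_dose = crow$cetuximab_dose,
                                inhibitor_dose = crow$inhibitor_dose,
                                medium = med, knockdown = kd,
                                timepoints = times)
        tr <- simulate_condition(net, theta, co,
                                 preeq = if (is.null(kd)) pe else NULL)
        fm <- observable_matrix(tr, obs[unique(m$observable_id[rows])])
        f[rows] <- fm[cbind(match(m$time[rows], times),
                            match(m$observable_id[rows], colnames(fm)))]
      }
    }
  }

  # per-(observable, gel) scaling factors and noise SDs
  sc_key <- paste(m$observable_id, m$experiment_id, sep = "|")
  keys <- sort(unique(sc_key))
  scalings <- stats::setNames(
    exp(stats::rnorm(length(keys), 0, truth$scaling_sdlog)), keys)
  scaled <- scalings[sc_key] * f
  sig <- vapply(keys, function(k) {
    v <- scaled[sc_key == k]
    max(truth$sigma_rel * diff(range(v)), 1e-4)
  }, 0)
  m$value <- scaled + if (noise)
    stats::rnorm(nrow(m), 0, sig[sc_key]) else 0

  sig_tab <- data.frame(
    observable_id = sub("\\|.*$", "", keys),
    experiment_id = sub("^.*\\|", "", keys),
    sigma = unname(sig), stringsAsFactors = FALSE)
  ds <- pathway_dataset(m, cond, sigma = sig_tab)
  attr(ds, "truth") <- truth
  attr(ds, "scalings") <- scalings
  attr(ds, "inventory") <- as.data.frame(
    table(cell_line = ck$cell_line, observable = m$observable_id),
    stringsAsFactors = FALSE)
  ds
}

#' Generate datasets under every specificity hypothesis
#'
#' For each of the module-specificity hypotheses, generates \code{n}
#' replicate datasets from a truth in which exactly the flagged modules
#' differ between cell lines (|xi| = \code{xi_magnitude}), for
#' selection-recovery studies.
#'
#' @param n replicates per hypothesis (>= 1).
#' @param design \code{pathway_design} (joint, both cell lines).
#' @param seed base seed; each (hypothesis, replicate) uses a deterministic
#'   offset.
#' @param xi_magnitude true fold-change magnitude (default \code{log(3)}).
#' @param hypotheses from \code{\link{enumerate_hypotheses}}.
#' @return nested list \code{result[[label]][[replicate]]} of datasets; each
#'   carries its generating truth as an attribute.
#' @export
generate_selection_suite <- function(n, design, seed = 1,
                                     xi_magnitude = log(3),
                                     hypotheses = enumerate_hypotheses()) {
  stopifnot(n >= 1)
  out <- list()
  modules <- setdiff(names(hypotheses), c("label", "free_xi"))
  for (i in seq_len(nrow(hypotheses))) {
    lab <- hypotheses$label[i]
    mods <- modules[unlist(hypotheses[i, modules])]
    tr <- default_truth(seed = seed, specificity = mods,
                        xi_magnitude = xi_magnitude)
    out[[lab]] <- lapply(seq_len(n), function(r)
      generate_dataset(tr, design, noise = TRUE,
                       seed = seed + 1000L * i + r))
  }
  out
}
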