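#' Normalize simulated responses
#'
#' \code{"max"} divides each observable's series by its maximum (values in
#' [0, 1], maximum exactly 1); \code{"untreated"} divides by the untreated
#' reference so the untreated condition maps to 1.
#'
#' @param x numeric vector or matrix (columns = observables/series).
#' @param mode \code{"max"} or \code{"untreated"}.
#' @param reference reference value(s) for untreated mode (scalar or one per
#'   column); must be nonzero.
#' @return normalized object of the same shape.
#' @export
normalize_response <- function(x, mode = c("max", "untreated"),
                               reference = NULL) {
  mode <- match.arg(mode)
  xm <- as.matrix(x)
  if (!length(xm)) stop("empty response")
  if (mode == "max") {
    mx <- apply(xm, 2, max)
    if (any(mx <= 0)) stop("non-positive maximum; cannot normalize")
    out <- sweep(xm, 2, mx, `/`)
  } else {
    if (is.null(reference)) stop("untreated mode requires a reference")
    if (any(reference == 0)) stop("zero untreated reference")
    out <- sweep(xm, 2, rep(reference, length.out = ncol(xm)), `/`)
  }
  if (is.vector(x)) drop(out) else out
}

#' In-silico MET inhibitor treatment of the mutant-MET cell line
#'
#' Simulates an inert-complex-forming MET inhibitor (irreversible binding on
#' the experiment timescale) at the given doses in the Hs746T variant and
#' reports pMMET and pAKT (and pERK) normalized to the untreated condition.
#'
#' @param params named resolved parameter vector for the Hs746T context.
#' @param doses inhibitor doses (a.u.), 0 is the untreated reference and is
#'   added if absent.
#' @param times timepoints (min); responses are reported at the last time.
#' @param ligand_dose optional co-stimulation with EGF (ng/ml).
#' @param cell_line must be a mutant-MET cell line (\code{"Hs746T"}).
#' @return list with \code{doses}, \code{raw} and \code{normalized}
#'   (dose x observable matrices at the final time), and \code{trajectories}.
#' @export
simulate_met_inhibitor <- function(params, doses = c(0, 0.1, 0.3, 1, 3, 10),
                                   times = c(0, 30, 60, 120, 240),
                                   ligand_dose = 0, cell_line = "Hs746T") {
  variant <- pathway_variant(cell_line, inhibitor_enabled = TRUE)
  net <- build_network(variant)
  obs <- pathway_observables(net)
  doses <- sort(unique(c(0, doses)))
  keep_obs <- c("obs_pMMET", "obs_pAKT", "obs_pERK")
  trajs <- lapply(doses, function(d) {
    co <- pathway_condition(ligand_dose = ligand_dose, inhibitor_dose = d,
                            timepoints = times)
    simulate_condition(net, params, co)
  })
  final <- t(vapply(trajs, function(tr)
    observable_matrix(tr, obs[keep_obs])[length(times), ], numeric(3)))
  dimnames(final) <- list(paste0("dose_", doses), keep_obs)
  ref <- final[1, ]
  if (any(ref == 0)) stop("zero untreated reference signal")
  list(doses = doses, raw = final,
       normalized = sweep(final, 2, ref, `/`),
       trajectories = trajs)
}

#' AREG stimulation with and without cetuximab
#'
#' Uses the identical network with the ligand association constant divided by
#' the affinity ratio (AREG binds EGFR with about 50-fold lower affinity than
#' EGF). Reports pEGFR/pERK/pAKT time courses under ligand alone and ligand
#' plus cetuximab.
#'
#' @param params named resolved parameter vector.
#' @param ligand_dose AREG dose (ng/ml).
#' @param cetuximab_dose cetuximab dose (ug/ml).
#' @param times timepoints (min).
#' @param affinity_ratio EGF:AREG affinity ratio (> 0, default 50; 1
#'   reproduces the EGF model exactly).
#' @param cell_line cell-line preset for the structural variant.
#' @param normalize \code{"max"}, \code{"untreated"} or \code{"none"}.
#' @return list with per-arm observable matrices (\code{ligand_only},
#'   \code{ligand_plus_cetuximab}), the normalization mode and ratio used.
#' @export
simulate_areg <- function(params, ligand_dose = 30, cetuximab_dose = 1,
                          times = c(0, 5, 15, 30, 60, 120, 240),
                          affinity_ratio = 50, cell_line = "MKN1",
                          normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  variant <- pathway_variant(cell_line, ligand = "AREG",
                             areg_affinity_ratio = affinity_ratio)
  net <- build_network(variant)
  obs <- pathway_observables(net)[c("obs_pEGFR", "obs_pERK", "obs_pAKT")]
  run <- function(cet) {
    co <- pathway_condition(ligand_dose = ligand_dose, cetuximab_dose = cet,
                            timepoints = times)
    observable_matrix(simulate_condition(net, params, co), obs)
  }
  a <- run(0); b <- run(cetuximab_dose)
  if (normalize == "max") {
    mx <- pmax(apply(a, 2, max), apply(b, 2, max))
    a <- sweep(a, 2, mx, `/`); b <- sweep(b, 2, mx, `/`)
  }
  list(times = times, ligand_only = a, ligand_plus_cetuximab = b,
       affinity_ratio = affinity_ratio, normalized = normalize)
}
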