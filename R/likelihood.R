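#' Immunoblot observables of the signaling model
#'
#' Observables are linear combinations of species: total EGFR counts the
#' receptor units in every EGFR-containing species (phospho-dimers count two),
#' pEGFR the phosphorylated receptor units, pERK/pAKT the phosphorylated
#' kinase pools, and total/phospho MET the mutant-MET pools (including inert
#' inhibitor complexes for total MET).
#'
#' @param net \code{pathway_network}.
#' @return named list mapping observable id to a named coefficient vector over
#'   the network's species.
#' @export
pathway_observables <- function(net) {
  ids <- net$species$id
  cf <- function(...) {
    w <- c(...)
    w[names(w) %in% ids]
  }
  obs <- list(
    obs_EGFR  = cf(R = 1, LR = 1, CR = 1, pD = 2, pDi = 2),
    obs_pEGFR = cf(pD = 2, pDi = 2),
    obs_pERK  = cf(pERK = 1),
    obs_pAKT  = cf(pAKT = 1))
  if ("MMET" %in% ids) {
    obs$obs_MET <- cf(MMET = 1, pMMET = 1, IM = 1, IpM = 1)
    obs$obs_pMMET <- cf(pMMET = 1)
  }
  obs
}

# time x observable matrix of unscaled observable formulas
observable_matrix <- function(traj, observables) {
  out <- matrix(0, length(traj$time), length(observables),
                dimnames = list(NULL, names(observables)))
  for (o in names(observables)) {
    w <- observables[[o]]
    out[, o] <- traj$states[, names(w), drop = FALSE] %*% w
  }
  out
}

#' Predict scaled observables from a trajectory
#'
#' Applies the per-experiment scaling factor of each observable:
#' \code{h = scaling * formula(x(t))}.
#'
#' @param traj \code{pathway_trajectory}.
#' @param observables observable list from \code{pathway_observables}.
#' @param scalings named numeric vector of scaling factors keyed by observable
#'   id (for one experiment/gel). Missing keys raise an error.
#' @return matrix time x observable of predicted measurement values.
#' @export
predict_observables <- function(traj, observables, scalings = NULL) {
  f <- observable_matrix(traj, observables)
  if (is.null(scalings))
    scalings <- stats::setNames(rep(1, length(observables)), names(observables))
  miss <- setdiff(colnames(f), names(scalings))
  if (length(miss))
    stop("missing scaling factor for observable(s): ",
         paste(miss, collapse = ", "))
  sweep(f, 2, scalings[colnames(f)], `*`)
}

#' Measurement dataset
#'
#' Bundles measurement records with their condition definitions and
#' per-(observable, experiment) noise standard deviations. Experiments (gels)
#' index groups of records that share one scaling factor per observable; blot
#' intensities are comparable within but not across gels.
#'
#' @param measurements data.frame with columns \code{condition_id},
#'   \code{observable_id}, \code{time}, \code{replicate}, \code{experiment_id},
#'   \code{value}.
#' @param conditions data.frame with columns \code{condition_id},
#'   \code{cell_line}, \code{medium}, \code{ligand_dose},
#'   \code{cetuximab_dose}, \code{inhibitor_dose}, and optional
#'   \code{kd_target}, \code{kd_fraction}.
#' @param sigma optional data.frame (\code{observable_id},
#'   \code{experiment_id}, \code{sigma}); estimated from replicates via
#'   \code{\link{estimate_noise_sd}} when omitted at fitting time.
#' @return object of class \code{pathway_dataset}.
#' @export
pathway_dataset <- function(measurements, conditions, sigma = NULL) {
  need <- c("condition_id", "observable_id", "time", "replicate",
            "experiment_id", "value")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(measurements[, c("condition_id", "observable_id", "time",
                                     "replicate", "experiment_id")]))
    stop("duplicate (condition, observable, time, replicate, experiment) records")
  if (!all(is.finite(measurements$value))) stop("non-finite measurement values")
  if (!all(measurements$condition_id %in% conditions$condition_id))
    stop("measurements reference unknown conditions")
  if (!is.null(sigma) && any(sigma$sigma <= 0)) stop("sigma must be > 0")
  structure(list(measurements = measurements, conditions = conditions,
                 sigma = sigma),
            class = "pathway_dataset")
}

#' Pooled replicate noise estimation
#'
#' Estimates one noise SD per (observable, experiment): the square root of the
#' mean within-replicate-group variance over all design points with at least
#' two replicates. SDs are assumed independent of time and treatment within an
#' experimental setup, and are treated as fixed during optimization. A floor of
#' \code{1e-3} times the observable's value range guards against degenerate
#' (zero-variance) likelihoods.
#'
#' @param dataset \code{pathway_dataset}.
#' @return data.frame \code{observable_id}, \code{experiment_id}, \code{sigma},
#'   with attribute \code{degenerate} listing floored entries.
#' @export
estimate_noise_sd <- function(dataset) {
  m <- dataset$measurements
  key <- interaction(m$observable_id, m$experiment_id, drop = TRUE)
  out <- list(); degenerate <- character()
  for (k in levels(key)) {
    mk <- m[key == k, , drop = FALSE]
    grp <- interaction(mk$condition_id, mk$time, drop = TRUE)
    vars <- tapply(mk$value, grp, function(v)
      if (length(v) >= 2) stats::var(v) else NA_real_)
    vars <- vars[!is.na(vars)]
    if (!length(vars))
      stop("no replicated design point for (", k, "); supply sigma explicitly")
    s <- sqrt(mean(vars))
    floor_s <- 1e-3 * max(diff(range(mk$value)), 1e-12)
    if (s < floor_s) {
      s <- floor_s
      degenerate <- c(degenerate, k)
    }
    out[[k]] <- data.frame(observable_id = mk$observable_id[1],
                           experiment_id = mk$experiment_id[1],
                           sigma = s, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "degenerate") <- degenerate
  res
}

# sigma per measurement row
sigma_for_records <- function(measurements, sigma) {
  i <- match(paste(measurements$observable_id, measurements$experiment_id),
             paste(sigma$observable_id, sigma$experiment_id))
  if (anyNA(i))
    stop("missing sigma entries for some (observable, experiment) pairs")
  s <- sigma$sigma[i]
  if (any(s <= 0)) stop("sigma must be > 0")
  s
}

#' Negative log-likelihood of Gaussian measurement noise
#'
#' \code{0.5 * sum(((y - h) / sigma)^2) + 0.5 * sum(log(2 pi sigma^2))}. The
#' additive constant is included explicitly so AIC values remain comparable
#' across noise maps.
#'
#' @param y,h,sigma measurement values, predictions and noise SDs, aligned.
#' @return scalar negative log-likelihood.
#' @export
negloglik <- function(y, h, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  0.5 * sum(((y - h) / sigma)^2) + 0.5 * sum(log(2 * pi * sigma^2))
}

#' Weighted residual vector
#'
#' \code{r_i = (y_i - h_i) / sigma_i}; \code{0.5 * ||r||^2} is the quadratic
#' part of \code{\link{negloglik}}.
#'
#' @inheritParams negloglik
#' @return numeric residual vector.
#' @export
weighted_residuals <- function(y, h, sigma) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  (y - h) / sigma
}

# the sigma-dependent additive constant of the negative log-likelihood
negloglik_const <- function(sigma) 0.5 * sum(log(2 * pi * sigma^2))
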