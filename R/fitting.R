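#' Define a maximum-likelihood estimation problem
#'
#' Binds a dataset to the signaling model and declares which parameters are
#' estimated: kinetic/abundance base parameters (log10 scale), cell-line and
#' medium log-fold-changes xi (natural scale), and per-(observable, experiment)
#' scaling factors (log10 scale). Noise SDs are estimated from replicates once
#' and then held fixed.
#'
#' @param dataset a \code{pathway_dataset}.
#' @param base_params parameter table (\code{\link{default_parameters}} form).
#' @param free_kinetic names of base parameters estimated on log10 scale.
#' @param free_xi_cell names of parameters whose Hs746T/MKN1 log-fold-change is
#'   estimated (must not be of class \code{direct}).
#' @param free_xi_medium names of parameters whose HM/FM log-fold-change is
#'   estimated (must be of class \code{expression}).
#' @param fixed named numeric overrides of base parameter values.
#' @param xi_cell,xi_medium named numeric vectors of fixed (not estimated)
#'   fold-changes.
#' @param free_scalings estimate scaling factors as free parameters (default
#'   TRUE). Ignored when \code{profile_scalings} is TRUE.
#' @param profile_scalings solve each scaling factor analytically (conditional
#'   linear least squares) inside every objective evaluation instead of
#'   estimating it by the optimizer. Off by default; the profiled optimum is
#'   identical but the search space is smaller.
#' @param sigma noise SD table; estimated via \code{\link{estimate_noise_sd}}
#'   when NULL.
#' @param feedback_erk_to_ras include the pERK -| RAS feedback variant.
#' @param ligand \code{"EGF"} or \code{"AREG"}.
#' @param xi_bounds bounds for xi parameters (natural log scale).
#' @param scaling_bounds_log10 bounds for log10 scaling factors.
#' @param ode_rtol,ode_atol integrator tolerances used for all simulations of
#'   this problem (smooth objectives need tight values; default 1e-8/1e-10).
#' @param priors optional Gaussian penalties on log10 kinetic parameters:
#'   data.frame with columns \code{name}, \code{mean_log10}, \code{sd_log10}.
#' @return object of class \code{pathway_problem}.
#' @export
pathway_problem <- function(dataset,
                            base_params = default_parameters(),
                            free_kinetic = character(),
                            free_xi_cell = character(),
                            free_xi_medium = character(),
                            fixed = NULL,
                            xi_cell = numeric(), xi_medium = numeric(),
                            free_scalings = TRUE,
                            profile_scalings = FALSE,
                            sigma = NULL,
                            feedback_erk_to_ras = FALSE,
                            ligand = "EGF",
                            xi_bounds = c(-3, 3),
                            scaling_bounds_log10 = c(-2, 2),
                            ode_rtol = 1e-8, ode_atol = 1e-10,
                            priors = NULL) {
  stopifnot(inherits(dataset, "pathway_dataset"))
  ptab <- base_params
  all_names <- ptab$name
  bad <- setdiff(c(free_kinetic, free_xi_cell, free_xi_medium,
                   names(fixed), names(xi_cell), names(xi_medium)), all_names)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  cl_free <- param_class(ptab, free_xi_cell)
  if (any(cl_free == "direct"))
    stop("cell-line fold-changes are fixed to zero for direct-interaction ",
         "parameters: ",
         paste(free_xi_cell[cl_free == "direct"], collapse = ", "))
  md_free <- param_class(ptab, free_xi_medium)
  if (any(md_free != "expression"))
    stop("medium fold-changes are allowed only for expression parameters: ",
         paste(free_xi_medium[md_free != "expression"], collapse = ", "))
  # fixed xi values go through the same validation
  fold_change_spec(xi_cell, xi_medium, ptab)

  if (!is.null(fixed)) {
    ptab$value[match(names(fixed), ptab$name)] <- unlist(fixed)
  }
  if (is.null(sigma)) sigma <- estimate_noise_sd(dataset)

  m <- dataset$measurements
  cond <- dataset$conditions
  cell_lines <- sort(unique(cond$cell_line[cond$condition_id %in% m$condition_id]))
  networks <- list()
  observables <- list()
  for (cl in cell_lines) {
    inh <- any(cond$inhibitor_dose[cond$cell_line == cl] > 0, na.rm = TRUE)
    networks[[cl]] <- build_network(pathway_variant(
      cl, inhibitor_enabled = inh, ligand = ligand,
      feedback_erk_to_ras = feedback_erk_to_ras))
    observables[[cl]] <- pathway_observables(networks[[cl]])
  }

  # free-parameter table in optimizer (scaled) space
  free <- list()
  addf <- function(pid, kind, target, lower, upper, init)
    free[[length(free) + 1L]] <<- data.frame(
      pid = pid, kind = kind, target = target, lower = lower, upper = upper,
      init = init, stringsAsFactors = FALSE)
  for (nm in free_kinetic) {
    i <- match(nm, ptab$name)
    addf(nm, "kinetic", nm, log10(ptab$lower[i]), log10(ptab$upper[i]),
         log10(ptab$value[i]))
  }
  for (nm in free_xi_cell)
    addf(paste0("xi_", nm), "xi_cell", nm, xi_bounds[1], xi_bounds[2], 0)
  for (nm in free_xi_medium)
    addf(paste0("xiM_", nm), "xi_medium", nm, xi_bounds[1], xi_bounds[2], 0)

  sc_pairs <- unique(m[, c("observable_id", "experiment_id")])
  sc_pairs <- sc_pairs[order(sc_pairs$observable_id, sc_pairs$experiment_id), ]
  scaling_ids <- paste0("s_", sc_pairs$observable_id, "__", sc_pairs$experiment_id)
  if (!profile_scalings && isTRUE(free_scalings)) {
    for (i in seq_along(scaling_ids))
      addf(scaling_ids[i], "scaling",
           paste(sc_pairs$observable_id[i], sc_pairs$experiment_id[i], sep = "|"),
           scaling_bounds_log10[1], scaling_bounds_log10[2], 0)
  }
  free <- if (length(free)) do.call(rbind, free) else
    data.frame(pid = character(), kind = character(), target = character(),
               lower = numeric(), upper = numeric(), init = numeric())

  if (!is.null(priors)) {
    if (!all(priors$name %in% free$pid[free$kind == "kinetic"]))
      stop("priors must refer to free kinetic parameters")
  }

  # execution plan: group measurements by context and condition
  m$sigma <- sigma_for_records(m, sigma)
  m$sc_key <- paste(m$observable_id, m$experiment_id, sep = "|")
  plan <- list()
  ckey <- cond[match(m$condition_id, cond$condition_id), ]
  ctx_of_row <- paste(ckey$cell_line, ckey$medium, sep = "|")
  for (ctx in unique(ctx_of_row)) {
    rows <- which(ctx_of_row == ctx)
    cl <- ckey$cell_line[rows[1]]; med <- ckey$medium[rows[1]]
    conds <- list()
    for (cid in unique(m$condition_id[rows])) {
      crow <- cond[match(cid, cond$condition_id), ]
      crows <- rows[m$condition_id[rows] == cid]
      times <- sort(unique(m$time[crows]))
      kd <- NULL
      if (!is.null(crow$kd_target) && !is.na(crow$kd_target) &&
          nzchar(crow$kd_target))
        kd <- stats::setNames(list(crow$kd_fraction), crow$kd_target)
      co <- pathway_condition(
        ligand_dose = crow$ligand_dose, cetuximab_dose = crow$cetuximab_dose,
        inhibitor_dose = if (is.null(crow$inhibitor_dose) ||
                             is.na(crow$inhibitor_dose)) 0 else
          crow$inhibitor_dose,
        medium = med, knockdown = kd, timepoints = times)
      conds[[cid]] <- list(
        condition = co, rows = crows,
        kd_key = if (is.null(kd)) "" else
          paste(names(kd), unlist(kd), sep = ":", collapse = ";"),
        t_idx = match(m$time[crows], times))
    }
    plan[[ctx]] <- list(cell_line = cl, medium = med, conditions = conds)
  }

  sens_set <- unique(c(free_kinetic, free_xi_cell, free_xi_medium))
  row_is_hs <- ckey$cell_line == "Hs746T"
  row_is_hm <- ckey$medium == "HM"

  structure(list(dataset = dataset, params = ptab, sigma = sigma,
                 row_is_hs = row_is_hs, row_is_hm = row_is_hm,
                 networks = networks, observables = observables,
                 free = free,
                 xi_cell = xi_cell, xi_medium = xi_medium,
                 free_kinetic = free_kinetic, free_xi_cell = free_xi_cell,
                 free_xi_medium = free_xi_medium,
                 profile_scalings = isTRUE(profile_scalings),
                 scaling_ids = scaling_ids, sc_pairs = sc_pairs,
                 priors = priors, plan = plan, sens_set = sens_set,
                 ode_rtol = ode_rtol, ode_atol = ode_atol,
                 meas = m, const = negloglik_const(m$sigma)),
            class = "pathway_problem")
}

# Assemble base parameter vector and fold-change spec from a free-parameter
# vector in optimizer space.
unpack_par <- function(problem, par) {
  free <- problem$free
  theta <- param_values(problem$params)
  kin <- free$kind == "kinetic"
  theta[free$target[kin]] <- 10^par[kin]
  xi_c <- problem$xi_cell
  xc <- free$kind == "xi_cell"
  if (any(xc)) {
    v <- stats::setNames(par[xc], free$target[xc])
    xi_c <- c(xi_c[setdiff(names(xi_c), names(v))], v)
  }
  xi_m <- problem$xi_medium
  xm <- free$kind == "xi_medium"
  if (any(xm)) {
    v <- stats::setNames(par[xm], free$target[xm])
    xi_m <- c(xi_m[setdiff(names(xi_m), names(v))], v)
  }
  sc <- stats::setNames(rep(1, length(problem$scaling_ids)),
                        paste(problem$sc_pairs$observable_id,
                              problem$sc_pairs$experiment_id, sep = "|"))
  s <- free$kind == "scaling"
  if (any(s)) sc[free$target[s]] <- 10^par[s]
  list(theta = theta, fc = fold_change_spec(xi_c, xi_m, problem$params),
       scalings = sc)
}

# Full objective evaluation: residual vector and (optionally) its Jacobian.
problem_eval <- function(problem, par, want_jac = FALSE) {
  pp <- unpack_par(problem, par)
  m <- problem$meas
  free <- problem$free
  npar <- nrow(free)
  nrec <- nrow(m)
  h <- numeric(nrec)
  f_raw <- numeric(nrec)       # unscaled observable formula values
  dF <- if (want_jac) matrix(0, nrec, length(problem$sens_set)) else NULL
  mult <- if (want_jac) matrix(0, nrec, length(problem$sens_set)) else NULL
  colnames_dF <- problem$sens_set
  sens_set <- if (want_jac) problem$sens_set else character()

  for (ctx in problem$plan) {
    net <- problem$networks[[ctx$cell_line]]
    obs <- problem$observables[[ctx$cell_line]]
    theta <- resolve_parameters(pp$theta, pp$fc, ctx$cell_line, ctx$medium)
    # fold-changes only influence the contexts they apply to; restrict the
    # forward sensitivities accordingly
    sens_ctx <- problem$free_kinetic
    if (ctx$cell_line == "Hs746T")
      sens_ctx <- union(sens_ctx, problem$free_xi_cell)
    if (ctx$medium == "HM")
      sens_ctx <- union(sens_ctx, problem$free_xi_medium)
    sens_ctx <- if (want_jac) sens_ctx else character()
    sj_ctx <- match(sens_ctx, sens_set)
    # pre-equilibrations shared across conditions with equal knockdown
    preeqs <- list()
    for (cd in ctx$conditions) {
      key <- cd$kd_key
      if (is.null(preeqs[[paste0("k", key)]])) {
        th <- theta
        if (!is.null(cd$condition$knockdown))
          for (tg in names(cd$condition$knockdown))
            th <- apply_knockdown(th, tg, cd$condition$knockdown[[tg]])
        preeqs[[paste0("k", key)]] <- list(
          pe = preequilibrate(net, th, sens_ctx, rtol = problem$ode_rtol,
                              atol = problem$ode_atol), theta = th)
      }
      pe <- preeqs[[paste0("k", key)]]
      co <- cd$condition; co$knockdown <- NULL  # already applied
      traj <- simulate_condition(net, pe$theta, co,
                                 sens_params = sens_ctx, preeq = pe$pe,
                                 rtol = problem$ode_rtol,
                                 atol = problem$ode_atol)
      rows <- cd$rows
      o_ids <- m$observable_id[rows]
      fmat <- observable_matrix(traj, obs[unique(o_ids)])
      f_raw[rows] <- fmat[cbind(cd$t_idx, match(o_ids, colnames(fmat)))]
      if (want_jac && length(sens_ctx)) {
        for (o in unique(o_ids)) {
          w <- obs[[o]]
          orows <- rows[o_ids == o]
          dfo <- apply(traj$sens[, names(w), , drop = FALSE], 3,
                       function(sl) sl %*% w)
          dfo <- matrix(dfo, nrow = length(traj$time))
          dF[orows, sj_ctx] <- dfo[cd$t_idx[o_ids == o], , drop = FALSE]
        }
        # chain-rule multiplier: value of the parameter as used in this
        # context's simulation (resolved fold-changes, knockdowns applied)
        thv <- pe$theta[sens_ctx]
        mult[rows, sj_ctx] <- matrix(thv, length(rows), length(sens_ctx),
                                     byrow = TRUE)
      }
    }
  }

  sc_row <- pp$scalings[m$sc_key]
  if (problem$profile_scalings) {
    # conditional optimum of each scaling factor (linear least squares)
    a <- tapply(m$value * f_raw / m$sigma^2, m$sc_key, sum)
    b <- tapply(f_raw^2 / m$sigma^2, m$sc_key, sum)
    s_star <- pmax(a / pmax(b, 1e-300), 1e-12)
    sc_row <- s_star[m$sc_key]
  }
  h <- sc_row * f_raw
  r <- (m$value - h) / m$sigma

  J <- NULL
  if (want_jac) {
    J <- matrix(0, nrec, npar, dimnames = list(NULL, free$pid))
    ln10 <- log(10)
    for (j in seq_len(npar)) {
      kind <- free$kind[j]; target <- free$target[j]
      if (kind == "scaling") {
        sel <- m$sc_key == target
        J[sel, j] <- -h[sel] * ln10 / m$sigma[sel]
      } else {
        sj <- match(target, colnames_dF)
        dfdp <- dF[, sj] * mult[, sj]   # d f / d theta * theta_sim
        if (kind == "kinetic") dfdp <- dfdp * ln10
        if (kind == "xi_cell") {
          appl <- problem$row_is_hs
          dfdp[!appl] <- 0
        } else if (kind == "xi_medium") {
          appl <- problem$row_is_hm
          dfdp[!appl] <- 0
        }
        dh <- sc_row * dfdp
        if (problem$profile_scalings) {
          # ds*/dp within each scaling group
          num <- tapply((m$value - 2 * h) * dfdp / m$sigma^2, m$sc_key, sum)
          den <- tapply(f_raw^2 / m$sigma^2, m$sc_key, sum)
          ds <- (num / pmax(den, 1e-300))[m$sc_key]
          dh <- dh + f_raw * ds
        }
        J[, j] <- -dh / m$sigma
      }
    }
  }

  if (!is.null(problem$priors)) {
    pr <- problem$priors
    idx <- match(pr$name, free$pid)
    r_pr <- (par[idx] - pr$mean_log10) / pr$sd_log10
    r <- c(r, r_pr)
    if (want_jac) {
      Jp <- matrix(0, length(idx), npar)
      Jp[cbind(seq_along(idx), idx)] <- 1 / pr$sd_log10
      J <- rbind(J, Jp)
    }
  }
  list(residuals = r, jacobian = J, h = h, f_raw = f_raw)
}

# negative log-likelihood at a free-parameter vector (priors excluded from the
# reported likelihood; they only shape the objective)
problem_negloglik <- function(problem, par) {
  r <- problem_eval(problem, par, want_jac = FALSE)$residuals
  nmeas <- nrow(problem$meas)
  0.5 * sum(r[seq_len(nmeas)]^2) + problem$const
}

#' Latin hypercube sample of optimization starting points
#'
#' Draws n points in the free-parameter (scaled) space with one point per
#' equal-probability stratum in every dimension; deterministic under the seed.
#'
#' @param problem \code{pathway_problem} (or a 2-column matrix of bounds).
#' @param n number of starts.
#' @param seed RNG seed.
#' @return n x npar matrix with free-parameter ids as column names.
#' @export
sample_starts <- function(problem, n, seed = 1) {
  if (inherits(problem, "pathway_problem")) {
    lower <- problem$free$lower; upper <- problem$free$upper
    ids <- problem$free$pid
  } else {
    lower <- problem[, 1]; upper <- problem[, 2]
    ids <- rownames(problem)
  }
  stopifnot(n >= 1)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("sample_starts requires finite bounds")
  set.seed(seed)
  u <- lhs::randomLHS(n, length(lower))
  st <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  colnames(st) <- ids
  st
}

#' Multi-start maximum-likelihood estimation
#'
#' Runs a trust-region least-squares optimization (\code{minpack.lm::nls.lm},
#' Levenberg-Marquardt on the weighted residual vector with sensitivity-based
#' Jacobians) from each starting point, in log10 space for positive parameters
#' and natural scale for fold-changes. Starts whose integration fails are
#' recorded as failed rather than dropped.
#'
#' @param problem \code{pathway_problem}.
#' @param n_starts number of Latin hypercube starts (ignored when
#'   \code{starts} is given).
#' @param seed RNG seed for start sampling.
#' @param starts optional matrix of starting points (rows).
#' @param include_init also start once from the problem's initial values
#'   (default FALSE).
#' @param control list overriding optimizer options: \code{maxiter} (default
#'   300), \code{ftol}, \code{ptol} (default 1e-10).
#' @return object of class \code{pathway_fit}: per-start results sorted by
#'   final negative log-likelihood, best parameter vector, and the problem.
#' @export
fit_pathway <- function(problem, n_starts = 50, seed = 1, starts = NULL,
                        include_init = FALSE,
                        control = list()) {
  stopifnot(inherits(problem, "pathway_problem"))
  if (is.null(starts)) starts <- sample_starts(problem, n_starts, seed)
  if (!is.matrix(starts) || ncol(starts) != nrow(problem$free))
    stop("starts must be a matrix with one row per start and ",
         nrow(problem$free), " columns")
  if (include_init) starts <- rbind(problem$free$init, starts)
  ctl <- utils::modifyList(list(maxiter = 300, ftol = 1e-12, ptol = 1e-10),
                           control)
  nmeas <- nrow(problem$meas)
  res <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    out <- tryCatch({
      # optimizer notes (e.g. hitting the iteration cap) are kept in the
      # per-start status rather than raised as warnings
      fit <- suppressWarnings(minpack.lm::nls.lm(
        par = p0,
        fn = function(p) problem_eval(problem, p, FALSE)$residuals,
        jac = function(p) problem_eval(problem, p, TRUE)$jacobian,
        lower = problem$free$lower, upper = problem$free$upper,
        control = minpack.lm::nls.lm.control(
          maxiter = ctl$maxiter, ftol = ctl$ftol, ptol = ctl$ptol)))
      r <- fit$fvec
      nll <- 0.5 * sum(r[seq_len(nmeas)]^2) + problem$const
      list(par = fit$par, nll = nll, status = fit$message,
           niter = fit$niter, ok = TRUE)
    }, error = function(e)
      list(par = rep(NA_real_, length(p0)), nll = Inf,
           status = conditionMessage(e), niter = 0L, ok = FALSE))
    res[[i]] <- out
  }
  if (!any(vapply(res, `[[`, TRUE, "ok")))
    stop("all starts failed; first diagnostic: ", res[[1]]$status)
  nlls <- vapply(res, `[[`, 0, "nll")
  ord <- order(nlls)
  finals <- do.call(rbind, lapply(res, `[[`, "par"))[ord, , drop = FALSE]
  colnames(finals) <- problem$free$pid
  tab <- data.frame(
    start = ord,
    nll = nlls[ord],
    status = vapply(res, `[[`, "", "status")[ord],
    niter = vapply(res, `[[`, 0L, "niter")[ord],
    failed = !vapply(res, `[[`, TRUE, "ok")[ord],
    stringsAsFactors = FALSE)
  structure(list(problem = problem, results = tab, par = finals,
                 starts = starts[ord, , drop = FALSE],
                 best_par = finals[1, ], best_nll = tab$nll[1],
                 const = problem$const, seed = seed),
            class = "pathway_fit")
}

#' Classify multi-start convergence
#'
#' Labels each start \code{"global-plateau"} if its final negative
#' log-likelihood lies within \code{margin} of the best, \code{"local"}
#' otherwise, and \code{"failed"} for failed starts. A likelihood-ratio note
#' additionally marks fits within \code{qchisq(0.95, 1)/2} of the best as
#' statistically indistinguishable from it.
#'
#' @param fit \code{pathway_fit}.
#' @param margin numerical plateau margin (default 0.1 negloglik units).
#' @return data.frame with \code{nll}, \code{label},
#'   \code{indistinguishable}.
#' @export
classify_convergence <- function(fit, margin = 0.1) {
  nll <- fit$results$nll
  best <- fit$best_nll
  label <- ifelse(fit$results$failed | !is.finite(nll), "failed",
                  ifelse(nll <= best + margin, "global-plateau", "local"))
  data.frame(nll = nll, label = label,
             indistinguishable = is.finite(nll) &
               (nll <= best + stats::qchisq(0.95, 1) / 2),
             stringsAsFactors = FALSE)
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat("Multi-start pathway fit:", nrow(x$results), "starts,",
      sum(!x$results$failed), "successful\n")
  cat("  best -log L:", format(x$best_nll, digits = 8),
      " | free parameters:", nrow(x$problem$free), "\n")
  cc <- classify_convergence(x)
  cat("  plateau starts (margin 0.1):", sum(cc$label == "global-plateau"), "\n")
  invisible(x)
}

#' @export
summary.pathway_fit <- function(object, ...) {
  est <- coef(object)
  cat("Best-fit parameters (natural scale):\n")
  print(data.frame(parameter = names(est), estimate = unname(est)))
  cat("\n-log L:", object$best_nll, " AIC:",
      aic(object$best_nll, nrow(object$problem$free)), "\n")
  invisible(object)
}

#' @export
coef.pathway_fit <- function(object, ...) {
  free <- object$problem$free
  p <- object$best_par
  est <- ifelse(free$kind %in% c("kinetic", "scaling"), 10^p, p)
  stats::setNames(est, free$pid)
}

#' @export
logLik.pathway_fit <- function(object, ...) {
  structure(-object$best_nll, df = nrow(object$problem$free),
            class = "logLik")
}

#' @export
plot.pathway_fit <- function(x, n_best = min(200, nrow(x$results)), ...) {
  nll <- x$results$nll[seq_len(n_best)]
  cc <- classify_convergence(x)$label[seq_len(n_best)]
  plot(seq_along(nll), nll, pch = 19,
       col = ifelse(cc == "global-plateau", "red", "grey30"),
       xlab = "sorted optimizer run", ylab = "final -log L",
       main = "Waterfall plot", ...)
  invisible(x)
}

#' @export
predict.pathway_fit <- function(object, ...) {
  ev <- problem_eval(object$problem, object$best_par, want_jac = FALSE)
  m <- object$problem$meas
  data.frame(condition_id = m$condition_id, observable_id = m$observable_id,
             time = m$time, replicate = m$replicate,
             experiment_id = m$experiment_id, observed = m$value,
             predicted = ev$h, stringsAsFactors = FALSE)
}

#' @export
residuals.pathway_fit <- function(object, weighted = TRUE, ...) {
  ev <- problem_eval(object$problem, object$best_par, want_jac = FALSE)
  m <- object$problem$meas
  r <- ev$residuals[seq_len(nrow(m))]
  if (weighted) r else r * m$sigma
}
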