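# molecular masses used to convert assay doses to nominal nM-equivalents
MASS_KDA <- c(EGF = 6.2, AREG = 6.2, cetuximab = 152)

#' Convert assay doses to nominal concentrations
#'
#' Ligand doses in ng/ml and cetuximab doses in ug/ml are converted to
#' nM-equivalent model inputs (dose / molecular mass in kDa, with the unit
#' factor 1000 for ug/ml). Residual unit ambiguity is absorbed by the rate
#' constants. The MET inhibitor dose is already in arbitrary concentration
#' units.
#'
#' @param ligand_ng_ml,cetuximab_ug_ml,inhibitor doses (>= 0).
#' @return named vector \code{c(L=, C=, I=)} in nM-equivalents.
#' @export
dose_inputs <- function(ligand_ng_ml = 0, cetuximab_ug_ml = 0, inhibitor = 0) {
  stopifnot(ligand_ng_ml >= 0, cetuximab_ug_ml >= 0, inhibitor >= 0)
  c(L = ligand_ng_ml / MASS_KDA[["EGF"]],
    C = cetuximab_ug_ml * 1000 / MASS_KDA[["cetuximab"]],
    I = inhibitor)
}

#' Treatment condition
#'
#' @param ligand_dose ligand (EGF or AREG) dose in ng/ml.
#' @param cetuximab_dose cetuximab dose in ug/ml.
#' @param inhibitor_dose MET inhibitor dose (a.u.).
#' @param medium \code{"FM"} (rich) or \code{"HM"} (starvation).
#' @param knockdown named list/vector mapping a synthesis parameter
#'   (\code{k_synR}, \code{k_synM}) to the retained fraction in [0, 1];
#'   applied before pre-equilibration.
#' @param timepoints observation times in minutes, sorted ascending, >= 0.
#' @return object of class \code{pathway_condition}.
#' @export
pathway_condition <- function(ligand_dose = 0, cetuximab_dose = 0,
                              inhibitor_dose = 0, medium = c("FM", "HM"),
                              knockdown = NULL,
                              timepoints = c(0, 5, 15, 30, 60, 120, 240)) {
  medium <- match.arg(medium)
  stopifnot(ligand_dose >= 0, cetuximab_dose >= 0, inhibitor_dose >= 0,
            all(timepoints >= 0), !is.unsorted(timepoints))
  if (!is.null(knockdown)) {
    kd <- unlist(knockdown)
    if (any(kd < 0 | kd > 1)) stop("knockdown retained fractions must be in [0, 1]")
    knockdown <- as.list(kd)
  }
  structure(list(ligand_dose = ligand_dose, cetuximab_dose = cetuximab_dose,
                 inhibitor_dose = inhibitor_dose, medium = medium,
                 knockdown = knockdown, timepoints = timepoints),
            class = "pathway_condition")
}

# pack the parameter block consumed by the compiled right-hand side
pack_parms <- function(net, params, inputs = c(L = 0, C = 0, I = 0),
                       sens_params = character()) {
  n <- nrow(net$species); nr <- nrow(net$reactions)
  kn <- unique(net$reactions$rate_param)
  K <- unname(params[kn])
  if (anyNA(K))
    stop("missing rate constants: ", paste(kn[is.na(K)], collapse = ", "))
  KI <- match(net$reactions$rate_param, kn) - 1L
  I1 <- match(net$reactions$r1, net$species$id); I1[is.na(I1)] <- 0L
  I2 <- match(net$reactions$r2, net$species$id); I2[is.na(I2)] <- 0L
  mod <- network_modifiers(net, inputs)
  mod[net$reactions$id == "bind_L"] <-
    mod[net$reactions$id == "bind_L"] * net$ligand_assoc_scale
  # rate-constant index per sensitivity parameter; -1 for IC-only parameters
  sk <- ifelse(sens_params %in% kn, match(sens_params, kn) - 1L, -1L)
  body <- c(n, nr, length(sens_params), length(kn),
            K, KI, I1 - 1L, I2 - 1L, mod, as.numeric(net$S), sk)
  p <- numeric(12000L)
  p[seq_along(body)] <- body
  p
}

# analytic unstimulated starting point used for pre-equilibration, and its
# parameter sensitivities
initial_state <- function(net, params) {
  x <- stats::setNames(numeric(nrow(net$species)), net$species$id)
  x["R"] <- params[["k_synR"]] / params[["k_degR"]]
  x["RASi"] <- params[["RAS_tot"]]
  x["ERK"] <- params[["ERK_tot"]]
  x["PI3Ki"] <- params[["PI3K_tot"]]
  x["AKT"] <- params[["AKT_tot"]]
  if ("MMET" %in% net$species$id)
    x["MMET"] <- params[["k_synM"]] / params[["k_degM"]]
  x
}

ode_integrate <- function(y, times, parms, rtol = 1e-8, atol = 1e-10) {
  out <- deSolve::lsoda(y = y, times = times, func = "pathway_derivs",
                        parms = parms, dllname = "egfrsig",
                        initfunc = "pathway_init",
                        jacfunc = "pathway_jac", jactype = "fullusr",
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), 1]
    stop("ODE integration failed (step-size collapse near t = ",
         signif(last, 6), " min)")
  }
  out
}

#' Pre-equilibrate the network to its unstimulated steady state
#'
#' Simulates the unperturbed system (all doses zero) to a long horizon and
#' applies one damped Newton refinement using the analytic state Jacobian
#' (pseudo-inverse step, respecting conserved moieties). The result is the
#' initial condition for all stimulation experiments.
#'
#' @param net \code{pathway_network}.
#' @param params named resolved parameter vector (knockdowns already applied).
#' @param sens_params character vector of parameters whose steady-state
#'   sensitivities are computed (from the linearized steady-state system with
#'   conserved-moiety totals pinned; empty for none).
#' @param t_end pre-equilibration horizon in minutes.
#' @param tol acceptance threshold on \code{max |dx/dt|}.
#' @param rtol,atol integrator tolerances.
#' @return list with \code{state} (named vector), \code{sens} (species x
#'   parameter matrix or NULL) and \code{residual} (max |dx/dt|).
#' @export
preequilibrate <- function(net, params, sens_params = character(),
                           t_end = 1e6, tol = 1e-8, rtol = 1e-8,
                           atol = 1e-10) {
  x0 <- initial_state(net, params)
  parms <- pack_parms(net, params, c(L = 0, C = 0, I = 0), character())
  out <- ode_integrate(x0, c(0, t_end), parms, rtol = rtol, atol = atol)
  n <- nrow(net$species)
  x <- stats::setNames(out[nrow(out), -1][seq_len(n)], net$species$id)

  # one damped Newton refinement (pseudo-inverse; the Jacobian is singular
  # along conserved-moiety directions)
  f <- eval_rhs(net, x, params)
  if (max(abs(f)) > tol / 10) {
    A <- eval_jacobian(net, x, params)
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-10
    delta <- -sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% f) / sv$d[pos])
    alpha <- 1
    repeat {
      xn <- x + alpha * drop(delta)
      if (all(xn >= 0) && max(abs(eval_rhs(net, xn, params))) <= max(abs(f)))
        break
      alpha <- alpha / 2
      if (alpha < 1e-4) { xn <- x; break }
    }
    x <- xn
    f <- eval_rhs(net, x, params)
  }
  res <- max(abs(f))
  if (res > tol)
    stop("pre-equilibration did not reach steady state: max |dx/dt| = ",
         signif(res, 4))
  sens <- NULL
  if (length(sens_params)) {
    # steady-state sensitivities from the linearized system:
    #   A dx0/dtheta = -S dv/dtheta  on the reachable subspace,
    # with conserved-moiety totals pinned to their (parametric) values;
    # minimum-norm solve handles decoupled species (e.g. unbound inhibitor
    # complexes at zero dose)
    A <- eval_jacobian(net, x, params)
    B <- eval_dvdtheta(net, x, params, sens_params)
    nm <- length(net$moieties)
    C <- matrix(0, nm, n, dimnames = list(NULL, net$species$id))
    D <- matrix(0, nm, length(sens_params),
                dimnames = list(NULL, sens_params))
    for (i in seq_len(nm)) {
      mo <- net$moieties[[i]]
      C[i, names(mo$species)] <- mo$species
      if (mo$total_param %in% sens_params) D[i, mo$total_param] <- 1
    }
    M <- rbind(A, C)
    rhs <- rbind(-B, D)
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-12
    sens <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% rhs) / sv$d[pos])
    dimnames(sens) <- list(net$species$id, sens_params)
  }
  list(state = x, sens = sens, residual = res)
}

#' Simulate a treatment condition
#'
#' Pre-equilibrates (after applying any knockdown to the synthesis rates) and
#' then integrates the stimulated system with the condition's doses applied as
#' constant inputs from t = 0. Optionally carries forward sensitivities with
#' respect to selected parameters.
#'
#' @param net \code{pathway_network}.
#' @param params named resolved parameter vector.
#' @param condition \code{pathway_condition}.
#' @param timepoints override of the condition's timepoints.
#' @param sens_params parameters for forward sensitivities.
#' @param preeq optional precomputed result of \code{preequilibrate} (to share
#'   one pre-equilibration across doses of the same context).
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{pathway_trajectory}: \code{time},
#'   \code{states} (time x species), \code{sens} (time x species x parameter
#'   array or NULL), \code{condition}.
#' @export
simulate_condition <- function(net, params, condition,
                               timepoints = condition$timepoints,
                               sens_params = character(), preeq = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(condition, "pathway_condition"))
  if (!is.null(condition$knockdown))
    for (tg in names(condition$knockdown))
      params <- apply_knockdown(params, tg, condition$knockdown[[tg]])
  if (is.null(preeq))
    preeq <- preequilibrate(net, params, sens_params, rtol = rtol,
                            atol = atol)
  n <- nrow(net$species)
  y0 <- preeq$state
  if (length(sens_params)) y0 <- c(y0, as.numeric(preeq$sens))
  inputs <- dose_inputs(condition$ligand_dose, condition$cetuximab_dose,
                        condition$inhibitor_dose)
  parms <- pack_parms(net, params, inputs, sens_params)
  tms <- sort(unique(c(0, timepoints)))
  if (length(tms) == 1L) {
    yout <- matrix(y0, 1, length(y0))
  } else {
    out <- ode_integrate(y0, tms, parms, rtol = rtol, atol = atol)
    yout <- out[, -1, drop = FALSE]
  }
  keep <- match(timepoints, tms)
  states <- yout[keep, seq_len(n), drop = FALSE]
  dimnames(states) <- list(NULL, net$species$id)
  sens <- NULL
  if (length(sens_params)) {
    sens <- array(yout[keep, -seq_len(n)],
                  dim = c(length(keep), n, length(sens_params)),
                  dimnames = list(NULL, net$species$id, sens_params))
  }
  structure(list(time = timepoints, states = states, sens = sens,
                 condition = condition),
            class = "pathway_trajectory")
}
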