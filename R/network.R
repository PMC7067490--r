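#' Structural variant configuration for the signaling network
#'
#' Defines which structural features of the EGFR/RAS-MAPK/PI3K-AKT network are
#' present: the constitutively active mutant MET receptor (MMET), the
#' gain-of-function mutant PI3K (receptor-independent activation), the identity
#' of the stimulating ligand (EGF or the lower-affinity AREG), an inert
#' MET-inhibitor binding reaction, and an optional negative feedback from pERK
#' to active RAS.
#'
#' @param cell_line optional preset: \code{"MKN1"} (mutant PI3K, no mutant MET)
#'   or \code{"Hs746T"} (mutant MET, wild-type PI3K). Explicit flags override
#'   the preset.
#' @param has_mutant_met mutant MET receptor present (constitutively active).
#' @param has_mutant_pi3k mutant PI3K present (receptor-independent activation
#'   term).
#' @param ligand \code{"EGF"} or \code{"AREG"}. AREG differs only by a reduced
#'   EGFR association constant (see \code{areg_affinity_ratio}).
#' @param inhibitor_enabled MET inhibitor binding reactions present (requires
#'   mutant MET).
#' @param feedback_erk_to_ras negative feedback pERK -| RAS present.
#' @param areg_affinity_ratio fold-reduction of the ligand association constant
#'   for AREG relative to EGF (default 50).
#' @return an object of class \code{pathway_variant}.
#' @export
pathway_variant <- function(cell_line = NULL,
                            has_mutant_met = FALSE,
                            has_mutant_pi3k = FALSE,
                            ligand = c("EGF", "AREG"),
                            inhibitor_enabled = FALSE,
                            feedback_erk_to_ras = FALSE,
                            areg_affinity_ratio = 50) {
  ligand <- match.arg(ligand)
  if (!is.null(cell_line)) {
    cell_line <- match.arg(cell_line, c("MKN1", "Hs746T"))
    if (missing(has_mutant_met)) has_mutant_met <- (cell_line == "Hs746T")
    if (missing(has_mutant_pi3k)) has_mutant_pi3k <- (cell_line == "MKN1")
  }
  if (inhibitor_enabled && !has_mutant_met)
    stop("inhibitor_enabled requires has_mutant_met: the inhibitor binds MMET")
  if (!is.numeric(areg_affinity_ratio) || areg_affinity_ratio <= 0)
    stop("areg_affinity_ratio must be > 0")
  structure(list(
    cell_line = cell_line,
    has_mutant_met = isTRUE(has_mutant_met),
    has_mutant_pi3k = isTRUE(has_mutant_pi3k),
    ligand = ligand,
    inhibitor_enabled = isTRUE(inhibitor_enabled),
    feedback_erk_to_ras = isTRUE(feedback_erk_to_ras),
    areg_affinity_ratio = areg_affinity_ratio
  ), class = "pathway_variant")
}

#' Build the signaling reaction network for a structural variant
#'
#' Constructs the mass-action reaction network of EGFR turnover (synthesis,
#' degradation, ligand and cetuximab binding, dimerization/autophosphorylation,
#' internalization, degradation, recycling), the lumped RAS-MAPK and PI3K-AKT
#' cascades, and — depending on the variant — constitutively active mutant MET,
#' the mutant-PI3K activation term, inert MET-inhibitor binding, and pERK -| RAS
#' feedback. Ligand, cetuximab and inhibitor are treated as constant inputs
#' (no depletion).
#'
#' Catalytic activations are realized as elementary mass-action columns, so the
#' summed activation of RAS (by membrane and internalized phospho-receptor, and
#' by pMMET) appears as separate columns sharing a rate constant. Membrane-bound
#' and internalized phospho-EGFR catalyze with equal weight.
#'
#' @param variant a \code{pathway_variant}.
#' @return an object of class \code{pathway_network} with elements
#'   \code{species} (data.frame id/role), \code{reactions} (data.frame with
#'   rate-parameter, up to two reactant species, constant input modifier),
#'   \code{S} (stoichiometric matrix, species x reactions),
#'   \code{moieties} (conserved totals), \code{egfr_units} (receptor-unit
#'   multiplicities for the EGFR mass balance) and \code{variant}.
#' @export
build_network <- function(variant = pathway_variant()) {
  stopifnot(inherits(variant, "pathway_variant"))
  sp <- data.frame(
    id = c("R", "LR", "CR", "pD", "pDi",
           "RASi", "RASa", "ERK", "pERK",
           "PI3Ki", "PI3Ka", "AKT", "pAKT"),
    role = c("receptor", "ligand-receptor complex", "drug-receptor complex",
             "phospho-dimer (membrane)", "phospho-dimer (internalized)",
             "inactive RAS", "active RAS", "ERK", "pERK",
             "inactive PI3K", "active PI3K", "AKT", "pAKT"),
    stringsAsFactors = FALSE)
  if (variant$has_mutant_met) {
    sp <- rbind(sp, data.frame(
      id = c("MMET", "pMMET"),
      role = c("MMET", "pMMET"), stringsAsFactors = FALSE))
    if (variant$inhibitor_enabled)
      sp <- rbind(sp, data.frame(
        id = c("IM", "IpM"),
        role = c("inhibitor-MET complex", "inhibitor-MET complex"),
        stringsAsFactors = FALSE))
  }

  # reaction table: rate param, up to 2 state reactants (rate law factors),
  # constant-input modifier, and net stoichiometry as a named list
  rx <- list()
  add <- function(id, k, r1 = NA, r2 = NA, mod = NA, stoich) {
    rx[[length(rx) + 1L]] <<- list(id = id, k = k, r1 = r1, r2 = r2,
                                   mod = mod, stoich = stoich)
  }
  add("syn_R",     "k_synR",   stoich = c(R = 1))
  add("deg_R",     "k_degR",   "R",           stoich = c(R = -1))
  add("bind_L",    "k_onL",    "R", mod = "L", stoich = c(R = -1, LR = 1))
  add("unbind_L",  "k_offL",   "LR",          stoich = c(LR = -1, R = 1))
  add("bind_C",    "k_onC",    "R", mod = "C", stoich = c(R = -1, CR = 1))
  add("unbind_C",  "k_offC",   "CR",          stoich = c(CR = -1, R = 1))
  add("dimerize",  "k_dim",    "LR", "LR",    stoich = c(LR = -2, pD = 1))
  add("internalize", "k_int",  "pD",          stoich = c(pD = -1, pDi = 1))
  add("deg_pD",    "k_degpD",  "pDi",         stoich = c(pDi = -1))
  add("recycle",   "k_rec",    "pDi",         stoich = c(pDi = -1, R = 2))
  add("ras_act_pD",  "k_rasE", "RASi", "pD",  stoich = c(RASi = -1, RASa = 1))
  add("ras_act_pDi", "k_rasE", "RASi", "pDi", stoich = c(RASi = -1, RASa = 1))
  if (variant$has_mutant_met)
    add("ras_act_met", "k_rasM", "RASi", "pMMET",
        stoich = c(RASi = -1, RASa = 1))
  add("ras_deact", "k_rasOff", "RASa",        stoich = c(RASa = -1, RASi = 1))
  if (variant$feedback_erk_to_ras)
    add("ras_deact_fb", "k_fb", "RASa", "pERK",
        stoich = c(RASa = -1, RASi = 1))
  add("erk_act",   "k_erk",    "ERK", "RASa", stoich = c(ERK = -1, pERK = 1))
  add("erk_deact", "k_erkOff", "pERK",        stoich = c(pERK = -1, ERK = 1))
  add("pi3k_act_pD",  "k_pi3kE", "PI3Ki", "pD",
      stoich = c(PI3Ki = -1, PI3Ka = 1))
  add("pi3k_act_pDi", "k_pi3kE", "PI3Ki", "pDi",
      stoich = c(PI3Ki = -1, PI3Ka = 1))
  if (variant$has_mutant_met)
    add("pi3k_act_met", "k_pi3kM", "PI3Ki", "pMMET",
        stoich = c(PI3Ki = -1, PI3Ka = 1))
  if (variant$has_mutant_pi3k)
    add("pi3k_act_mut", "k_pi3kMut", "PI3Ki",
        stoich = c(PI3Ki = -1, PI3Ka = 1))
  add("pi3k_deact", "k_pi3kOff", "PI3Ka",    stoich = c(PI3Ka = -1, PI3Ki = 1))
  add("akt_act",   "k_akt",    "AKT", "PI3Ka", stoich = c(AKT = -1, pAKT = 1))
  add("akt_deact", "k_aktOff", "pAKT",        stoich = c(pAKT = -1, AKT = 1))
  if (variant$has_mutant_met) {
    add("syn_M",    "k_synM",                 stoich = c(MMET = 1))
    add("deg_M",    "k_degM",  "MMET",        stoich = c(MMET = -1))
    add("met_act",  "k_metOn", "MMET",        stoich = c(MMET = -1, pMMET = 1))
    add("met_deact", "k_metOff", "pMMET",     stoich = c(pMMET = -1, MMET = 1))
    if (variant$inhibitor_enabled) {
      add("inh_bind_M",  "k_onI", "MMET",  mod = "I",
          stoich = c(MMET = -1, IM = 1))
      add("inh_bind_pM", "k_onI", "pMMET", mod = "I",
          stoich = c(pMMET = -1, IpM = 1))
    }
  }

  reactions <- data.frame(
    id = vapply(rx, `[[`, "", "id"),
    rate_param = vapply(rx, `[[`, "", "k"),
    r1 = vapply(rx, function(z) as.character(z$r1), ""),
    r2 = vapply(rx, function(z) as.character(z$r2), ""),
    modifier = vapply(rx, function(z) as.character(z$mod), ""),
    stringsAsFactors = FALSE)

  S <- matrix(0L, nrow = nrow(sp), ncol = nrow(reactions),
              dimnames = list(sp$id, reactions$id))
  for (j in seq_along(rx))
    S[names(rx[[j]]$stoich), j] <- as.integer(rx[[j]]$stoich)

  moieties <- list(
    list(name = "RAS",  species = c(RASi = 1, RASa = 1), total_param = "RAS_tot"),
    list(name = "ERK",  species = c(ERK = 1, pERK = 1),  total_param = "ERK_tot"),
    list(name = "PI3K", species = c(PI3Ki = 1, PI3Ka = 1), total_param = "PI3K_tot"),
    list(name = "AKT",  species = c(AKT = 1, pAKT = 1),  total_param = "AKT_tot"))

  # receptor-unit multiplicity of each species in the EGFR mass balance
  egfr_units <- stats::setNames(numeric(nrow(sp)), sp$id)
  egfr_units[c("R", "LR", "CR")] <- 1
  egfr_units[c("pD", "pDi")] <- 2

  # AREG differs from EGF only by the ligand association constant
  ligand_assoc_scale <-
    if (variant$ligand == "AREG") 1 / variant$areg_affinity_ratio else 1

  structure(list(species = sp, reactions = reactions, S = S,
                 moieties = moieties, egfr_units = egfr_units,
                 ligand_assoc_scale = ligand_assoc_scale,
                 variant = variant),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  v <- x$variant
  cat("EGFR signaling network:", nrow(x$species), "species,",
      nrow(x$reactions), "reactions\n")
  cat("  variant: ligand =", v$ligand,
      "| mutant MET:", v$has_mutant_met,
      "| mutant PI3K:", v$has_mutant_pi3k,
      "| inhibitor:", v$inhibitor_enabled,
      "| ERK->RAS feedback:", v$feedback_erk_to_ras, "\n")
  invisible(x)
}

# Resolved per-reaction rate constants, folding the AREG affinity scale into
# the ligand association column.
network_rate_constants <- function(net, params) {
  k <- unname(params[net$reactions$rate_param])
  if (anyNA(k))
    stop("missing rate constants: ",
         paste(setdiff(net$reactions$rate_param, names(params)), collapse = ", "))
  k[net$reactions$id == "bind_L"] <-
    k[net$reactions$id == "bind_L"] * net$ligand_assoc_scale
  k
}

# Constant-input modifier values per reaction for a condition (inputs in nM /
# a.u.), 1 where no modifier applies.
network_modifiers <- function(net, inputs) {
  mod <- rep(1, nrow(net$reactions))
  m <- net$reactions$modifier
  mod[m == "L"] <- inputs[["L"]]
  mod[m == "C"] <- inputs[["C"]]
  mod[m == "I"] <- inputs[["I"]]
  mod
}

# Reference R implementation of the reaction fluxes v(x, theta) and their state
# Jacobian. Used for Newton refinement of steady states and as the independent
# oracle for the compiled right-hand side in tests.
eval_fluxes <- function(net, x, params, inputs = c(L = 0, C = 0, I = 0)) {
  k <- network_rate_constants(net, params)
  mod <- network_modifiers(net, inputs)
  r1 <- match(net$reactions$r1, net$species$id)
  r2 <- match(net$reactions$r2, net$species$id)
  f1 <- ifelse(is.na(r1), 1, x[r1])
  f2 <- ifelse(is.na(r2), 1, x[r2])
  k * mod * f1 * f2
}

eval_rhs <- function(net, x, params, inputs = c(L = 0, C = 0, I = 0)) {
  drop(net$S %*% eval_fluxes(net, x, params, inputs))
}

eval_dvdx <- function(net, x, params, inputs = c(L = 0, C = 0, I = 0)) {
  k <- network_rate_constants(net, params)
  mod <- network_modifiers(net, inputs)
  n <- nrow(net$species); nr <- nrow(net$reactions)
  r1 <- match(net$reactions$r1, net$species$id)
  r2 <- match(net$reactions$r2, net$species$id)
  dv <- matrix(0, nr, n, dimnames = list(net$reactions$id, net$species$id))
  for (j in seq_len(nr)) {
    if (!is.na(r1[j]))
      dv[j, r1[j]] <- dv[j, r1[j]] +
        k[j] * mod[j] * (if (is.na(r2[j])) 1 else x[r2[j]])
    if (!is.na(r2[j]))
      dv[j, r2[j]] <- dv[j, r2[j]] +
        k[j] * mod[j] * (if (is.na(r1[j])) 1 else x[r1[j]])
  }
  dv
}

# d(Sv)/dx: state Jacobian of the right-hand side
eval_jacobian <- function(net, x, params, inputs = c(L = 0, C = 0, I = 0)) {
  net$S %*% eval_dvdx(net, x, params, inputs)
}

# S dv/dtheta for selected rate parameters (zero columns for parameters that
# only enter through initial conditions)
eval_dvdtheta <- function(net, x, params, sens_params,
                          inputs = c(L = 0, C = 0, I = 0)) {
  mod <- network_modifiers(net, inputs)
  mod[net$reactions$id == "bind_L"] <-
    mod[net$reactions$id == "bind_L"] * net$ligand_assoc_scale
  r1 <- match(net$reactions$r1, net$species$id)
  r2 <- match(net$reactions$r2, net$species$id)
  base <- mod * ifelse(is.na(r1), 1, x[r1]) * ifelse(is.na(r2), 1, x[r2])
  B <- matrix(0, nrow(net$species), length(sens_params),
              dimnames = list(net$species$id, sens_params))
  for (s in sens_params) {
    j <- which(net$reactions$rate_param == s)
    if (length(j))
      B[, s] <- net$S[, j, drop = FALSE] %*% base[j]
  }
  B
}

#' Structural difference between two networks
#'
#' Compares species sets and reaction columns (reaction identity, rate
#' parameter, reactants, modifier and stoichiometry) of two networks.
#'
#' @param a,b \code{pathway_network} objects.
#' @return list with \code{species_only_a/b}, \code{reactions_only_a/b} and
#'   \code{n_differing_columns}.
#' @export
network_diff <- function(a, b) {
  key <- function(net) {
    paste(net$reactions$id, net$reactions$rate_param, net$reactions$r1,
          net$reactions$r2, net$reactions$modifier,
          apply(net$S, 2, paste, collapse = ","), sep = "|")
  }
  ka <- key(a); kb <- key(b)
  list(species_only_a = setdiff(a$species$id, b$species$id),
       species_only_b = setdiff(b$species$id, a$species$id),
       reactions_only_a = a$reactions$id[!(ka %in% kb)],
       reactions_only_b = b$reactions$id[!(kb %in% ka)],
       n_differing_columns = length(union(
         a$reactions$id[!(ka %in% kb)], b$reactions$id[!(kb %in% ka)])))
}
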