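#' Default kinetic and abundance parameters
#'
#' Returns the package's default parameterization of the signaling model in
#' the MKN1 (base) context. Units: concentrations in nM-equivalent arbitrary
#' units, time in minutes; first-order rates in 1/min, second-order rates in
#' 1/(nM min), synthesis rates in nM/min. Each parameter carries a class used
#' by the fold-change machinery and the module-specificity hypotheses:
#' \describe{
#'   \item{direct}{elementary binding/dimerization constants, conserved across
#'     cell lines (cell-line fold-changes fixed to zero)}
#'   \item{ras_mapk}{lumped RAS-MAPK cascade rates (module i)}
#'   \item{pi3k_akt}{lumped PI3K-AKT cascade rates (module ii)}
#'   \item{egfr_turnover}{EGFR internalization/degradation/recycling rates
#'     (module iii)}
#'   \item{met}{mutant-MET cycle rates (present in the Hs746T variant only)}
#'   \item{expression}{synthesis rates and moiety totals; the only class whose
#'     fold-changes may differ between culture media}
#' }
#'
#' @return data.frame with columns \code{name}, \code{value}, \code{class},
#'   \code{lower}, \code{upper} (natural-scale bounds used for estimation).
#' @export
default_parameters <- function() {
  p <- list(
    #        value   class
    k_synR    = c(0.025, "expression"),
    k_degR    = c(0.01,  "egfr_turnover"),
    k_onL     = c(0.1,   "direct"),
    k_offL    = c(0.1,   "direct"),
    k_onC     = c(0.05,  "direct"),
    k_offC    = c(0.01,  "direct"),
    k_dim     = c(1.0,   "direct"),
    k_int     = c(0.1,   "egfr_turnover"),
    k_degpD   = c(0.05,  "egfr_turnover"),
    k_rec     = c(0.05,  "egfr_turnover"),
    k_rasE    = c(1.0,   "ras_mapk"),
    k_rasM    = c(0.5,   "ras_mapk"),
    k_rasOff  = c(1.0,   "ras_mapk"),
    k_fb      = c(1.0,   "ras_mapk"),
    k_erk     = c(1.0,   "ras_mapk"),
    k_erkOff  = c(0.3,   "ras_mapk"),
    k_pi3kE   = c(0.05,  "pi3k_akt"),
    k_pi3kM   = c(0.5,   "pi3k_akt"),
    k_pi3kMut = c(1.0,   "pi3k_akt"),
    k_pi3kOff = c(1.0,   "pi3k_akt"),
    k_akt     = c(2.0,   "pi3k_akt"),
    k_aktOff  = c(0.5,   "pi3k_akt"),
    k_synM    = c(0.02,  "expression"),
    k_degM    = c(0.01,  "met"),
    k_metOn   = c(1.0,   "met"),
    k_metOff  = c(1.0,   "met"),
    k_onI     = c(1.0,   "direct"),
    RAS_tot   = c(1.0,   "expression"),
    ERK_tot   = c(1.0,   "expression"),
    PI3K_tot  = c(1.0,   "expression"),
    AKT_tot   = c(1.0,   "expression"))
  value <- vapply(p, function(z) as.numeric(z[1]), 0)
  data.frame(name = names(p), value = unname(value),
             class = vapply(p, `[`, "", 2),
             lower = unname(value) * 10^-2.5,
             upper = unname(value) * 10^2.5,
             stringsAsFactors = FALSE, row.names = NULL)
}

param_values <- function(ptab) stats::setNames(ptab$value, ptab$name)

param_class <- function(ptab, names) {
  ptab$class[match(names, ptab$name)]
}

#' Fold-change specification across cell-line and medium contexts
#'
#' Log-fold changes xi act multiplicatively on base (MKN1, rich-medium)
#' parameters: \code{theta_resolved = theta_base * exp(xi_cell_line) *
#' exp(xi_medium)}. Cell-line fold-changes are fixed to zero for all
#' \code{direct}-class parameters (elementary interactions conserved between
#' cell lines); medium fold-changes are allowed only for \code{expression}-class
#' parameters.
#'
#' @param cell_line named numeric vector (or empty) of xi values for the
#'   non-reference cell line (Hs746T), named by parameter.
#' @param medium named numeric vector of xi values for the non-reference
#'   medium (HM, starvation), named by parameter.
#' @param params parameter table (for class validation), default
#'   \code{default_parameters()}.
#' @return object of class \code{fold_change_spec}.
#' @export
fold_change_spec <- function(cell_line = numeric(), medium = numeric(),
                             params = default_parameters()) {
  cl <- param_class(params, names(cell_line))
  if (any(!is.na(cl) & cl == "direct" & cell_line != 0))
    stop("cell-line fold-changes are fixed to zero for direct-interaction ",
         "parameters: ", paste(names(cell_line)[cl == "direct"], collapse = ", "))
  md <- param_class(params, names(medium))
  if (any(!is.na(md) & md != "expression" & medium != 0))
    stop("medium fold-changes are allowed only for expression parameters: ",
         paste(names(medium)[md != "expression"], collapse = ", "))
  structure(list(cell_line = cell_line, medium = medium),
            class = "fold_change_spec")
}

#' Resolve parameters for a (cell line, medium) context
#'
#' Applies the multiplicative fold-change parameterization. MKN1 and rich
#' medium (FM) are the reference context (all xi = 0 by construction);
#' Hs746T and starvation medium (HM) apply \code{exp(xi)} factors.
#'
#' @param base named numeric vector of base parameters, or the data.frame from
#'   \code{default_parameters()}.
#' @param fc a \code{fold_change_spec}.
#' @param cell_line \code{"MKN1"} or \code{"Hs746T"}.
#' @param medium \code{"FM"} (rich) or \code{"HM"} (starvation).
#' @return named numeric vector of resolved parameters.
#' @export
resolve_parameters <- function(base, fc = fold_change_spec(),
                               cell_line = c("MKN1", "Hs746T"),
                               medium = c("FM", "HM")) {
  cell_line <- match.arg(cell_line)
  medium <- match.arg(medium)
  theta <- if (is.data.frame(base)) param_values(base) else base
  if (cell_line == "Hs746T" && length(fc$cell_line)) {
    idx <- names(fc$cell_line)
    theta[idx] <- theta[idx] * exp(fc$cell_line)
  }
  if (medium == "HM" && length(fc$medium)) {
    idx <- names(fc$medium)
    theta[idx] <- theta[idx] * exp(fc$medium)
  }
  theta
}

#' Scale synthesis rates to emulate an siRNA knockdown
#'
#' Knockdowns are modeled by scaling the synthesis rate of the targeted
#' receptor by the retained fraction (the measured residual expression after
#' siRNA treatment); pre-equilibration must be re-run afterwards so the
#' knocked-down steady state is the new initial condition.
#'
#' @param params named numeric parameter vector.
#' @param target \code{"k_synR"} (EGFR) or \code{"k_synM"} (MET).
#' @param retained_fraction fraction of expression retained, in [0, 1].
#' @return modified parameter vector.
#' @export
apply_knockdown <- function(params, target, retained_fraction) {
  if (!target %in% c("k_synR", "k_synM"))
    stop("knockdown target must be a synthesis parameter (k_synR or k_synM), got: ",
         target)
  if (!is.numeric(retained_fraction) || retained_fraction < 0 ||
      retained_fraction > 1)
    stop("retained_fraction must be in [0, 1]")
  params[target] <- params[target] * retained_fraction
  params
}

#' Replace mutant PI3K by wild type
#'
#' Sets the receptor-independent (constitutive) PI3K activation rate of the
#' p.E545K mutant to zero, leaving only receptor-driven PI3K activation. With
#' the mutant term removed, pAKT regains sensitivity to cetuximab.
#'
#' @param params named numeric parameter vector.
#' @return modified parameter vector (idempotent).
#' @export
swap_pi3k_wildtype <- function(params) {
  if ("k_pi3kMut" %in% names(params)) params[["k_pi3kMut"]] <- 0
  params
}

# parameters eligible for cell-line fold-changes within each candidate module,
# restricted to rates present in both cell-line variants
module_xi_parameters <- function(module) {
  switch(module,
         ras_mapk      = c("k_rasE", "k_rasOff", "k_erk", "k_erkOff"),
         pi3k_akt      = c("k_pi3kE", "k_pi3kOff", "k_akt", "k_aktOff"),
         egfr_turnover = c("k_degR", "k_int", "k_degpD", "k_rec"),
         stop("unknown module: ", module))
}
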