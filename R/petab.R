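#' Write a dataset as PEtab-style TSV tables
#'
#' Emits tab-separated, UTF-8 tables with mandatory header rows:
#' \code{measurements.tsv} (observableId, simulationConditionId, time,
#' measurement, replicateId, datasetId, noiseParameters),
#' \code{conditions.tsv}, \code{observables.tsv} and \code{parameters.tsv}
#' (log10 scale, bounds, nominal values).
#'
#' @param dataset \code{pathway_dataset}.
#' @param dir output directory (created if missing).
#' @param params parameter table for \code{parameters.tsv}.
#' @return invisibly, the paths written.
#' @export
write_petab_tables <- function(dataset, dir,
                               params = default_parameters()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- dataset$measurements
  sig <- sigma_for_records(m, dataset$sigma)
  meas <- data.frame(observableId = m$observable_id,
                     simulationConditionId = m$condition_id,
                     time = m$time, measurement = m$value,
                     replicateId = m$replicate,
                     datasetId = m$experiment_id,
                     noiseParameters = sig,
                     stringsAsFactors = FALSE)
  conds <- dataset$conditions
  names(conds)[names(conds) == "condition_id"] <- "conditionId"
  formulas <- c(obs_EGFR = "R + LR + CR + 2*pD + 2*pDi",
                obs_pEGFR = "2*pD + 2*pDi", obs_pERK = "pERK",
                obs_pAKT = "pAKT", obs_MET = "MMET + pMMET + IM + IpM",
                obs_pMMET = "pMMET")
  oids <- unique(m$observable_id)
  obs <- data.frame(observableId = oids,
                    observableFormula = paste0(
                      "scaling_", oids, " * (", formulas[oids], ")"),
                    noiseFormula = paste0("sigma_", oids),
                    stringsAsFactors = FALSE)
  par <- data.frame(parameterId = params$name, parameterScale = "log10",
                    lowerBound = params$lower, upperBound = params$upper,
                    nominalValue = params$value, estimate = 1L,
                    stringsAsFactors = FALSE)
  paths <- file.path(dir, c("measurements.tsv", "conditions.tsv",
                            "observables.tsv", "parameters.tsv"))
  wr <- function(x, p) utils::write.table(
    x, p, sep = "\t", quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  wr(meas, paths[1]); wr(conds, paths[2]); wr(obs, paths[3]); wr(par, paths[4])
  invisible(paths)
}

#' Read PEtab-style TSV tables back into a dataset
#'
#' @param dir directory containing \code{measurements.tsv} and
#'   \code{conditions.tsv} as written by \code{\link{write_petab_tables}}.
#' @return \code{pathway_dataset}.
#' @export
read_petab_tables <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), sep = "\t",
                                      stringsAsFactors = FALSE)
  meas <- rd("measurements.tsv")
  conds <- rd("conditions.tsv")
  names(conds)[names(conds) == "conditionId"] <- "condition_id"
  if ("kd_target" %in% names(conds))
    conds$kd_target[conds$kd_target %in% c("", "NA")] <- NA_character_
  m <- data.frame(condition_id = meas$simulationConditionId,
                  observable_id = meas$observableId,
                  time = meas$time, replicate = meas$replicateId,
                  experiment_id = meas$datasetId,
                  value = meas$measurement, stringsAsFactors = FALSE)
  sig <- NULL
  if ("noiseParameters" %in% names(meas)) {
    key <- !duplicated(paste(meas$observableId, meas$datasetId))
    sig <- data.frame(observable_id = meas$observableId[key],
                      experiment_id = meas$datasetId[key],
                      sigma = meas$noiseParameters[key],
                      stringsAsFactors = FALSE)
  }
  pathway_dataset(m, conds, sigma = sig)
}

#' Export a network variant as SBML Level 3
#'
#' Writes a minimal SBML Level 3 Version 1 document (one compartment,
#' species, parameters, reactions with reactants/products/modifiers). Intended
#' for structural interchange; kinetic laws are annotated as mass action via
#' reaction notes. Requires the \pkg{xml2} package.
#'
#' @param net \code{pathway_network}.
#' @param file output path.
#' @param params optional named parameter vector for parameter values.
#' @return invisibly, the file path.
#' @export
export_sbml <- function(net, file, params = NULL) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the xml2 package")
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "egfr_signaling")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", constant = "true",
                      size = "1")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$species)))
    xml2::xml_add_child(ls, "species", id = net$species$id[i],
                        compartment = "cell", constant = "false",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false")
  lp <- xml2::xml_add_child(model, "listOfParameters")
  for (pn in unique(net$reactions$rate_param))
    xml2::xml_add_child(lp, "parameter", id = pn, constant = "true",
                        value = as.character(
                          if (!is.null(params) && pn %in% names(params))
                            params[[pn]] else 1))
  lr <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_len(nrow(net$reactions))) {
    rxn <- xml2::xml_add_child(lr, "reaction", id = net$reactions$id[j],
                               reversible = "false", fast = "false")
    sj <- net$S[, j]
    if (any(sj < 0)) {
      lre <- xml2::xml_add_child(rxn, "listOfReactants")
      for (s in names(sj)[sj < 0])
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = as.character(-sj[s]),
                            constant = "true")
    }
    if (any(sj > 0)) {
      lpr <- xml2::xml_add_child(rxn, "listOfProducts")
      for (s in names(sj)[sj > 0])
        xml2::xml_add_child(lpr, "speciesReference", species = s,
                            stoichiometry = as.character(sj[s]),
                            constant = "true")
    }
    # catalytic reactants that are not consumed appear as modifiers
    rr <- c(net$reactions$r1[j], net$reactions$r2[j])
    mods <- setdiff(rr[!is.na(rr) & rr != "NA"], names(sj)[sj != 0])
    if (length(mods)) {
      lm <- xml2::xml_add_child(rxn, "listOfModifiers")
      for (s in unique(mods))
        xml2::xml_add_child(lm, "modifierSpeciesReference", species = s)
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}
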