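#' Enumerate cell-line-specificity hypotheses
#'
#' Builds the model ensemble over all subsets of the candidate modules whose
#' parameters may differ between cell lines: (i) RAS-MAPK signaling,
#' (ii) PI3K-AKT signaling, (iii) EGFR turnover (internalization, degradation,
#' recycling). Labels follow binary order M1 (no module specific) through
#' M2^k (all specific); with the default three modules, M5 is the
#' turnover-only hypothesis.
#'
#' @param modules candidate module names (default the three above).
#' @return data.frame with columns \code{label}, one logical column per
#'   module, and a list-column \code{free_xi} of the implied free
#'   fold-change parameters.
#' @export
enumerate_hypotheses <- function(modules = c("ras_mapk", "pi3k_akt",
                                             "egfr_turnover")) {
  k <- length(modules)
  n <- 2^k
  flags <- matrix(FALSE, n, k, dimnames = list(NULL, modules))
  for (j in seq_len(k))
    flags[, j] <- bitwAnd(seq_len(n) - 1L, 2^(j - 1L)) > 0
  free_xi <- lapply(seq_len(n), function(i) {
    unlist(lapply(modules[flags[i, ]], module_xi_parameters),
           use.names = FALSE)
  })
  out <- data.frame(label = paste0("M", seq_len(n)), flags,
                    stringsAsFactors = FALSE)
  out$free_xi <- free_xi
  out
}

#' Akaike information criterion
#'
#' \code{AIC = 2k + 2 * negloglik} with negloglik the minimized negative
#' log-likelihood and k the number of estimated parameters. A difference of
#' 10 between models is considered substantial for model selection.
#'
#' @param negloglik minimized negative log-likelihood.
#' @param k number of free parameters (>= 0).
#' @return AIC value.
#' @export
aic <- function(negloglik, k) {
  stopifnot(k >= 0)
  2 * k + 2 * negloglik
}

#' Fit the specificity-hypothesis ensemble on a joint dataset
#'
#' Fits every hypothesis on the identical joint (both-cell-line) dataset.
#' All direct parameters are shared between cell lines; expression and
#' mutation differences (the EGFR-synthesis fold-change) are free in every
#' hypothesis; only the module fold-change sets vary.
#'
#' @param dataset joint \code{pathway_dataset} covering both cell lines.
#' @param hypotheses from \code{\link{enumerate_hypotheses}}.
#' @param free_kinetic shared kinetic parameters estimated in every model.
#' @param always_free_xi fold-changes free in every hypothesis (default the
#'   EGFR expression difference, \code{k_synR}).
#' @param n_starts multi-start count per model (default 20).
#' @param seed RNG seed; each model uses a deterministic offset.
#' @param profile_scalings solve scaling factors analytically per evaluation
#'   (recommended for ensemble runs; the scalings still count as estimated
#'   parameters in k).
#' @param control optimizer control passed to \code{\link{fit_pathway}}.
#' @param ... further arguments to \code{\link{pathway_problem}} (for example
#'   integrator tolerances).
#' @return list of \code{pathway_fit} objects named by hypothesis label.
#' @export
fit_hypotheses <- function(dataset, hypotheses = enumerate_hypotheses(),
                           free_kinetic = character(),
                           always_free_xi = "k_synR",
                           n_starts = 20, seed = 1,
                           profile_scalings = TRUE,
                           control = list(), ...) {
  fits <- list()
  for (i in seq_len(nrow(hypotheses))) {
    lab <- hypotheses$label[i]
    fx <- unique(c(always_free_xi, hypotheses$free_xi[[i]]))
    prob <- pathway_problem(dataset,
                            free_kinetic = free_kinetic,
                            free_xi_cell = fx,
                            profile_scalings = profile_scalings, ...)
    fits[[lab]] <- fit_pathway(prob, n_starts = n_starts,
                               seed = seed + 97L * i, control = control)
  }
  fits
}

#' Rank an ensemble of fitted models by AIC
#'
#' @param fits named list of \code{pathway_fit} objects (one per hypothesis),
#'   or a named list of \code{list(nll =, k =)} entries.
#' @param labels expected hypothesis labels; an entry missing from
#'   \code{fits} raises an error naming it.
#' @param delta_substantial AIC difference regarded as substantial support
#'   loss (default 10).
#' @return object of class \code{pathway_selection}: data.frame
#'   \code{model}, \code{k}, \code{nll}, \code{AIC}, \code{dAIC},
#'   \code{substantial_support}, sorted by AIC (ties: fewer parameters, then
#'   label order).
#' @export
rank_models <- function(fits, labels = names(fits), delta_substantial = 10) {
  miss <- setdiff(labels, names(fits))
  if (length(miss))
    stop("missing hypothesis fit(s): ", paste(miss, collapse = ", "))
  rows <- lapply(labels, function(lab) {
    f <- fits[[lab]]
    if (is.null(f)) stop("missing hypothesis fit(s): ", lab)
    if (inherits(f, "pathway_fit")) {
      k <- nrow(f$problem$free)
      if (f$problem$profile_scalings)
        k <- k + length(f$problem$scaling_ids)
      nll <- f$best_nll
    } else {
      k <- f$k; nll <- f$nll
    }
    data.frame(model = lab, k = k, nll = nll, AIC = aic(nll, k),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$AIC, tab$k, match(tab$model, labels))
  tab <- tab[ord, , drop = FALSE]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$substantial_support <- tab$dAIC < delta_substantial
  rownames(tab) <- NULL
  structure(list(table = tab, best = tab$model[1],
                 delta_substantial = delta_substantial),
            class = "pathway_selection")
}

#' @export
print.pathway_selection <- function(x, ...) {
  cat("AIC model selection (best:", x$best, ")\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' Screen per-parameter cell-line differences by one-way ANOVA
#'
#' Compares the log10 parameter vectors of the best multi-start fits of the
#' two cell lines, one parameter at a time, by one-way ANOVA (equivalent to a
#' two-sample F test). Only lumped/indirect parameters are tested; direct
#' binding parameters are reported as not tested. A Benjamini-Hochberg column
#' is reported for guidance but the headline flag uses the raw p at the given
#' threshold.
#'
#' @param top_a,top_b matrices (fits x parameters, log10 scale) with matching
#'   column names; by default the best 100 fits of each cell line.
#' @param classes named character vector of parameter classes (by column
#'   name); defaults to the package parameter table.
#' @param alpha significance threshold on the raw p-value (default 0.05).
#' @return data.frame \code{parameter}, \code{class}, \code{F}, \code{p},
#'   \code{p_BH}, \code{tested}, \code{significant}.
#' @export
compare_parameters_anova <- function(top_a, top_b, classes = NULL,
                                     alpha = 0.05) {
  top_a <- as.matrix(top_a); top_b <- as.matrix(top_b)
  if (nrow(top_a) < 2 || nrow(top_b) < 2)
    stop("each group needs at least 2 parameter vectors")
  pars <- intersect(colnames(top_a), colnames(top_b))
  if (!length(pars)) stop("no common parameters between groups")
  if (is.null(classes)) {
    ptab <- default_parameters()
    classes <- stats::setNames(ptab$class, ptab$name)
  }
  grp <- factor(rep(c("A", "B"), c(nrow(top_a), nrow(top_b))))
  out <- lapply(pars, function(pn) {
    cls <- if (pn %in% names(classes)) classes[[pn]] else NA_character_
    tested <- !is.na(cls) && cls != "direct"
    Fv <- NA_real_; pv <- NA_real_
    if (tested) {
      v <- c(top_a[, pn], top_b[, pn])
      ssw <- sum(tapply(v, grp, function(z) sum((z - mean(z))^2)))
      ssb <- sum(tapply(v, grp, length) *
                   (tapply(v, grp, mean) - mean(v))^2)
      if (ssb + ssw < 1e-300) {
        Fv <- 0; pv <- 1            # identical groups
      } else if (ssw < 1e-300) {
        Fv <- Inf; pv <- 0          # degenerate separation
      } else {
        a <- stats::anova(stats::lm(v ~ grp))
        Fv <- a$`F value`[1]; pv <- a$`Pr(>F)`[1]
      }
    }
    data.frame(parameter = pn, class = cls, F = Fv, p = pv, tested = tested,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  tab$p_BH <- NA_real_
  tab$p_BH[tab$tested] <- stats::p.adjust(tab$p[tab$tested], method = "BH")
  tab$significant <- tab$tested & !is.na(tab$p) & tab$p < alpha
  tab
}
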