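#' Fisher information matrix at the maximum-likelihood estimate
#'
#' Gauss-Newton approximation \code{FIM = t(J) J} from the sensitivity-based
#' Jacobian of the weighted residuals at the fitted optimum. The headline
#' spectrum is restricted to the dynamical parameters (kinetic rates,
#' abundances and fold-changes); scaling factors are excluded because they do
#' not shape the dynamical response. Rank deficiency is a finding, not an
#' error.
#'
#' @param x a \code{pathway_fit}, or a residual Jacobian matrix.
#' @param dynamical_only restrict to kinetic/fold-change parameters (default
#'   TRUE; ignored when \code{x} is a matrix).
#' @return object of class \code{pathway_fim}: \code{matrix},
#'   \code{eigenvalues} (sorted descending), \code{normalized}
#'   (lambda / lambda_max), \code{n_above_floor} and \code{sloppy}.
#' @export
fim <- function(x, dynamical_only = TRUE) {
  if (inherits(x, "pathway_fit")) {
    ev <- problem_eval(x$problem, x$best_par, want_jac = TRUE)
    J <- ev$jacobian[seq_len(nrow(x$problem$meas)), , drop = FALSE]
    if (dynamical_only) {
      keep <- x$problem$free$kind %in% c("kinetic", "xi_cell", "xi_medium")
      J <- J[, keep, drop = FALSE]
    }
  } else {
    J <- as.matrix(x)
  }
  M <- crossprod(J)
  lam <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  floor_val <- max(lam) * 1e-12
  res <- structure(list(matrix = M, eigenvalues = lam,
                        normalized = lam / max(lam),
                        floor = floor_val,
                        n_above_floor = sum(lam > floor_val)),
                   class = "pathway_fim")
  res$sloppy <- if (length(lam) >= 2) sloppiness(res)$sloppy else NA
  res
}

#' Sloppiness of a FIM eigenvalue spectrum
#'
#' A spectrum is sloppy if the largest and smallest eigenvalues differ by more
#' than six orders of magnitude (strict inequality). Eigenvalues below the
#' numerical-zero floor (\code{lambda_max * 1e-12}) are reported separately
#' and excluded from the span.
#'
#' @param x \code{pathway_fim} or a numeric vector of eigenvalues.
#' @return list \code{sloppy}, \code{span} (lambda_max / lambda_min over
#'   above-floor eigenvalues), \code{n_numerical_zero}.
#' @export
sloppiness <- function(x) {
  lam <- if (inherits(x, "pathway_fim")) x$eigenvalues else
    sort(as.numeric(x), decreasing = TRUE)
  if (length(lam) < 2) stop("need at least 2 eigenvalues")
  floor_val <- max(lam) * 1e-12
  keep <- lam > floor_val
  span <- max(lam) / min(lam[keep])
  list(sloppy = span > 1e6, span = span,
       n_numerical_zero = sum(!keep))
}

# re-optimize all free parameters except fix_idx, with the fixed one set to
# fix_val; warm-started from par_init
reoptimize_fixed <- function(problem, par_init, fix_idx, fix_val,
                             control = list()) {
  ctl <- utils::modifyList(list(maxiter = 100, ftol = 1e-12, ptol = 1e-10),
                           control)
  nmeas <- nrow(problem$meas)
  keep <- setdiff(seq_len(nrow(problem$free)), fix_idx)
  embed <- function(p) {
    full <- numeric(nrow(problem$free))
    full[keep] <- p; full[fix_idx] <- fix_val
    full
  }
  if (!length(keep)) {
    r <- problem_eval(problem, embed(numeric(0)), FALSE)$residuals
    return(list(par = embed(numeric(0)),
                nll = 0.5 * sum(r[seq_len(nmeas)]^2) + problem$const))
  }
  fit <- suppressWarnings(minpack.lm::nls.lm(
    par = par_init[keep],
    fn = function(p) problem_eval(problem, embed(p), FALSE)$residuals,
    jac = function(p)
      problem_eval(problem, embed(p), TRUE)$jacobian[, keep, drop = FALSE],
    lower = problem$free$lower[keep], upper = problem$free$upper[keep],
    control = minpack.lm::nls.lm.control(maxiter = ctl$maxiter,
                                         ftol = ctl$ftol, ptol = ctl$ptol)))
  r <- fit$fvec
  list(par = embed(fit$par),
       nll = 0.5 * sum(r[seq_len(nmeas)]^2) + problem$const)
}

#' Profile likelihood of one parameter
#'
#' Walks the parameter away from the optimum in both directions with adaptive
#' steps (targeting a negative log-likelihood increase of about
#' \code{target_dnll} per step), re-optimizing all remaining free parameters
#' at each grid point, until the 99\% threshold is exceeded or a bound is
#' reached. Confidence intervals at each level follow from the
#' \code{qchisq(level, 1) / 2} offset; a parameter is practically
#' non-identifiable if its 90\% interval is unbounded within the parameter
#' bounds.
#'
#' @param fit \code{pathway_fit}.
#' @param param free-parameter id (row of \code{fit$problem$free}); scaling
#'   factors are not profiled.
#' @param levels confidence levels (default 0.90, 0.95, 0.99).
#' @param target_dnll step-size target on the objective increase.
#' @param min_step,max_step step bounds in the parameter's scaled units.
#' @param max_steps cap per direction.
#' @param control re-optimizer control.
#' @return object of class \code{pathway_profile}.
#' @export
profile_likelihood <- function(fit, param, levels = c(0.90, 0.95, 0.99),
                               target_dnll = 0.1, min_step = 1e-3,
                               max_step = 0.5, max_steps = 60,
                               control = list()) {
  problem <- fit$problem
  j <- match(param, problem$free$pid)
  if (is.na(j)) stop("unknown free parameter: ", param)
  if (problem$free$kind[j] == "scaling")
    stop("profiles are computed only for dynamical parameters, not scalings")
  thresh99 <- stats::qchisq(max(c(levels, 0.99)), 1) / 2
  v0 <- fit$best_par[j]
  lo <- problem$free$lower[j]; up <- problem$free$upper[j]

  walk <- function(dir) {
    grid <- list()
    v <- v0; par <- fit$best_par; nll_prev <- fit$best_nll
    h <- min(max(min_step, 0.05), max_step)
    for (i in seq_len(max_steps)) {
      v <- v + dir * h
      at_bound <- FALSE
      if (v <= lo) { v <- lo; at_bound <- TRUE }
      if (v >= up) { v <- up; at_bound <- TRUE }
      ok <- TRUE
      nll <- NA_real_
      res <- tryCatch(reoptimize_fixed(problem, par, j, v, control),
                      error = function(e) NULL)
      if (is.null(res)) {
        ok <- FALSE
      } else {
        nll <- res$nll; par <- res$par
      }
      grid[[i]] <- data.frame(value = v, nll = nll, ok = ok)
      if (ok) {
        dnll <- abs(nll - nll_prev)
        h <- h * min(2, max(0.5, target_dnll / max(dnll, 1e-3)))
        h <- min(max(h, min_step), max_step)
        nll_prev <- nll
        if (nll - fit$best_nll > thresh99) break
      }
      if (at_bound) break
    }
    do.call(rbind, grid)
  }

  left <- walk(-1); right <- walk(+1)
  center <- data.frame(value = v0, nll = fit$best_nll, ok = TRUE)
  grid <- rbind(left[rev(seq_len(nrow(left))), , drop = FALSE], center, right)
  rownames(grid) <- NULL
  prof <- structure(list(param = param, grid = grid, best_value = v0,
                         best_nll = fit$best_nll,
                         bounds = c(lo, up), levels = levels),
                    class = "pathway_profile")
  prof$ci <- confidence_intervals(prof, levels)
  prof$identifiable <- with(prof$ci[prof$ci$level == min(levels), ],
                            lower_finite & upper_finite)
  prof
}

#' Profile-based confidence intervals
#'
#' Interpolates the profile's crossings of the \code{best_nll +
#' qchisq(level, 1) / 2} thresholds. A side whose profile never crosses the
#' threshold before the parameter bound yields an infinite endpoint (flagged
#' not finite).
#'
#' @param profile \code{pathway_profile} (or any list with \code{grid},
#'   \code{best_value}, \code{best_nll}).
#' @param levels confidence levels.
#' @return data.frame \code{level}, \code{lower}, \code{upper},
#'   \code{lower_finite}, \code{upper_finite}.
#' @export
confidence_intervals <- function(profile, levels = c(0.90, 0.95, 0.99)) {
  g <- profile$grid
  g <- g[g$ok & is.finite(g$nll), , drop = FALSE]
  v0 <- profile$best_value
  out <- lapply(levels, function(l) {
    thr <- profile$best_nll + stats::qchisq(l, 1) / 2
    cross <- function(side) {
      gg <- if (side < 0) g[g$value <= v0, , drop = FALSE] else
        g[g$value >= v0, , drop = FALSE]
      gg <- gg[order(if (side < 0) -gg$value else gg$value), , drop = FALSE]
      # walk outward from the optimum until the profile exceeds the threshold
      above <- which(gg$nll > thr)
      if (!length(above)) return(c(side * Inf, FALSE))
      i <- above[1]
      if (i == 1) return(c(gg$value[1], TRUE))
      x1 <- gg$value[i - 1]; x2 <- gg$value[i]
      y1 <- gg$nll[i - 1]; y2 <- gg$nll[i]
      c(x1 + (thr - y1) / (y2 - y1) * (x2 - x1), TRUE)
    }
    lo <- cross(-1); hi <- cross(+1)
    data.frame(level = l, lower = lo[1], upper = hi[1],
               lower_finite = as.logical(lo[2]),
               upper_finite = as.logical(hi[2]))
  })
  do.call(rbind, out)
}

#' @export
print.pathway_profile <- function(x, ...) {
  cat("Profile likelihood for", x$param,
      if (isTRUE(x$identifiable)) "(identifiable)" else
        "(practically non-identifiable)", "\n")
  print(x$ci, digits = 4)
  invisible(x)
}

#' @export
plot.pathway_profile <- function(x, ...) {
  g <- x$grid[x$grid$ok, ]
  plot(g$value, g$nll - x$best_nll, type = "l",
       xlab = x$param, ylab = expression(Delta ~ "-log L"),
       main = paste("Profile:", x$param), ...)
  for (l in x$levels)
    abline(h = stats::qchisq(l, 1) / 2, lty = 3)
  invisible(x)
}
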