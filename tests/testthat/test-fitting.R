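test_that("Latin hypercube starts stratify every dimension", {
  bounds <- cbind(c(-2, 0, 3), c(2, 1, 13))
  rownames(bounds) <- c("a", "b", "c")
  st <- sample_starts(bounds, 10, seed = 5)
  expect_equal(dim(st), c(10L, 3L))
  for (j in 1:3) {
    u <- (st[, j] - bounds[j, 1]) / (bounds[j, 2] - bounds[j, 1])
    # exactly one point per decile
    expect_equal(sort(floor(u * 10)), 0:9)
  }
  expect_identical(st, sample_starts(bounds, 10, seed = 5))
  st1 <- sample_starts(bounds, 1, seed = 2)
  expect_true(all(st1 >= bounds[, 1] & st1 <= bounds[, 2]))
  expect_error(sample_starts(cbind(-Inf, 1), 3, seed = 1), "finite")
})

test_that("fitting the turnover toy reproduces the closed-form solution", {
  y <- c(2.0, 2.4, 2.2, 3.0)
  prob <- toy_turnover_problem(y)
  fit <- fit_pathway(prob, n_starts = 5, seed = 3)
  k_synR <- default_parameters()$value[default_parameters()$name == "k_synR"]
  expect_equal(unname(coef(fit)[["k_degR"]]), k_synR / mean(y),
               tolerance = 1e-6)
  # analytic minimum of the quadratic objective
  r_star <- (y - mean(y)) / 0.33
  expect_equal(fit$best_nll,
               0.5 * sum(r_star^2) + egfrsig:::negloglik_const(rep(0.33, 4)),
               tolerance = 1e-8)
})

test_that("multi-start results are invariant to start order and reproducible", {
  prob <- toy_turnover_problem()
  st <- sample_starts(prob, 4, seed = 9)
  f1 <- fit_pathway(prob, starts = st)
  f2 <- fit_pathway(prob, starts = st[c(3, 1, 4, 2), , drop = FALSE])
  expect_equal(f1$results$nll, f2$results$nll, tolerance = 1e-10)
  f3 <- fit_pathway(prob, n_starts = 4, seed = 9)
  expect_equal(f1$results$nll, f3$results$nll)
})

test_that("the objective never increases from start to final", {
  prob <- toy_turnover_problem()
  st <- sample_starts(prob, 5, seed = 11)
  fit <- fit_pathway(prob, starts = st)
  for (i in seq_len(nrow(fit$results))) {
    start_nll <- egfrsig:::problem_negloglik(
      prob, as.numeric(fit$starts[i, ]))
    expect_lte(fit$results$nll[i], start_nll + 1e-10)
  }
})

test_that("a noise-free optimum is a fixed point of the optimizer", {
  fit <- fx_fit_noisefree()
  prob <- fit$problem
  # at the generating truth the residuals vanish: the final objective equals
  # the sigma constant and the parameters stay put
  expect_equal(fit$best_nll, prob$const, tolerance = 1e-6)
  start <- fx_truth_start(prob, fx_ds_noisefree())
  expect_lt(max(abs(fit$best_par - start)), 1e-4)
})

test_that("convergence classification splits plateau, local and failed starts", {
  fake <- list(results = data.frame(nll = c(5.00, 5.05, 7.0),
                                    failed = c(FALSE, FALSE, FALSE)),
               best_nll = 5.00)
  expect_equal(classify_convergence(fake, margin = 0.1)$label,
               c("global-plateau", "global-plateau", "local"))
  expect_equal(classify_convergence(fake, margin = 0)$label,
               c("global-plateau", "local", "local"))
  allsame <- list(results = data.frame(nll = rep(2, 4), failed = FALSE),
                  best_nll = 2)
  expect_true(all(classify_convergence(allsame)$label == "global-plateau"))
  withfail <- list(results = data.frame(nll = c(1, Inf),
                                        failed = c(FALSE, TRUE)),
                   best_nll = 1)
  expect_equal(classify_convergence(withfail)$label[2], "failed")
  # likelihood-ratio note: within chi2(0.95,1)/2 of the best
  expect_equal(classify_convergence(fake)$indistinguishable,
               c(TRUE, TRUE, FALSE))
})

test_that("problem construction validates free parameter declarations", {
  ds <- fx_ds_noisy()
  expect_error(pathway_problem(ds, free_kinetic = "k_nope"), "unknown")
  expect_error(pathway_problem(ds, free_xi_cell = "k_onL"), "direct")
  expect_error(pathway_problem(ds, free_xi_medium = "k_erkOff"),
               "expression")
})

test_that("analytic scaling profiling reaches the same optimum as free scalings", {
  ds <- fx_ds_noisy()
  freek <- c("k_degR", "k_erkOff")
  p1 <- pathway_problem(ds, free_kinetic = freek, profile_scalings = TRUE)
  p2 <- pathway_problem(ds, free_kinetic = freek, profile_scalings = FALSE)
  f1 <- fit_pathway(p1, n_starts = 3, seed = 4,
                    control = list(maxiter = 100))
  f2 <- fit_pathway(p2, n_starts = 3, seed = 4,
                    control = list(maxiter = 300))
  expect_equal(f1$best_nll, f2$best_nll, tolerance = 1e-4)
})

test_that("optional log10 priors pull weakly informed estimates", {
  y <- c(2.0, 2.4, 2.2, 3.0)
  prob0 <- toy_turnover_problem(y)
  data_opt <- log10(default_parameters()$value[
    default_parameters()$name == "k_synR"] / mean(y))
  prior_mean <- data_opt + 0.5
  fit_with <- function(sd) {
    ds <- prob0$dataset
    prob <- pathway_problem(ds, free_kinetic = "k_degR",
                            free_scalings = FALSE, sigma = prob0$sigma,
                            priors = data.frame(name = "k_degR",
                                                mean_log10 = prior_mean,
                                                sd_log10 = sd))
    fit_pathway(prob, n_starts = 3, seed = 1)$best_par[[1]]
  }
  loose <- fit_with(0.5)
  tight <- fit_with(0.003)
  # the penalized optimum lies between the data optimum and the prior mean,
  # and approaches the prior as it tightens
  expect_gt(loose, data_opt)
  expect_lt(loose, prior_mean)
  expect_gt(tight, loose)
  expect_equal(tight, prior_mean, tolerance = 1e-2)
  expect_error(pathway_problem(prob0$dataset, free_kinetic = "k_degR",
                               priors = data.frame(name = "k_int",
                                                   mean_log10 = 0,
                                                   sd_log10 = 1)),
               "free kinetic")
})
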