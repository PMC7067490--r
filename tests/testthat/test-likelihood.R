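make_traj <- function(net, states, times = seq_len(nrow(states)) - 1) {
  structure(list(time = times, states = states, sens = NULL,
                 condition = NULL), class = "pathway_trajectory")
}

test_that("observable prediction is linear in the scaling factor", {
  net <- build_network(pathway_variant("MKN1"))
  obs <- pathway_observables(net)
  x <- matrix(0, 2, nrow(net$species),
              dimnames = list(NULL, net$species$id))
  x[, "pERK"] <- c(0.3, 0.6)
  x[, "pD"] <- 0.1; x[, "pDi"] <- 0.05
  tr <- make_traj(net, x)
  h1 <- predict_observables(tr, obs[c("obs_pERK", "obs_pEGFR")],
                            c(obs_pERK = 1, obs_pEGFR = 2))
  expect_equal(unname(h1[, "obs_pERK"]), c(0.3, 0.6))
  expect_equal(unname(h1[1, "obs_pEGFR"]), 2 * (2 * 0.1 + 2 * 0.05))  # 0.6
  h2 <- predict_observables(tr, obs[c("obs_pERK", "obs_pEGFR")],
                            c(obs_pERK = 2, obs_pEGFR = 4))
  expect_equal(h2, 2 * h1)
  expect_error(predict_observables(tr, obs["obs_pAKT"],
                                   c(obs_pERK = 1)), "obs_pAKT")
})

test_that("MKN1 and Hs746T observables reflect the variant species", {
  mk <- pathway_observables(build_network(pathway_variant("MKN1")))
  hs <- pathway_observables(build_network(pathway_variant("Hs746T",
                                                          inhibitor_enabled = TRUE)))
  expect_false("obs_pMMET" %in% names(mk))
  expect_setequal(names(hs$obs_MET), c("MMET", "pMMET", "IM", "IpM"))
  expect_equal(hs$obs_pMMET, c(pMMET = 1))
})

simple_dataset <- function(values_by_group, observable = "obs_pERK",
                           experiment = "gelA") {
  rows <- list()
  for (g in seq_along(values_by_group)) {
    v <- values_by_group[[g]]
    rows[[g]] <- data.frame(condition_id = "c1", observable_id = observable,
                            time = 10 * g, replicate = seq_along(v),
                            experiment_id = experiment, value = v,
                            stringsAsFactors = FALSE)
  }
  m <- do.call(rbind, rows)
  conds <- data.frame(condition_id = "c1", cell_line = "MKN1", medium = "FM",
                      ligand_dose = 30, cetuximab_dose = 0,
                      inhibitor_dose = 0, stringsAsFactors = FALSE)
  pathway_dataset(m, conds)
}

test_that("pooled noise estimation matches hand-computed SDs", {
  # one replicated group {0, 2}: SD = sqrt(2)
  ds1 <- simple_dataset(list(c(0, 2)))
  expect_equal(estimate_noise_sd(ds1)$sigma, sqrt(2))
  # equal group variances pool to themselves
  ds2 <- simple_dataset(list(c(0, 2), c(10, 12)))
  expect_equal(estimate_noise_sd(ds2)$sigma, sqrt(2))
  # identical replicates everywhere: degenerate, floored
  ds3 <- simple_dataset(list(c(1, 1, 1), c(2, 2, 2)))
  s3 <- estimate_noise_sd(ds3)
  expect_equal(s3$sigma, 1e-3 * 1)  # 1e-3 x value range
  expect_true(length(attr(s3, "degenerate")) == 1)
  # no replicated design point at all: instruct the user
  ds4 <- simple_dataset(list(0.5, 1.5))
  expect_error(estimate_noise_sd(ds4), "sigma")
})

test_that("negative log-likelihood follows the Gaussian closed form", {
  # perfect fit, 3 records, sigma = 1: only the constant term remains
  expect_equal(negloglik(c(1, 2, 3), c(1, 2, 3), rep(1, 3)),
               1.5 * log(2 * pi))
  # single record, residual 2, sigma 2
  expect_equal(negloglik(3, 1, 2), 0.5 + 0.5 * log(8 * pi))
  # scaling all sigma by c adds sum(log c) and shrinks the quadratic term
  y <- c(0.3, 1.2, -0.5); h <- c(0.1, 1.0, 0.2); s <- c(1, 2, 0.5)
  cc <- 3
  quad <- function(y, h, s) 0.5 * sum(((y - h) / s)^2)
  expect_equal(negloglik(y, h, cc * s),
               quad(y, h, s) / cc^2 + negloglik(y, h, s) - quad(y, h, s) +
                 length(y) * log(cc))
  expect_error(negloglik(1, 1, 0), "sigma")
})

test_that("weighted residuals reproduce the quadratic likelihood term", {
  expect_equal(weighted_residuals(c(1, 2), c(1, 2), c(1, 3)), c(0, 0))
  expect_equal(weighted_residuals(3, 1, 2), 1)
  set.seed(1)
  for (i in 1:100) {
    n <- sample(1:20, 1)
    y <- rnorm(n); h <- rnorm(n); s <- runif(n, 0.1, 2)
    r <- weighted_residuals(y, h, s)
    expect_equal(0.5 * sum(r^2) + egfrsig:::negloglik_const(s),
                 negloglik(y, h, s), tolerance = 1e-12)
  }
})

test_that("rescaling a gel's data, scaling factor and sigma leaves residuals invariant", {
  # the gauge freedom of blot quantification: y -> c y, s -> c s, sigma -> c
  # sigma changes the likelihood only through the Jacobian constant
  set.seed(2)
  f <- runif(6, 0.5, 2)          # unscaled model observables
  s <- 1.4                       # scaling factor
  y <- s * f + rnorm(6, 0, 0.1)
  sig <- rep(0.1, 6)
  cc <- 5
  r1 <- weighted_residuals(y, s * f, sig)
  r2 <- weighted_residuals(cc * y, (cc * s) * f, cc * sig)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(negloglik(cc * y, cc * s * f, cc * sig) -
                 negloglik(y, s * f, sig), 6 * log(cc), tolerance = 1e-10)
})

test_that("dataset validation rejects malformed records", {
  m <- data.frame(condition_id = "c1", observable_id = "obs_pERK",
                  time = 0, replicate = 1, experiment_id = "g", value = 1)
  conds <- data.frame(condition_id = "c1", cell_line = "MKN1", medium = "FM",
                      ligand_dose = 0, cetuximab_dose = 0, inhibitor_dose = 0)
  expect_s3_class(pathway_dataset(m, conds), "pathway_dataset")
  expect_error(pathway_dataset(rbind(m, m), conds), "duplicate")
  m2 <- m; m2$value <- NA_real_
  expect_error(pathway_dataset(m2, conds), "finite")
  m3 <- m; m3$condition_id <- "nope"
  expect_error(pathway_dataset(m3, conds), "unknown conditions")
})
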