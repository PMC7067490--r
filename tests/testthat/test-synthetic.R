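test_that("the default truth encodes the selected specificity structure", {
  tr <- fx_truth()
  # 2.5-fold higher EGFR expression in MKN1 than Hs746T
  expect_equal(exp(-tr$fc$cell_line[["k_synR"]]), 2.5)
  # turnover-only truth: no RAS-MAPK or PI3K-AKT fold-changes
  turn <- egfrsig:::module_xi_parameters("egfr_turnover")
  expect_true(all(turn %in% names(tr$fc$cell_line)))
  expect_false(any(egfrsig:::module_xi_parameters("ras_mapk") %in%
                     names(tr$fc$cell_line)))
  expect_false(any(egfrsig:::module_xi_parameters("pi3k_akt") %in%
                     names(tr$fc$cell_line)))
  expect_equal(abs(unname(tr$fc$cell_line[turn])), rep(log(3), 4))
  # reproducible construction
  expect_equal(default_truth(seed = 1), tr)
})

test_that("dataset generation is reproducible and exact without noise", {
  tr <- fx_truth()
  des <- pathway_design(cell_lines = "MKN1", tc_times = c(0, 15, 60),
                        cetux_doses = NULL, egf_doses = c(5, 100),
                        replicates = 2)
  d1 <- generate_dataset(tr, des, noise = TRUE, seed = 3)
  d2 <- generate_dataset(tr, des, noise = TRUE, seed = 3)
  expect_equal(d1$measurements, d2$measurements)
  d3 <- generate_dataset(tr, des, noise = TRUE, seed = 4)
  expect_false(isTRUE(all.equal(d1$measurements$value,
                                d3$measurements$value)))

  d0 <- generate_dataset(tr, des, noise = FALSE, seed = 3)
  # noise-free values equal scaling x simulated observables: check one
  # condition independently
  sc <- attr(d0, "scalings")
  theta <- fx_theta("MKN1")
  net <- build_network(pathway_variant("MKN1"))
  obs <- pathway_observables(net)
  co <- pathway_condition(ligand_dose = 30, timepoints = c(0, 15, 60))
  fm <- egfrsig:::observable_matrix(simulate_condition(net, theta, co), obs)
  m0 <- d0$measurements
  sel <- m0$condition_id == "MKN1_FM_tc" & m0$observable_id == "obs_pERK" &
    m0$replicate == 1
  expect_equal(m0$value[sel],
               unname(sc[["obs_pERK|MKN1_FM_tc"]] * fm[, "obs_pERK"]),
               tolerance = 1e-10)
})

test_that("replicate noise estimation recovers the generating SD within 15%", {
  tr <- fx_truth()
  # >= 30 replicated design points per gel
  des <- pathway_design(cell_lines = "MKN1",
                        tc_times = seq(0, 240, by = 8),
                        cetux_doses = NULL, egf_doses = NULL,
                        replicates = 3)
  ds <- generate_dataset(tr, des, noise = TRUE, seed = 12)
  est <- estimate_noise_sd(ds)
  cmp <- merge(est, ds$sigma, by = c("observable_id", "experiment_id"))
  expect_true(all(abs(cmp$sigma.x - cmp$sigma.y) / cmp$sigma.y < 0.15))
})

test_that("generated designs report their inventory per cell line", {
  ds <- fx_ds_noisy()
  inv <- attr(ds, "inventory")
  expect_equal(sum(inv$Freq), nrow(ds$measurements))
  expect_setequal(unique(inv$cell_line), "MKN1")
})

test_that("the selection suite spans all hypotheses with distinct replicates", {
  des <- pathway_design(cell_lines = c("MKN1", "Hs746T"),
                        tc_times = c(0, 30, 240), cetux_doses = NULL,
                        egf_doses = NULL, replicates = 2)
  suite <- generate_selection_suite(2, des, seed = 5)
  expect_equal(length(suite), 8L)
  expect_equal(names(suite), paste0("M", 1:8))
  expect_true(all(vapply(suite, length, 0L) == 2L))
  # the no-specificity truth carries only the expression fold-change
  tr1 <- attr(suite$M1[[1]], "truth")
  expect_equal(names(tr1$fc$cell_line), "k_synR")
  # full-specificity truth frees all 12 module parameters
  tr8 <- attr(suite$M8[[1]], "truth")
  expect_equal(length(tr8$fc$cell_line), 13L)
  # replicates share the truth but differ in their noise draws
  expect_false(isTRUE(all.equal(suite$M5[[1]]$measurements$value,
                                suite$M5[[2]]$measurements$value)))
})

test_that("mutant-MET signaling makes Hs746T a weak EGF responder", {
  # the non-responder phenotype emerges from mechanism: relative pERK
  # induction by EGF is much smaller in Hs746T than in MKN1
  resp <- vapply(c("MKN1", "Hs746T"), function(cl) {
    net <- build_network(pathway_variant(cl))
    th <- fx_theta(cl)
    co <- pathway_condition(ligand_dose = 30, timepoints = c(0, 15))
    tr <- simulate_condition(net, th, co)
    tr$states[2, "pERK"] / max(tr$states[1, "pERK"], 1e-9)
  }, 0)
  expect_gt(resp[["MKN1"]], 50)     # near-zero basal, strong induction
  expect_lt(resp[["Hs746T"]], 1.5)  # MET-driven basal, weak induction
})

test_that("starvation medium lowers expression through the medium fold-change", {
  tr <- fx_truth()
  # the truth halves EGFR synthesis in starvation medium
  th_fm <- resolve_parameters(fx_base_theta(), tr$fc, "MKN1", "FM")
  th_hm <- resolve_parameters(fx_base_theta(), tr$fc, "MKN1", "HM")
  expect_equal(th_hm[["k_synR"]] / th_fm[["k_synR"]], 0.5)

  # a two-media dataset reproduces exactly at the generating truth
  des <- pathway_design(cell_lines = "MKN1", media = c("FM", "HM"),
                        tc_times = c(0, 15, 60), cetux_doses = NULL,
                        egf_doses = NULL, replicates = 2)
  ds0 <- generate_dataset(tr, des, noise = FALSE, seed = 31)
  dsn <- generate_dataset(tr, des, noise = TRUE, seed = 31)
  prob <- pathway_problem(ds0, free_kinetic = c("k_degR", "k_erkOff"),
                          xi_medium = tr$fc$medium, sigma = dsn$sigma)
  start <- fx_truth_start(prob, ds0)
  r <- egfrsig:::problem_eval(prob, start, want_jac = FALSE)$residuals
  expect_lt(max(abs(r)), 1e-6)

  # medium fold-change sensitivities agree with finite differences
  prob2 <- pathway_problem(dsn, free_kinetic = "k_degR",
                           free_xi_medium = "k_synR",
                           profile_scalings = TRUE)
  p <- prob2$free$init + c(0.1, -0.3)
  ev <- egfrsig:::problem_eval(prob2, p, want_jac = TRUE)
  h <- 1e-4
  for (j in 1:2) {
    up <- p; up[j] <- up[j] + h
    dn <- p; dn[j] <- dn[j] - h
    fd <- (egfrsig:::problem_eval(prob2, up, FALSE)$residuals -
             egfrsig:::problem_eval(prob2, dn, FALSE)$residuals) / (2 * h)
    expect_lt(max(abs(ev$jacobian[, j] - fd)) / max(abs(fd)), 1e-3)
  }
})
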