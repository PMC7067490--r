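test_that("response normalization modes behave as specified", {
  expect_equal(normalize_response(c(2, 2, 2), "max"), c(1, 1, 1))
  expect_equal(normalize_response(c(1, 2, 4), "max"), c(0.25, 0.5, 1))
  m <- cbind(a = c(1, 2), b = c(5, 10))
  nm <- normalize_response(m, "max")
  expect_equal(apply(nm, 2, max), c(a = 1, b = 1))
  expect_true(all(nm >= 0 & nm <= 1))
  expect_equal(normalize_response(1, "untreated", reference = 2), 0.5)
  expect_error(normalize_response(1, "untreated", reference = 0), "zero")
  expect_error(normalize_response(1, "untreated"), "reference")
  expect_error(normalize_response(c(0, 0), "max"), "non-positive")
})

test_that("MET inhibition suppresses pMMET and pAKT monotonically", {
  th <- fx_theta("Hs746T")
  sim <- simulate_met_inhibitor(th, doses = c(0, 0.1, 0.3, 1, 3))
  # untreated reference maps to 1
  expect_equal(unname(sim$normalized[1, ]), rep(1, 3))
  expect_true(all(diff(sim$normalized[, "obs_pMMET"]) < 0))
  expect_true(all(diff(sim$normalized[, "obs_pAKT"]) < 0))
  # saturating dose drives pMMET towards zero
  expect_lt(sim$normalized[nrow(sim$normalized), "obs_pMMET"], 0.05)
  # pAKT keeps receptor-driven input: its reduction cannot exceed pMMET's
  expect_true(all(sim$normalized[, "obs_pAKT"] >=
                    sim$normalized[, "obs_pMMET"] - 1e-9))
  # the inhibitor needs the mutant-MET variant
  expect_error(simulate_met_inhibitor(fx_theta("MKN1"), cell_line = "MKN1"),
               "MMET")
})

test_that("AREG at affinity ratio 1 reproduces the EGF model exactly", {
  th <- fx_theta("MKN1")
  areg1 <- simulate_areg(th, ligand_dose = 30, cetuximab_dose = 1,
                         affinity_ratio = 1)
  net <- build_network(pathway_variant("MKN1"))
  obs <- pathway_observables(net)[c("obs_pEGFR", "obs_pERK", "obs_pAKT")]
  co <- pathway_condition(ligand_dose = 30, timepoints = areg1$times)
  egf <- egfrsig:::observable_matrix(simulate_condition(net, th, co), obs)
  expect_equal(areg1$ligand_only, egf, tolerance = 1e-8)
  expect_error(pathway_variant("MKN1", ligand = "AREG",
                               areg_affinity_ratio = 0), "ratio")
})

test_that("cetuximab blocks the lower-affinity ligand AREG more strongly", {
  th <- fx_theta("MKN1")
  red <- function(ratio) {
    a <- simulate_areg(th, ligand_dose = 30, cetuximab_dose = 1,
                       affinity_ratio = ratio)
    1 - max(a$ligand_plus_cetuximab[, "obs_pEGFR"]) /
      max(a$ligand_only[, "obs_pEGFR"])
  }
  expect_gte(red(50), red(1))
  # mutant PI3K keeps pAKT insensitive to cetuximab under either ligand
  for (ratio in c(1, 50)) {
    a <- simulate_areg(th, ligand_dose = 30, cetuximab_dose = 50,
                       affinity_ratio = ratio)
    rel <- abs(a$ligand_plus_cetuximab[, "obs_pAKT"] -
                 a$ligand_only[, "obs_pAKT"]) /
      a$ligand_only[, "obs_pAKT"]
    expect_lt(max(rel), 0.05)
  }
})

test_that("MET knockdown reduces downstream signaling monotonically", {
  th <- fx_theta("Hs746T")
  net <- build_network(pathway_variant("Hs746T"))
  ss <- t(vapply(c(1, 0.75, 0.5, 0.25, 0), function(fr) {
    pe <- preequilibrate(net, apply_knockdown(th, "k_synM", fr))
    c(pERK = pe$state[["pERK"]], pAKT = pe$state[["pAKT"]],
      met = pe$state[["MMET"]] + pe$state[["pMMET"]])
  }, numeric(3)))
  expect_true(all(diff(ss[, "pERK"]) < 1e-12))
  expect_true(all(diff(ss[, "pAKT"]) < 1e-12))
  # complete knockdown removes the MET pool entirely
  expect_equal(unname(ss[5, "met"]), 0, tolerance = 1e-10)
  # the MET pool scales exactly linearly with the retained fraction
  expect_equal(unname(ss[, "met"]), unname(ss[1, "met"] * c(1, 0.75, 0.5, 0.25, 0)),
               tolerance = 1e-7)
})

test_that("EGFR knockdown attenuates along the signaling cascade", {
  th <- fx_theta("MKN1")
  net <- build_network(pathway_variant("MKN1"))
  obs <- pathway_observables(net)[c("obs_pEGFR", "obs_pERK", "obs_pAKT")]
  at60 <- function(kd) {
    co <- pathway_condition(ligand_dose = 5, knockdown = kd,
                            timepoints = c(0, 60))
    egfrsig:::observable_matrix(simulate_condition(net, th, co), obs)[2, ]
  }
  ref <- at60(NULL)
  red <- 1 - at60(list(k_synR = 0.2)) / ref
  expect_gte(red[["obs_pEGFR"]], red[["obs_pERK"]])
  expect_gte(red[["obs_pERK"]], red[["obs_pAKT"]])
})

test_that("restoring wild-type PI3K re-sensitizes pAKT to cetuximab", {
  th <- fx_theta("MKN1")
  wt <- swap_pi3k_wildtype(th)
  net <- build_network(pathway_variant("MKN1"))
  # unstimulated steady-state pAKT decreases when the mutant term is removed
  expect_lt(preequilibrate(net, wt)$state[["pAKT"]],
            preequilibrate(net, th)$state[["pAKT"]])
  pakt <- function(p, cet) {
    co <- pathway_condition(ligand_dose = 30, cetuximab_dose = cet,
                            timepoints = c(0, 60))
    simulate_condition(net, p, co)$states[2, "pAKT"]
  }
  red_mut <- 1 - pakt(th, 50) / pakt(th, 0)
  red_wt <- 1 - pakt(wt, 50) / pakt(wt, 0)
  expect_gt(red_wt, red_mut)
  expect_lt(red_mut, 0.05)
})
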