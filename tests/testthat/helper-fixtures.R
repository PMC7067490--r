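# Shared fixtures, built lazily once per test run. All synthetic inputs are
# generated in code under fixed seeds.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

fx_truth <- function() fx_memo("truth", function() default_truth(seed = 1))

fx_base_theta <- function() {
  ptab <- default_parameters()
  stats::setNames(ptab$value, ptab$name)
}

fx_theta <- function(cell_line = "MKN1", medium = "FM") {
  resolve_parameters(fx_base_theta(), fx_truth()$fc, cell_line, medium)
}

# small MKN1 time-course + cetuximab dose-response design (the recovery
# layout, without the EGF dose series)
fx_design_mk <- function() fx_memo("design_mk", function()
  pathway_design(cell_lines = "MKN1", egf_doses = NULL))

fx_ds_noisefree <- function() fx_memo("ds_noisefree", function()
  generate_dataset(fx_truth(), fx_design_mk(), noise = FALSE, seed = 7))

fx_ds_noisy <- function() fx_memo("ds_noisy", function()
  generate_dataset(fx_truth(), fx_design_mk(), noise = TRUE, seed = 7))

fx_free_kinetic <- function() c("k_degR", "k_int", "k_rasE", "k_erkOff",
                                "k_aktOff", "k_synR")

# free-parameter start vector at the generating truth (kinetics at their true
# log10 values, scalings at the true per-gel factors)
fx_truth_start <- function(prob, ds) {
  start <- prob$free$init
  names(start) <- prob$free$pid
  sc <- attr(ds, "scalings")
  is_sc <- prob$free$kind == "scaling"
  start[is_sc] <- log10(sc[prob$free$target[is_sc]])
  start
}

# a small noise-free problem solved exactly at the truth; reused by the
# fitting, uncertainty and acceptance tests
fx_fit_noisefree <- function() fx_memo("fit_noisefree", function() {
  ds <- fx_ds_noisefree()
  prob <- pathway_problem(ds, free_kinetic = fx_free_kinetic(),
                          sigma = fx_ds_noisy()$sigma)
  fit_pathway(prob, starts = rbind(fx_truth_start(prob, ds)))
})

expect_rel_equal <- function(actual, expected, tol) {
  testthat::expect_lt(max(abs(actual - expected)) /
                        max(abs(expected), 1e-12), tol)
}

# tiny analytically solvable problem: unstimulated total-EGFR measurements,
# h = k_synR / k_degR, only k_degR free => least-squares optimum at
# k_degR = k_synR / weighted mean(y)
toy_turnover_problem <- function(y = c(2.0, 2.4, 2.2, 3.0), sigma = 0.33) {
  m <- data.frame(condition_id = "unstim", observable_id = "obs_EGFR",
                  time = 0, replicate = seq_along(y),
                  experiment_id = "gel1", value = y,
                  stringsAsFactors = FALSE)
  conds <- data.frame(condition_id = "unstim", cell_line = "MKN1",
                      medium = "FM", ligand_dose = 0, cetuximab_dose = 0,
                      inhibitor_dose = 0, stringsAsFactors = FALSE)
  sig <- data.frame(observable_id = "obs_EGFR", experiment_id = "gel1",
                    sigma = sigma)
  pathway_problem(pathway_dataset(m, conds, sig), free_kinetic = "k_degR",
                  free_scalings = FALSE, sigma = sig)
}

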