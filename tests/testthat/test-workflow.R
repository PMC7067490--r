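test_that("PEtab-style tables round-trip through write and read", {
  ds <- fx_ds_noisy()
  dir <- withr::local_tempdir()
  write_petab_tables(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("measurements.tsv", "conditions.tsv", "observables.tsv",
           "parameters.tsv")))))
  back <- read_petab_tables(dir)
  for (col in c("condition_id", "observable_id", "time", "value"))
    expect_equal(back$measurements[[col]], ds$measurements[[col]])
  sig <- merge(back$sigma, ds$sigma,
               by = c("observable_id", "experiment_id"))
  expect_equal(sig$sigma.x, sig$sigma.y, tolerance = 1e-12)
  # the round-tripped dataset supports the same likelihood computation
  expect_equal(estimate_noise_sd(back)$sigma, estimate_noise_sd(ds)$sigma)
})

test_that("unknown configuration keys are rejected by name", {
  expect_error(run_workflow(list(sead = 1)), "sead")
  expect_error(run_workflow(list(estimation = list(nstarts = 5))),
               "estimation.nstarts")
})

test_that("the generate stage writes seeded, reproducible artifacts", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- list(seed = 7, stages = "generate",
              design = list(cell_lines = "MKN1", tc_times = c(0, 30, 120),
                            cetux_doses = NULL, egf_doses = NULL,
                            replicates = 2))
  res <- run_workflow(cfg, outdir = d1)
  expect_true(file.exists(file.path(d1, "resolved_config.yaml")))
  expect_true(file.exists(file.path(d1, "log.jsonl")))
  expect_true(file.exists(file.path(d1, "petab", "measurements.tsv")))
  expect_true(file.exists(file.path(d1, "petab", "truth.yaml")))
  expect_s3_class(res$dataset, "pathway_dataset")
  # identical configuration and seed reproduce the bytes
  run_workflow(cfg, outdir = d2)
  expect_identical(readLines(file.path(d1, "petab", "measurements.tsv")),
                   readLines(file.path(d2, "petab", "measurements.tsv")))
  # log records the stages
  logs <- lapply(readLines(file.path(d1, "log.jsonl")), jsonlite::fromJSON)
  expect_true(any(vapply(logs, `[[`, "", "stage") == "generate"))
  # requesting only `generate` produces no fit artifacts
  expect_false(file.exists(file.path(d1, "waterfall.tsv")))
})

test_that("generate-fit-predict stages chain into one reproducible run", {
  dir <- withr::local_tempdir()
  cfg <- list(seed = 3, stages = c("generate", "fit", "predict"),
              design = list(cell_lines = "MKN1", tc_times = c(0, 15, 60),
                            cetux_doses = NULL, egf_doses = NULL,
                            replicates = 2),
              estimation = list(n_starts = 2, maxiter = 25,
                                free_kinetic = c("k_degR", "k_erkOff"),
                                profile_scalings = TRUE),
              predictions = list(experiments = c("met-inhibitor", "pi3k-wt"),
                                 inhibitor_doses = c(0, 1)))
  res <- run_workflow(cfg, outdir = dir)
  expect_true(file.exists(file.path(dir, "waterfall.tsv")))
  expect_true(file.exists(file.path(dir, "best_parameters.tsv")))
  expect_true(file.exists(file.path(dir, "predict_met_inhibitor.tsv")))
  expect_true(file.exists(file.path(dir, "predict_pi3k_wt.tsv")))
  wf <- utils::read.delim(file.path(dir, "waterfall.tsv"))
  expect_equal(nrow(wf), 2L)
  expect_true(all(is.finite(wf$nll)))
  # the prediction table reflects mutant-PI3K cetuximab insensitivity
  pw <- utils::read.delim(file.path(dir, "predict_pi3k_wt.tsv"))
  mut <- pw[pw$genotype == "mutant", ]
  wtr <- pw[pw$genotype == "wildtype", ]
  expect_lt(abs(mut$pAKT_cetuximab - mut$pAKT_untreated) / mut$pAKT_untreated,
            0.05)
  expect_gt(abs(wtr$pAKT_cetuximab - wtr$pAKT_untreated) / wtr$pAKT_untreated,
            0.05)
})

test_that("SBML export round-trips species and reaction counts", {
  skip_if_not_installed("xml2")
  net <- build_network(pathway_variant("Hs746T", inhibitor_enabled = TRUE))
  f <- withr::local_tempfile(fileext = ".xml")
  export_sbml(net, f, params = fx_base_theta())
  doc <- xml2::read_xml(f)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  expect_length(xml2::xml_find_all(doc, "//sbml:species", ns),
                nrow(net$species))
  expect_length(xml2::xml_find_all(doc, "//sbml:reaction", ns),
                nrow(net$reactions))
})
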