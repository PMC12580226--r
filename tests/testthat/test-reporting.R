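test_that("the bundled scenario grid mirrors the standard 8+6+4 layout", {
  scen <- load_scenarios()
  expect_named(scen, c("fit_based", "tcs_based", "combined"))
  expect_length(scen$fit_based$scenarios, 8)
  expect_length(scen$tcs_based$scenarios, 6)
  expect_length(scen$combined$scenarios, 4)

  p <- synthesize_parameters(41)
  # desk-scale grid run: structure is what is under test here
  small <- list(fit_based = scen$fit_based,
                tcs_based = list(reference_mode = "same_uptake_fit",
                                 scenarios = scen$tcs_based$scenarios[c(1, 5)]))
  small$fit_based$scenarios <- scen$fit_based$scenarios[c(1, 2)]
  grids <- run_grid(p, small, n_individuals = 400, seed = 3)
  expect_named(grids, c("fit_based", "tcs_based"))
  tab <- grids$fit_based
  expect_equal(tab$row,
               c("Cost (per person)", "CRC cases (per 10^5 persons)",
                 "CRC death (per 10^5 persons)", "QALYs (per person)",
                 "ICER (per QALY)"))
  expect_equal(ncol(tab), 3)  # row labels + 2 scenarios
  expect_s3_class(attr(grids, "manifest"), "crc_manifest")
})

test_that("a single-scenario grid degenerates to one column", {
  p <- synthesize_parameters(42)
  one <- list(solo = list(
    reference = list(kind = "FIT_based", fit_uptake = 0.4),
    scenarios = list(list(label = "only", kind = "FIT_based", fit_uptake = 0.4))))
  grids <- run_grid(p, one, n_individuals = 300, seed = 2)
  expect_equal(ncol(grids$solo), 2)
  # self-comparison against the reference shows equivalence
  expect_identical(grids$solo[["only"]][5], "Equivalent")
})

test_that("grid reruns reproduce the CSV bytes and flag synthetic inputs", {
  p <- synthesize_parameters(43)
  one <- list(solo = list(
    reference = list(kind = "None"),
    scenarios = list(list(label = "fit", kind = "FIT_based", fit_uptake = 0.5))))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_grid(p, one, n_individuals = 400, seed = 9, out_dir = d1)
  run_grid(p, one, n_individuals = 400, seed = 9, out_dir = d2)
  f1 <- readLines(file.path(d1, "grid_solo.csv"))
  f2 <- readLines(file.path(d2, "grid_solo.csv"))
  expect_identical(f1, f2)
  expect_true(any(grepl("SYNTHETIC PARAMETERS", f1)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  m <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_true(m$synthetic_parameters)
  expect_equal(m$provenance$synthetic, 7)
})

test_that("run_scenario is reproducible and honors overrides", {
  p <- synthesize_parameters(44)
  st <- strategy_spec("FIT_based", fit_uptake = 0.4)
  r1 <- run_scenario(p, st, NULL, n_individuals = 500, seed = 7)
  r2 <- run_scenario(p, st, NULL, n_individuals = 500, seed = 7)
  expect_equal(r1$outcomes$strategy$mean_discounted_cost,
               r2$outcomes$strategy$mean_discounted_cost)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
  # Dukes-D scenario flows into the manifest hash and the costs
  r3 <- run_scenario(p, st, NULL, n_individuals = 500, seed = 7, dukesd_x10 = TRUE)
  expect_false(identical(r1$manifest$config_hash, r3$manifest$config_hash))
  expect_gte(r3$outcomes$strategy$mean_discounted_cost,
             r1$outcomes$strategy$mean_discounted_cost)
})

test_that("PSA scenario labels carry the documented uptake tuples", {
  p <- synthesize_parameters(45)
  cfg <- psa_config(n_draws = 2, n_individuals_per_draw = 200, seed = 3)
  r <- run_psa_scenario(p, "realistic", cfg)
  expect_equal(unlist(r$uptakes),
               c(fit_uptake = 0.40, tcs_after_fit_uptake = 0.70,
                 primary_tcs_uptake = 0.20))
  o <- run_psa_scenario(p, "optimistic", cfg)
  expect_equal(unlist(o$uptakes),
               c(fit_uptake = 0.60, tcs_after_fit_uptake = 0.70,
                 primary_tcs_uptake = 0.60))
  expect_error(run_psa_scenario(p, "pessimistic", cfg), "realistic, optimistic")
  # custom tuple accepted
  c1 <- run_psa_scenario(p, list(fit_uptake = 0.5, tcs_after_fit_uptake = 0.8,
                                 primary_tcs_uptake = 0.3), cfg)
  expect_identical(c1$scenario, "custom")
})

test_that("fixtures round-trip through the loader", {
  d <- withr::local_tempdir()
  paths <- write_fixtures(d, seed = 4, n_individuals = 50)
  p <- load_parameters(paths[["params"]])
  expect_s3_class(p, "crc_parameters")
  expect_equal(p, synthesize_parameters(4), tolerance = 1e-15)
  pop <- utils::read.csv(paths[["population"]])
  expect_equal(nrow(pop), 50)
})
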