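test_that("parameter draws are moment-matched to mean base, sd = base*rf/2", {
  set.seed(21)
  n <- 1e5
  x <- draw_parameter(0.8, "beta", 0.25, n = n)
  expect_lt(abs(mean(x) - 0.8), 3.3 * 0.1 / sqrt(n))
  expect_lt(abs(sd(x) / 0.1 - 1), 0.05)
  g <- draw_parameter(30000, "gamma", 0.25, n = n)
  expect_true(all(g > 0))
  expect_lt(abs(mean(g) / 30000 - 1), 0.005)
  expect_lt(abs(sd(g) / 3750 - 1), 0.05)
  # degenerate limit: draws collapse to the base value
  tight <- draw_parameter(0.5, "beta", 1e-4, n = 1000)
  expect_lt(max(abs(tight - 0.5)), 1e-3)
  expect_error(draw_parameter(0, "gamma"), "> 0")
  expect_error(draw_parameter(-1, "beta"), "> 0")
  expect_error(draw_parameter(1.2, "beta"), "base < 1")
})

test_that("hard-bound mode stays on its support with the right mean", {
  set.seed(22)
  x <- draw_parameter(0.4, "beta", 0.25, n = 2e4, bound_mode = "hard")
  expect_true(all(x >= 0.3 & x <= 0.5))
  expect_lt(abs(mean(x) - 0.4), 3.3 * sd(x) / sqrt(2e4))
})

test_that("perturbed parameter sets keep every invariant", {
  p <- synthesize_parameters(23)
  cfg <- psa_config(n_draws = 1, n_individuals_per_draw = 10, seed = 1)
  set.seed(33)
  for (i in 1:20) {
    pj <- crcscreen:::perturb_parameters(p, cfg)
    expect_silent(validate_parameters(pj))
    expect_true(all(abs(apply(pj$transition, c(1, 2, 3), sum) - 1) < 1e-9))
  }
})

test_that("self-comparison yields zero deltas and the tie rule", {
  p <- synthesize_parameters(24)
  st <- strategy_spec("FIT_based", fit_uptake = 0.4)
  cfg <- psa_config(n_draws = 10, n_individuals_per_draw = 300, seed = 5)
  res <- run_psa(p, st, st, cfg)
  expect_true(all(res$draws$delta_cost == 0))
  expect_true(all(res$draws$delta_qaly == 0))
  # NMB exactly 0 counts as not cost-effective
  expect_equal(res$summary$prob_cost_effective, 0)
})

test_that("PSA is reproducible and leaves the session RNG alone", {
  p <- synthesize_parameters(25)
  a <- strategy_spec("TCS_based", primary_tcs_uptake = 0.4)
  b <- strategy_spec("FIT_based", fit_uptake = 0.4)
  cfg <- psa_config(n_draws = 4, n_individuals_per_draw = 400, seed = 6)
  set.seed(1); before <- .Random.seed
  r1 <- run_psa(p, a, b, cfg)
  expect_identical(before, .Random.seed)
  r2 <- run_psa(p, a, b, cfg)
  expect_identical(r1$draws, r2$draws)
})

test_that("a constructed-dominance configuration gives probability 1", {
  p <- synthesize_parameters(26, "aggressive")
  # free, perfect colonoscopy: the screening arm can only do better
  p$costs$fit <- 1e-6
  p$costs$tcs <- 1e-6
  p$costs$polypectomy <- 1e-6
  p$test_chars$tcs_sensitivity[] <- 1 - 1e-9
  p$test_chars$tcs_perforation_prob <- 1e-12
  a <- strategy_spec("TCS_based", primary_tcs_uptake = 1, tcs_interval = 5,
                     surveillance_uptake = 1)
  b <- strategy_spec("None")
  cfg <- psa_config(n_draws = 10, n_individuals_per_draw = 2000, seed = 7,
                    perturb = "costs")
  res <- run_psa(p, a, b, cfg)
  expect_equal(res$summary$prob_cost_effective, 1.0)
})

test_that("threshold limits recompute exactly from the stored draws", {
  p <- synthesize_parameters(27)
  a <- strategy_spec("TCS_based", primary_tcs_uptake = 0.5)
  b <- strategy_spec("FIT_based", fit_uptake = 0.5)
  cfg <- psa_config(n_draws = 30, n_individuals_per_draw = 500, seed = 8)
  res <- run_psa(p, a, b, cfg)
  expect_equal(prob_cost_effective(res, 0), mean(res$draws$delta_cost < 0))
  expect_equal(prob_cost_effective(res, 1e15), mean(res$draws$delta_qaly > 0))
  # invariant to draw order / relabeling
  perm <- sample(nrow(res$draws))
  shuffled <- res; shuffled$draws <- res$draws[perm, ]
  expect_equal(prob_cost_effective(shuffled, 5e6), prob_cost_effective(res, 5e6))
})

test_that("CE-plane export is consistent and round-trips through CSV", {
  p <- synthesize_parameters(28)
  a <- strategy_spec("TCS_based", primary_tcs_uptake = 0.5)
  b <- strategy_spec("FIT_based", fit_uptake = 0.5)
  cfg <- psa_config(n_draws = 12, n_individuals_per_draw = 300, seed = 9)
  res <- run_psa(p, a, b, cfg)
  tab <- ce_plane_export(res)
  expect_equal(nrow(tab), 12)
  expect_equal(mean(tab$cost_effective), res$summary$prob_cost_effective)
  expect_equal(sum(res$summary$quadrants), 12)
  f <- withr::local_tempfile(fileext = ".csv")
  ce_plane_export(res, f)
  back <- utils::read.csv(f)
  expect_equal(back$delta_qaly, tab$delta_qaly)
  expect_equal(back$delta_cost, tab$delta_cost)
  expect_equal(back$cost_effective, tab$cost_effective)
})
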