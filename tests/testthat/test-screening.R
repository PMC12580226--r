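test_that("offers respect the age range, schedule and CRC exit", {
  st <- strategy_spec("FIT_based")
  expect_identical(plan_offer(new_person(75, "female"), st, year = 0), "none")
  expect_identical(plan_offer(new_person(45, "female"), st, year = 0), "FIT")
  expect_identical(plan_offer(new_person(45, "female", "ClinicalCRC_DukesA"), st, 0), "none")
  expect_error(plan_offer({pr <- new_person(45, "female"); pr$state <- 14L; pr}, st, 0), "live")

  # 35-year trajectory: exactly one FIT offer per eligible alive year
  pr <- new_person(40, "male")
  offers <- 0
  for (year in 0:40) {
    if (plan_offer(pr, st, year) == "FIT") offers <- offers + 1
    pr$age <- pr$age + 1L
  }
  expect_equal(offers, 35)  # ages 40..74 inclusive

  # 10-yearly primary colonoscopy: offers in rounds 0, 10, 20, 30 only
  st2 <- strategy_spec("TCS_based")
  pr <- new_person(40, "male")
  got <- c()
  for (year in 0:34) {
    if (plan_offer(pr, st2, year) == "TCS_primary") got <- c(got, year)
    pr$age <- pr$age + 1L
  }
  expect_equal(got, c(0, 10, 20, 30))

  # surveillance supersedes routine screening
  pr <- new_person(60, "female", "PostPolypectomy")
  pr$surveillance_due_year <- 3L
  expect_identical(plan_offer(pr, st, year = 3), "TCS_surveillance")
  expect_identical(plan_offer(pr, st, year = 2), "FIT")
})

test_that("combined-arm assignment is persistent and binomial", {
  st <- strategy_spec("Combined", combined_fit_fraction = 1)
  set.seed(1)
  expect_identical(assign_combined_arm(new_person(50, "female"), st)$arm, "FIT_arm")
  st8 <- strategy_spec("Combined", combined_fit_fraction = 0.8)
  set.seed(42)
  arms <- replicate(10000, assign_combined_arm(new_person(50, "female"), st8)$arm)
  expect_lt(abs(mean(arms == "FIT_arm") - 0.8), 3.3 * sqrt(0.8 * 0.2 / 10000))
  # idempotent: cached arm wins
  pr <- new_person(50, "female"); pr$arm <- "TCS_arm"
  expect_identical(assign_combined_arm(pr, st8)$arm, "TCS_arm")
  # deterministic under a fixed seed
  set.seed(9); a1 <- assign_combined_arm(new_person(50, "female"), st8)$arm
  set.seed(9); a2 <- assign_combined_arm(new_person(50, "female"), st8)$arm
  expect_identical(a1, a2)
})

test_that("FIT realization follows sensitivity and specificity", {
  p <- default_parameters()
  expect_error(perform_fit(new_person(50, "female", "ClinicalCRC_DukesB"), p),
               "excluded")
  p$test_chars$fit_specificity <- 1
  set.seed(3)
  res <- replicate(200, perform_fit(new_person(50, "female"), p)$event$result)
  expect_true(all(res == "negative"))
  # positive fraction matches the lesion-class sensitivity
  s <- p$test_chars$fit_sensitivity[["hr"]]
  set.seed(4)
  n <- 10000
  pos <- replicate(n, perform_fit(new_person(60, "male", "HighRiskPolyp"), p)$event$result)
  expect_lt(abs(mean(pos == "positive") - s), 3.3 * sqrt(s * (1 - s) / n))
  # cost booked with the person-cycle discount factor
  pr <- new_person(50, "female"); pr$year <- 5L
  set.seed(1)
  out <- perform_fit(pr, p)
  expect_equal(out$person$cost_disc, p$costs$fit / 1.02^5)
  expect_equal(out$person$cost_undisc, p$costs$fit)
})

test_that("colonoscopy detects, resects, refers and perforates as configured", {
  p <- default_parameters()
  st <- strategy_spec("TCS_based")
  p$test_chars$tcs_sensitivity[] <- 1
  p$test_chars$tcs_perforation_prob <- 0
  set.seed(5)
  out <- perform_tcs(new_person(55, "female", "HighRiskPolyp"), p, st, "primary")
  expect_identical(crc_states()[out$person$state], "PostPolypectomy")
  expect_equal(out$person$surveillance_due_year,
               0L + st$surveillance_intervals[["hr"]])
  expect_equal(out$event$cost_booked, p$costs$tcs + p$costs$polypectomy)
  # detected preclinical CRC becomes clinical at the same stage
  out2 <- perform_tcs(new_person(60, "male", "PreclinicalCRC_DukesC"), p, st, "followup")
  expect_identical(crc_states()[out2$person$state], "ClinicalCRC_DukesC")
  expect_true(out2$person$ever_crc)
  # blind scope: state unchanged, only the scope cost booked
  p$test_chars$tcs_sensitivity[] <- 0
  out3 <- perform_tcs(new_person(55, "female", "HighRiskPolyp"), p, st, "primary")
  expect_identical(crc_states()[out3$person$state], "HighRiskPolyp")
  expect_equal(out3$event$cost_booked, p$costs$tcs)
  # perforation frequency matches its probability
  p$test_chars$tcs_perforation_prob <- 0.3
  set.seed(6)
  n <- 5000
  perf <- replicate(n, perform_tcs(new_person(55, "female"), p, st, "primary")$event$complication)
  expect_lt(abs(mean(perf) - 0.3), 3.3 * sqrt(0.3 * 0.7 / n))
})

test_that("surveillance intervals come from the guideline table", {
  expect_equal(surveillance_next_due("hr"), 3)
  expect_equal(surveillance_next_due(c("lr_small", "hr")), 3)  # most advanced wins
  expect_true(is.na(surveillance_next_due(character(0))))
  expect_error(surveillance_next_due("sessile_serrated"), "lesion class")
  # configured table flows through to scheduled surveillance
  st <- strategy_spec("TCS_based", surveillance_intervals = c(lr_small = 7, lr_medium = 6, hr = 2))
  p <- default_parameters()
  p$test_chars$tcs_sensitivity[] <- 1
  set.seed(2)
  out <- perform_tcs(new_person(50, "female", "LowRiskPolyp_5_9mm"), p, st, "primary")
  expect_equal(out$person$surveillance_due_year, 6L)
})

test_that("zero uptake reproduces the no-screening comparator exactly", {
  p <- synthesize_parameters(3)
  pop <- small_pop(1500, seed = 6)
  ref <- run_cohort(pop, p, NULL, seed = 8, keep_person = TRUE)
  for (kind in c("FIT_based", "TCS_based", "Combined")) {
    st <- strategy_spec(kind, fit_uptake = 0, tcs_after_fit_uptake = 0,
                        primary_tcs_uptake = 0, surveillance_uptake = 0)
    out <- run_cohort(pop, p, st, seed = 8, keep_person = TRUE)
    expect_identical(out$person, ref$person)
    expect_equal(out$mean_discounted_cost, ref$mean_discounted_cost)
    expect_equal(out$mean_discounted_qalys, ref$mean_discounted_qalys)
  }
})

test_that("perfect annual FIT screening intercepts CRC before presentation", {
  p <- synthesize_parameters(4, "aggressive")
  p$test_chars$fit_sensitivity[c("crc_a", "crc_b", "crc_c", "crc_d")] <- 1
  p$test_chars$tcs_sensitivity[] <- 1
  st <- strategy_spec("FIT_based", fit_uptake = 1, tcs_after_fit_uptake = 1,
                      surveillance_uptake = 1)
  set.seed(11)
  presented_in_range <- 0
  for (i in 1:150) {
    pr <- new_person(40L, if (i %% 2) "female" else "male")
    year <- 0L
    while (pr$state <= 13L) {
      pr <- apply_screening_cycle(pr, st, p, year)
      was_preclin <- pr$state %in% 5:8
      pr <- step_person(pr, p)
      # clinical presentation = preclinical before the step, clinical after
      if (was_preclin && pr$state %in% 9:12 && (pr$age - 1L) <= 74) {
        presented_in_range <- presented_in_range + 1
      }
      year <- year + 1L
    }
  }
  expect_equal(presented_in_range, 0)
})

test_that("surveillance attendance honors its uptake rate", {
  p <- synthesize_parameters(5, "aggressive")
  st <- strategy_spec("TCS_based", primary_tcs_uptake = 0.8)
  out <- run_cohort(small_pop(20000, seed = 12), p, st, seed = 13)
  ev <- out$events
  expect_gt(ev$n_surveillance_offered, 500)
  phat <- ev$n_surveillance_attended / ev$n_surveillance_offered
  expect_lt(abs(phat - 0.70),
            3.3 * sqrt(0.7 * 0.3 / ev$n_surveillance_offered))
})

test_that("booked screening costs reconcile with event counts", {
  p <- synthesize_parameters(6)
  p$costs$crc_treatment[] <- 0  # isolate the screening ledger
  st <- strategy_spec("Combined", fit_uptake = 0.6, tcs_after_fit_uptake = 0.8,
                      primary_tcs_uptake = 0.5)
  out <- run_cohort(small_pop(5000, seed = 14), p, st, seed = 15, keep_person = TRUE)
  ev <- out$events
  expected <- ev$n_fit * p$costs$fit + ev$n_tcs * p$costs$tcs +
    ev$n_polypectomy * p$costs$polypectomy +
    ev$n_perforation * p$costs$perforation_management
  expect_equal(ev$screening_cost_booked_undisc, expected)
  # with treatment zeroed, per-person undiscounted ledgers reconcile too
  expect_equal(sum(out$person$cost_undisc), expected)
})

test_that("uptake-mode persistent yields habitual participants", {
  p <- synthesize_parameters(7)
  st <- strategy_spec("FIT_based", fit_uptake = 0.5, uptake_mode = "persistent")
  out <- run_cohort(small_pop(4000, seed = 16), p, st, seed = 17)
  sti <- strategy_spec("FIT_based", fit_uptake = 0.5)
  outi <- run_cohort(small_pop(4000, seed = 16), p, sti, seed = 17)
  # marginal uptake is the same, so FIT volumes are comparable ...
  expect_lt(abs(out$events$n_fit / outi$events$n_fit - 1), 0.15)
  # ... but persistent participation concentrates tests in fewer people,
  # which shows up as a higher per-attender count; proxy: the persistent
  # mode must differ from the independent mode
  expect_false(out$events$n_fit == outi$events$n_fit &&
                 out$mean_discounted_cost == outi$mean_discounted_cost)
})
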