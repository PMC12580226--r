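test_that("transition distributions are valid for every state, band and sex", {
  p <- synthesize_parameters(2)
  for (age in c(40, 52, 67, 83, 100)) {
    for (sex in c("female", "male")) {
      for (state in crc_states()[1:13]) {
        d <- transition_distribution(state, age, sex, p)
        expect_equal(sum(d), 1, tolerance = 1e-9)
        expect_true(all(d >= 0 & d <= 1))
      }
    }
  }
  expect_error(transition_distribution("DeadOther", 50, "female", p), "absorbing")
  expect_error(transition_distribution("Normal", 39, "female", p), "age")
  expect_error(transition_distribution("Normal", 101, "female", p), "age")
})

test_that("with zero disease the only exit is the life-table hazard", {
  p <- zero_disease_params()
  h <- p$life_table$female[56 - 39]
  d <- transition_distribution("Normal", 56, "female", p)
  expect_equal(unname(d[["Normal"]]), 1 - h)
  expect_equal(unname(d[["DeadOther"]]), h)
  expect_equal(sum(d) - d[["Normal"]] - d[["DeadOther"]], 0)
})

test_that("CRC death competes disease-first with the life table", {
  p <- default_parameters()
  d <- transition_distribution("ClinicalCRC_DukesD", 70, "male", p)
  m <- p$transition[age_band_index(70), 2, 12, 14]
  h <- p$life_table$male[70 - 39]
  expect_equal(unname(d[["DeadCRC"]]), m)
  expect_equal(unname(d[["DeadOther"]]), (1 - m) * h)
  expect_equal(unname(d[["ClinicalCRC_DukesD"]]), (1 - m) * (1 - h))
})

test_that("step_person draws successors at the advertised frequencies", {
  p <- synthesize_parameters(8, "aggressive")
  target <- transition_distribution("PreclinicalCRC_DukesB", 65, "female", p)
  n <- 30000
  set.seed(123)
  succ <- character(n)
  for (i in seq_len(n)) {
    pr <- step_person(new_person(65, "female", "PreclinicalCRC_DukesB"), p)
    succ[i] <- crc_states()[pr$state]
  }
  counts <- table(factor(succ, levels = crc_states()))
  for (s in names(target)[target > 1e-4]) {
    sigma <- sqrt(n * target[[s]] * (1 - target[[s]]))
    expect_lt(abs(counts[[s]] - n * target[[s]]), 3.5 * sigma)
  }
  # determinism under a fixed seed
  set.seed(77); a <- step_person(new_person(50, "male"), p)
  set.seed(77); b <- step_person(new_person(50, "male"), p)
  expect_identical(a, b)
  a$state <- 15L
  expect_error(step_person(a, p), "dead")
})

test_that("disease-free discounted QALYs match the life-table closed form", {
  for (rate in c(0, 0.02)) {
    p <- zero_disease_params(discount = rate)
    pop <- data.frame(age = rep(c(45, 60), each = 50),
                      sex = rep(c("female", "male"), 50),
                      state = "Normal")
    class(pop) <- c("crc_population", class(pop))
    # expected-value engine equals the closed form exactly
    e <- run_cohort_expected(pop, p)
    oracle <- mean(mapply(life_table_qalys, age0 = pop$age, sex = pop$sex,
                          MoreArgs = list(p = p, rate = rate)))
    expect_equal(e$mean_discounted_qalys, oracle, tolerance = 1e-12)
    expect_equal(e$mean_discounted_cost, 0)
    expect_equal(e$crc_cases_per_1e5, 0)
    # microsimulation agrees within Monte-Carlo error
    m <- run_cohort(pop, p, NULL, seed = 4)
    expect_equal(m$mean_discounted_cost, 0)
    expect_lt(abs(m$mean_discounted_qalys - oracle), 4 * m$se$qalys + 1e-12)
  }
})

test_that("constant survival, discount r: QALYs are the geometric sum", {
  p <- constant_hazard_params(h = 0, discount = 0.05)
  p$life_table$female[61] <- 1  # certain death only at the age cap
  p$life_table$male[61] <- 1
  pop <- data.frame(age = rep(40L, 10), sex = "female", state = "Normal")
  class(pop) <- c("crc_population", class(pop))
  e <- run_cohort_expected(pop, p)
  geom <- sum(1 / 1.05^(0:60))  # ages 40..100 inclusive, accrual at cycle start
  expect_equal(e$mean_discounted_qalys, geom, tolerance = 1e-12)
  m <- run_cohort(pop, p, NULL, seed = 1)
  expect_equal(m$mean_discounted_qalys, geom, tolerance = 1e-12)
})

test_that("microsimulation matches the expected-value cohort (module oracle)", {
  p <- synthesize_parameters(21)
  pop <- small_pop(30000, seed = 9)
  m <- run_cohort(pop, p, NULL, seed = 17)
  e <- run_cohort_expected(pop, p)
  expect_lt(abs(m$mean_discounted_cost - e$mean_discounted_cost), 3 * m$se$cost)
  expect_lt(abs(m$mean_discounted_qalys - e$mean_discounted_qalys), 3 * m$se$qalys)
  expect_lt(abs(m$crc_cases_per_1e5 - e$crc_cases_per_1e5), 3 * m$se$cases_per_1e5)
  expect_lt(abs(m$crc_deaths_per_1e5 - e$crc_deaths_per_1e5), 3 * m$se$deaths_per_1e5)
  # the deterministic engine is deterministic
  expect_identical(e, run_cohort_expected(pop, p))
  expect_error(run_cohort_expected(pop, p, strategy_spec("FIT_based")),
               "unsupported strategy")
})

test_that("zero transition probabilities leave occupancy to the life table", {
  p <- zero_disease_params()
  pop <- data.frame(age = 50L, sex = "female", state = "Normal")
  class(pop) <- c("crc_population", class(pop))
  e <- run_cohort_expected(pop, p)
  expect_equal(e$crc_cases_per_1e5, 0)
  expect_equal(e$crc_deaths_per_1e5, 0)
})

test_that("deaths never exceed cases and dead persons accrue nothing", {
  p <- synthesize_parameters(5, "aggressive")
  for (seed in 1:3) {
    m <- run_cohort(small_pop(3000, seed = seed), p, NULL, seed = seed,
                    keep_person = TRUE)
    expect_lte(m$crc_deaths_per_1e5, m$crc_cases_per_1e5)
    expect_true(all(m$person$cost_disc >= 0))
    expect_true(all(m$person$qaly_disc >= 0))
    # a CRC death implies the person was a case
    expect_true(all(!m$person$crc_death | m$person$ever_crc))
  }
})

test_that("raising progression probabilities never lowers lifetime incidence", {
  base <- synthesize_parameters(13)
  bumped <- base
  tr <- bumped$transition
  for (b in 1:10) for (s in 1:2) {
    # increase high-risk polyp -> preclinical CRC conversion by 50%
    row <- tr[b, s, 4, ]
    row[5] <- min(row[5] * 1.5, 0.9)
    row[4] <- 1 - sum(row[-4])
    tr[b, s, 4, ] <- row
  }
  bumped$transition <- tr
  e0 <- run_cohort_expected(small_pop(1000, seed = 2), base)
  e1 <- run_cohort_expected(small_pop(1000, seed = 2), bumped)
  expect_gt(e1$crc_cases_per_1e5, e0$crc_cases_per_1e5)
})
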