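#' Deterministic expected-value cohort evaluation
#'
#' Propagates the state-occupancy distribution cycle-by-cycle instead of
#' simulating individuals, using exactly the same accrual conventions as
#' [run_cohort()] (book at cycle start, no half-cycle correction, death
#' forced at the age cap). There is no random number anywhere, so two
#' calls return identical results; the microsimulation converges to
#' these values as the cohort grows, which makes this engine the
#' variance-free oracle for [run_cohort()].
#'
#' Screening strategies require person-level memory (surveillance
#' schedules, arm assignment) outside the health-state space, so only
#' the natural-history comparator (`strategy = NULL` or kind `"None"`)
#' is supported; anything else is an unsupported-strategy error.
#'
#' @param pop A `crc_population` data frame (its empirical age/sex
#'   counts are used, making it directly comparable to a microsimulation
#'   run on the same sample) or a [population_spec()] (its theoretical
#'   weights are used).
#' @param params A `crc_parameters` object.
#' @param strategy Must be `NULL` or a `"None"` strategy.
#' @param max_age Age cap, as in [run_cohort()].
#' @return A [cohort_outcomes()] object with `se = NULL`.
#' @export
run_cohort_expected <- function(pop, params, strategy = NULL, max_age = 100L) {
  validate_parameters(params)
  if (!is.null(strategy)) {
    strategy <- validate_strategy(strategy)
    if (strategy$kind != "None") {
      stop("unsupported strategy: the expected-value cohort supports only the ",
           "no-screening comparator (screening needs person-level memory ",
           "outside the state space)", call. = FALSE)
    }
  }

  if (inherits(pop, "crc_population_spec")) {
    ages <- as.integer(names(pop$age_weights))
    w <- outer(pop$age_weights, pop$sex_weights)
    groups <- data.frame(age = rep(ages, 2L),
                         sex = rep(1:2, each = length(ages)),
                         weight = c(w[, "female"], w[, "male"]))
    n_total <- pop$n_individuals
  } else {
    if (nrow(pop) == 0L) stop("empty population", call. = FALSE)
    tab <- table(age = pop$age, sex = sex_code(pop$sex))
    groups <- as.data.frame(tab, stringsAsFactors = FALSE)
    groups$weight <- groups$Freq / nrow(pop)
    groups$age <- as.integer(as.character(groups$age))
    groups$sex <- as.integer(as.character(groups$sex))
    groups <- groups[groups$Freq > 0, c("age", "sex", "weight")]
    n_total <- nrow(pop)
  }
  groups$weight <- groups$weight / sum(groups$weight)

  rate <- params$econ$discount_rate
  util_vec <- c(params$utilities$states[crc_states()[.LIVE]], 0, 0)
  treat_vec <- numeric(.N_STATES)
  treat_vec[.CLINICAL] <- params$costs$crc_treatment[c("a", "b", "c", "d")]
  treat_vec[.S$clin_d] <- treat_vec[.S$clin_d] * params$costs$dukes_d_multiplier
  comp <- build_composed_transitions(params)

  tot_cost <- 0; tot_qaly <- 0; tot_cases <- 0; tot_deaths <- 0
  for (g in seq_len(nrow(groups))) {
    age0 <- groups$age[g]; sx <- groups$sex[g]; w <- groups$weight[g]
    occ <- numeric(.N_STATES); occ[.S$normal] <- 1
    cost <- 0; qaly <- 0; cases <- 0; deaths <- 0
    t <- 0L; age <- age0
    repeat {
      d <- 1 / (1 + rate)^t
      qaly <- qaly + sum(occ[.LIVE] * util_vec[.LIVE]) * d
      cost <- cost + sum(occ[.CLINICAL] * treat_vec[.CLINICAL]) * d
      if (age >= max_age) {
        # cap: survivors die of other causes after this year's accrual
        break
      }
      idx <- composed_row_index(age, sx, .LIVE, comp$n_age)
      M <- comp$prob[idx, , drop = FALSE]   # 13 x 15
      from_occ <- occ[.LIVE]
      inflow <- from_occ %*% M              # 1 x 15
      non_clin <- setdiff(.LIVE, .CLINICAL)
      cases <- cases + sum(occ[non_clin] * M[match(non_clin, .LIVE), .CLINICAL])
      deaths <- deaths + inflow[1, .S$dead_crc]  # flow from live states only
      new_occ <- as.numeric(inflow)
      new_occ[.DEAD] <- new_occ[.DEAD] + occ[.DEAD]  # carry accumulated dead mass
      occ <- new_occ
      t <- t + 1L; age <- age + 1L
      if (sum(occ[.LIVE]) < 1e-14) break
    }
    tot_cost <- tot_cost + w * cost
    tot_qaly <- tot_qaly + w * qaly
    tot_cases <- tot_cases + w * cases
    tot_deaths <- tot_deaths + w * deaths
  }

  cohort_outcomes(mean_discounted_cost = tot_cost,
                  mean_discounted_qalys = tot_qaly,
                  crc_cases_per_1e5 = tot_cases * 1e5,
                  crc_deaths_per_1e5 = tot_deaths * 1e5,
                  n = n_total, se = NULL, events = NULL)
}
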