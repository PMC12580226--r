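#' Cohort outcome summaries
#'
#' Container for per-person mean discounted cost and QALYs plus lifetime
#' CRC incidence and mortality per 100,000 persons. Monte-Carlo standard
#' errors are attached when the outcomes come from the microsimulation;
#' the deterministic expected-value engine reports `NA` errors.
#'
#' @param mean_discounted_cost Mean discounted lifetime cost, JPY/person.
#' @param mean_discounted_qalys Mean discounted QALYs/person.
#' @param crc_cases_per_1e5,crc_deaths_per_1e5 Lifetime counts per 1e5.
#' @param n Cohort size.
#' @param se Optional named list of standard errors.
#' @param events Optional named counts of screening events.
#' @return A `crc_outcomes` object.
#' @export
cohort_outcomes <- function(mean_discounted_cost, mean_discounted_qalys,
                            crc_cases_per_1e5 = NA_real_,
                            crc_deaths_per_1e5 = NA_real_,
                            n = NA_integer_, se = NULL, events = NULL) {
  if (!is.na(crc_cases_per_1e5) && !is.na(crc_deaths_per_1e5) &&
      crc_deaths_per_1e5 > crc_cases_per_1e5 + 1e-9) {
    stop("CRC deaths per 1e5 cannot exceed CRC cases per 1e5", call. = FALSE)
  }
  structure(list(mean_discounted_cost = mean_discounted_cost,
                 mean_discounted_qalys = mean_discounted_qalys,
                 crc_cases_per_1e5 = crc_cases_per_1e5,
                 crc_deaths_per_1e5 = crc_deaths_per_1e5,
                 n = n, se = se, events = events),
            class = "crc_outcomes")
}

#' @export
print.crc_outcomes <- function(x, ...) {
  cat("<crc_outcomes> n =", format(x$n, big.mark = ","), "\n")
  cat(sprintf("  Cost (per person):            %s JPY\n",
              format(round(x$mean_discounted_cost), big.mark = ",")))
  cat(sprintf("  QALYs (per person):           %.4f\n", x$mean_discounted_qalys))
  cat(sprintf("  CRC cases (per 10^5 persons): %s\n",
              format(round(x$crc_cases_per_1e5), big.mark = ",")))
  cat(sprintf("  CRC death (per 10^5 persons): %s\n",
              format(round(x$crc_deaths_per_1e5), big.mark = ",")))
  invisible(x)
}

#' Run the microsimulation over a cohort
#'
#' Advances every person through 1-year cycles from their starting age
#' to death (other-cause death is forced at the maximum age cap),
#' overlaying a screening strategy when one is given. Costs and QALYs
#' are booked at cycle start with that cycle's discount factor (no
#' half-cycle correction); persons in a clinical CRC state accrue the
#' stage's annual treatment cost (Dukes D times the scenario
#' multiplier) and stage utility.
#'
#' Randomness is split over two independent streams derived from
#' `seed`: one for disease transitions, one for screening (uptake, test
#' results, complications). Because the disease stream is consumed
#' identically whatever the strategy, runs with the same seed use common
#' random numbers: strategy comparisons are paired person-by-person, and
#' a strategy with all uptake rates 0 reproduces the no-screening
#' comparator exactly.
#'
#' @param pop A `crc_population` data frame from [sample_population()],
#'   or a [population_spec()] (sampled with its own seed).
#' @param params A `crc_parameters` object.
#' @param strategy A [strategy_spec()], or `NULL` for pure natural
#'   history (the no-screening comparator).
#' @param seed Integer seed for the simulation streams.
#' @param max_age Maximum simulated age; survivors die of other causes
#'   after accruing that year (default 100).
#' @param keep_person If `TRUE`, attach a per-person data frame of
#'   discounted cost, QALYs and CRC flags (used for paired comparisons
#'   under common random numbers).
#' @return A [cohort_outcomes()] object with Monte-Carlo standard
#'   errors and screening-event counts.
#' @export
run_cohort <- function(pop, params, strategy = NULL, seed = 1L,
                       max_age = 100L, keep_person = FALSE) {
  validate_parameters(params)
  if (inherits(pop, "crc_population_spec")) pop <- sample_population(pop)
  n <- nrow(pop)
  if (is.null(n) || n == 0L) stop("empty population", call. = FALSE)
  if (!is.null(strategy)) {
    strategy <- validate_strategy(strategy)
    if (strategy$kind == "None") strategy <- NULL
  }

  P <- new.env(parent = emptyenv())
  P$n <- n
  P$age <- as.integer(pop$age)
  P$sex <- sex_code(pop$sex)
  P$state <- state_code(pop$state %||% "Normal")
  P$surv_due <- rep(NA_integer_, n)
  P$arm <- rep(NA_integer_, n)
  P$pend_dis <- numeric(n)
  P$cost_disc <- numeric(n)
  P$cost_undisc <- numeric(n)
  P$qaly_disc <- numeric(n)
  P$ever_crc <- state_code(P$state) %in% .CLINICAL
  P$crc_death <- rep(FALSE, n)
  P$u_persist <- NULL

  counters <- new.env(parent = emptyenv())
  counters$n_fit <- 0L; counters$n_tcs <- 0L
  counters$n_polypectomy <- 0L; counters$n_perforation <- 0L
  counters$n_surv_offered <- 0L; counters$n_surv_attended <- 0L
  counters$screen_cost_booked_undisc <- 0

  streams <- rng_streams(seed)
  if (!is.null(strategy)) {
    if (strategy$kind == "Combined") {
      P$arm <- 1L + (stream_runif(streams, "screen", n) >= strategy$combined_fit_fraction)
    }
    if (strategy$uptake_mode == "persistent") {
      P$u_persist <- stream_runif(streams, "screen", n)
    }
  }

  rate <- params$econ$discount_rate
  util_vec <- c(params$utilities$states[crc_states()[.LIVE]], 0, 0)
  treat_vec <- numeric(.N_STATES)
  treat_vec[.CLINICAL] <- params$costs$crc_treatment[c("a", "b", "c", "d")]
  treat_vec[.S$clin_d] <- treat_vec[.S$clin_d] * params$costs$dukes_d_multiplier
  comp <- build_composed_transitions(params)

  t <- 0L
  repeat {
    alive <- which(P$state <= 13L)
    if (length(alive) == 0L) break
    d <- 1 / (1 + rate)^t

    if (!is.null(strategy)) {
      draws <- list(u_uptake = stream_runif(streams, "screen", n),
                    u_fit = stream_runif(streams, "screen", n),
                    u_followup = stream_runif(streams, "screen", n),
                    u_detect = stream_runif(streams, "screen", n),
                    u_perf = stream_runif(streams, "screen", n))
      screen_cycle_impl(P, strategy, params, d, t, draws, counters)
      alive <- which(P$state <= 13L)
    }

    # accrual at cycle start (screening-adjusted state)
    st_a <- P$state[alive]
    P$qaly_disc[alive] <- P$qaly_disc[alive] +
      pmax(util_vec[st_a] - P$pend_dis[alive], 0) * d
    P$pend_dis[alive] <- 0
    tc <- treat_vec[st_a]
    P$cost_disc[alive] <- P$cost_disc[alive] + tc * d
    P$cost_undisc[alive] <- P$cost_undisc[alive] + tc

    # transition (one uniform per person per cycle keeps streams aligned)
    u <- stream_runif(streams, "nh", n)
    capped <- alive[P$age[alive] >= max_age]
    mover <- setdiff(alive, capped)
    if (length(mover) > 0) {
      idx <- composed_row_index(P$age[mover], P$sex[mover], P$state[mover], comp$n_age)
      succ <- 1L + as.integer(rowSums(u[mover] > comp$cum[idx, , drop = FALSE]))
      P$ever_crc[mover] <- P$ever_crc[mover] | succ %in% .CLINICAL
      P$crc_death[mover] <- P$crc_death[mover] | succ == .S$dead_crc
      P$state[mover] <- succ
    }
    if (length(capped) > 0) P$state[capped] <- .S$dead_other
    P$age[alive] <- P$age[alive] + 1L
    t <- t + 1L
  }

  p_case <- mean(P$ever_crc)
  p_death <- mean(P$crc_death)
  out <- cohort_outcomes(
    mean_discounted_cost = mean(P$cost_disc),
    mean_discounted_qalys = mean(P$qaly_disc),
    crc_cases_per_1e5 = p_case * 1e5,
    crc_deaths_per_1e5 = p_death * 1e5,
    n = n,
    se = list(cost = stats::sd(P$cost_disc) / sqrt(n),
              qalys = stats::sd(P$qaly_disc) / sqrt(n),
              cases_per_1e5 = sqrt(p_case * (1 - p_case) / n) * 1e5,
              deaths_per_1e5 = sqrt(p_death * (1 - p_death) / n) * 1e5),
    events = list(n_fit = counters$n_fit, n_tcs = counters$n_tcs,
                  n_polypectomy = counters$n_polypectomy,
                  n_perforation = counters$n_perforation,
                  n_surveillance_offered = counters$n_surv_offered,
                  n_surveillance_attended = counters$n_surv_attended,
                  screening_cost_booked_undisc = counters$screen_cost_booked_undisc)
  )
  if (keep_person) {
    out$person <- data.frame(cost_disc = P$cost_disc, cost_undisc = P$cost_undisc,
                             qaly_disc = P$qaly_disc,
                             ever_crc = P$ever_crc, crc_death = P$crc_death)
  }
  out
}

#' Construct a single simulated person
#'
#' Mostly useful for unit-level work with [step_person()] and
#' [apply_screening_cycle()]; [run_cohort()] manages whole cohorts
#' internally.
#'
#' @param age Starting age (years). @param sex `"female"` or `"male"`.
#' @param state Starting health state label (default `"Normal"`).
#' @return A `crc_person` list with zeroed ledgers at cycle 0.
#' @export
new_person <- function(age, sex, state = "Normal") {
  stopifnot(age >= 40, age <= 100)
  structure(list(age = as.integer(age), sex = .SEXES[sex_code(sex)],
                 state = state_code(state), year = 0L,
                 surveillance_due_year = NA_integer_,
                 cost_undisc = 0, cost_disc = 0, qaly_disc = 0,
                 pending_disutility = 0,
                 ever_crc = state_code(state) %in% .CLINICAL,
                 crc_death = FALSE),
            class = "crc_person")
}

#' Advance one person through one natural-history cycle
#'
#' Books the cycle's utility and any clinical CRC treatment cost with
#' the current discount factor, draws the successor state from
#' [transition_distribution()] using the session RNG (seed it with
#' `set.seed()` for reproducibility), and increments age and cycle
#' counter. Screening is applied separately by
#' [apply_screening_cycle()] before stepping.
#'
#' @param person A `crc_person` (alive).
#' @param p A `crc_parameters` object.
#' @param max_age Age cap, as in [run_cohort()].
#' @return The updated `crc_person`.
#' @export
step_person <- function(person, p, max_age = 100L) {
  if (person$state %in% .DEAD) stop("person is dead; step_person requires a live person", call. = FALSE)
  d <- 1 / (1 + p$econ$discount_rate)^person$year
  util <- p$utilities$states[[crc_states()[person$state]]]
  person$qaly_disc <- person$qaly_disc + max(util - person$pending_disutility, 0) * d
  person$pending_disutility <- 0
  if (person$state %in% .CLINICAL) {
    tc <- p$costs$crc_treatment[[c("a", "b", "c", "d")[person$state - 8L]]]
    if (person$state == .S$clin_d) tc <- tc * p$costs$dukes_d_multiplier
    person$cost_disc <- person$cost_disc + tc * d
    person$cost_undisc <- person$cost_undisc + tc
  }
  if (person$age >= max_age) {
    person$state <- .S$dead_other
  } else {
    pr <- transition_distribution(person$state, person$age,
                                  person$sex, p)
    succ <- 1L + sum(stats::runif(1) > cumsum(pr))
    person$ever_crc <- person$ever_crc || succ %in% .CLINICAL
    person$crc_death <- person$crc_death || succ == .S$dead_crc
    person$state <- succ
  }
  person$age <- person$age + 1L
  person$year <- person$year + 1L
  person
}
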