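#' Define a screening strategy
#'
#' Three strategy families are supported, mirroring the usual design of
#' organized CRC screening programs:
#'
#' * `"FIT_based"` — an annual (configurable) fecal immunochemical test
#'   is offered within the screening age range; FIT-positives are
#'   referred to total colonoscopy in the same cycle and attend it with
#'   `tcs_after_fit_uptake`.
#' * `"TCS_based"` — primary screening colonoscopy offered every
#'   `tcs_interval` years (default 10).
#' * `"Combined"` — a one-time, lifelong split of the population:
#'   a fraction `combined_fit_fraction` (default 0.80) follows the
#'   FIT-based program, the rest the TCS-based program.
#' * `"None"` — no screening (the natural-history comparator).
#'
#' Polyps detected at any colonoscopy are resected; the person enters
#' post-polypectomy surveillance with the interval given by
#' `surveillance_intervals` ([surveillance_next_due()]), attended with
#' `surveillance_uptake` (default 0.70). Surveillance supersedes routine
#' screening, and a person diagnosed with CRC exits screening.
#'
#' Uptake draws are independent across rounds by default;
#' `uptake_mode = "persistent"` instead gives each person a fixed latent
#' propensity so the same marginal uptake splits the cohort into
#' habitual participants and never-participants.
#'
#' @param kind Strategy family (see above).
#' @param fit_uptake Probability of attending an offered FIT.
#' @param tcs_after_fit_uptake Probability of attending colonoscopy
#'   after a positive FIT (same cycle).
#' @param primary_tcs_uptake Probability of attending an offered
#'   primary screening colonoscopy.
#' @param surveillance_uptake Probability of attending a scheduled
#'   surveillance colonoscopy (default 0.70).
#' @param fit_interval,tcs_interval Offer intervals in years (offers are
#'   anchored to the simulation start: everyone is invited in the same
#'   calendar rounds).
#' @param combined_fit_fraction Fraction assigned to the FIT arm under
#'   `"Combined"`.
#' @param screening_age_range Two ages `[start, stop]`, offers made
#'   inclusive of both ends (default `c(40, 74)`).
#' @param surveillance_intervals Named years-to-next-surveillance per
#'   resected lesion class (`lr_small`, `lr_medium`, `hr`).
#' @param surveillance_age_max Last age at which surveillance is still
#'   offered (default 84).
#' @param uptake_mode `"independent"` (default) or `"persistent"`.
#' @return A validated `crc_strategy` list.
#' @export
#' @examples
#' strategy_spec("FIT_based", fit_uptake = 0.4, tcs_after_fit_uptake = 0.7)
strategy_spec <- function(kind = c("FIT_based", "TCS_based", "Combined", "None"),
                          fit_uptake = 0.40,
                          tcs_after_fit_uptake = 0.70,
                          primary_tcs_uptake = 0.20,
                          surveillance_uptake = 0.70,
                          fit_interval = 1L,
                          tcs_interval = 10L,
                          combined_fit_fraction = 0.80,
                          screening_age_range = c(40L, 74L),
                          surveillance_intervals = c(lr_small = 5, lr_medium = 5, hr = 3),
                          surveillance_age_max = 84L,
                          uptake_mode = c("independent", "persistent")) {
  s <- list(kind = match.arg(kind),
            fit_uptake = fit_uptake,
            tcs_after_fit_uptake = tcs_after_fit_uptake,
            primary_tcs_uptake = primary_tcs_uptake,
            surveillance_uptake = surveillance_uptake,
            fit_interval = as.integer(fit_interval),
            tcs_interval = as.integer(tcs_interval),
            combined_fit_fraction = combined_fit_fraction,
            screening_age_range = as.integer(screening_age_range),
            surveillance_intervals = surveillance_intervals,
            surveillance_age_max = as.integer(surveillance_age_max),
            uptake_mode = match.arg(uptake_mode))
  class(s) <- "crc_strategy"
  validate_strategy(s)
}

validate_strategy <- function(s) {
  if (!inherits(s, "crc_strategy")) stop("not a crc_strategy object", call. = FALSE)
  for (nm in c("fit_uptake", "tcs_after_fit_uptake", "primary_tcs_uptake",
               "surveillance_uptake", "combined_fit_fraction")) {
    stopifnot_scalar_prob(s[[nm]], nm)
  }
  if (s$fit_interval < 1L || s$tcs_interval < 1L) {
    stop("screening intervals must be >= 1 year", call. = FALSE)
  }
  if (length(s$screening_age_range) != 2L ||
      s$screening_age_range[1] > s$screening_age_range[2]) {
    stop("screening_age_range must be [start, stop] with start <= stop", call. = FALSE)
  }
  if (!all(c("lr_small", "lr_medium", "hr") %in% names(s$surveillance_intervals)) ||
      any(s$surveillance_intervals < 1)) {
    stop("surveillance_intervals must give >= 1 year for lr_small, lr_medium, hr",
         call. = FALSE)
  }
  s
}

#' Years until the next surveillance colonoscopy
#'
#' Looks up the guideline interval for the most advanced lesion class
#' removed at a colonoscopy. With no findings, no surveillance is
#' scheduled (routine screening resumes) and `NA` is returned.
#'
#' @param findings Character vector of resected lesion classes
#'   (`"lr_small"`, `"lr_medium"`, `"hr"`); may be empty.
#' @param intervals Guideline table, as in [strategy_spec()].
#' @return Years until the next surveillance TCS, or `NA` if none.
#' @export
surveillance_next_due <- function(findings,
                                  intervals = c(lr_small = 5, lr_medium = 5, hr = 3)) {
  if (length(findings) == 0) return(NA_real_)
  unknown <- setdiff(findings, names(intervals))
  if (length(unknown) > 0) {
    stop("no surveillance interval configured for lesion class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  min(intervals[findings])
}

#' Which screening offer (if any) does a person receive this year?
#'
#' Deterministic given the person's history: persons with diagnosed CRC
#' exit screening; due surveillance supersedes routine offers (and is
#' offered up to `surveillance_age_max`); otherwise the routine modality
#' of the strategy arm is offered in its scheduled rounds within the
#' screening age range. A person never receives two offers in one cycle.
#'
#' @param person A `crc_person` from [new_person()] (alive).
#' @param strategy A [strategy_spec()].
#' @param year Simulation year (cycle index, 0-based).
#' @param arm For `"Combined"`, the person's arm from
#'   [assign_combined_arm()] (`"FIT_arm"` or `"TCS_arm"`).
#' @return One of `"FIT"`, `"TCS_primary"`, `"TCS_surveillance"`, or
#'   `"none"`.
#' @export
plan_offer <- function(person, strategy, year, arm = NULL) {
  strategy <- validate_strategy(strategy)
  if (person$state %in% .DEAD) stop("plan_offer requires a live person", call. = FALSE)
  if (strategy$kind == "None") return("none")
  if (person$state %in% .CLINICAL) return("none")
  if (!is.na(person$surveillance_due_year) &&
      year >= person$surveillance_due_year &&
      person$age <= strategy$surveillance_age_max) {
    return("TCS_surveillance")
  }
  rng_age <- strategy$screening_age_range
  if (person$age < rng_age[1] || person$age > rng_age[2]) return("none")
  modality <- switch(strategy$kind,
                     FIT_based = "FIT",
                     TCS_based = "TCS_primary",
                     Combined = {
                       if (is.null(arm)) stop("Combined strategy needs the person's arm", call. = FALSE)
                       if (arm == "FIT_arm") "FIT" else "TCS_primary"
                     })
  interval <- if (modality == "FIT") strategy$fit_interval else strategy$tcs_interval
  if (year %% interval == 0L) modality else "none"
}

#' Assign (once) a person's arm under the combined strategy
#'
#' A Bernoulli(`combined_fit_fraction`) draw made once per person and
#' cached for life: the population split is persistent, not re-drawn per
#' round. Calling again returns the cached arm.
#'
#' @param person A `crc_person`; the arm is cached in `person$arm`.
#' @param strategy A [strategy_spec()] with `kind = "Combined"`.
#' @return The updated person, with `person$arm` set to `"FIT_arm"` or
#'   `"TCS_arm"`.
#' @export
assign_combined_arm <- function(person, strategy) {
  strategy <- validate_strategy(strategy)
  if (strategy$kind != "Combined") stop("strategy is not Combined", call. = FALSE)
  if (!is.null(person$arm)) return(person)
  person$arm <- if (stats::runif(1) < strategy$combined_fit_fraction) "FIT_arm" else "TCS_arm"
  person
}

#' Perform a FIT for one attending person
#'
#' The test is positive with the FIT sensitivity of the person's lesion
#' class, or with one minus specificity when there is no lesion
#' (Normal / post-polypectomy). Books the FIT cost at the cycle's
#' discount factor. Result randomness comes from the session RNG.
#'
#' @param person Attending `crc_person` (uptake draw already passed; not
#'   in a clinical CRC state).
#' @param p A `crc_parameters` object.
#' @return List `(person, event)`; `event` holds `modality`,
#'   `attended`, `result` (`"positive"`/`"negative"`), `complication`
#'   and `cost_booked`.
#' @export
perform_fit <- function(person, p) {
  if (person$state %in% .CLINICAL) stop("clinical CRC is excluded from screening upstream", call. = FALSE)
  d <- 1 / (1 + p$econ$discount_rate)^person$year
  cls <- lesion_class_of_state(person$state)
  p_pos <- if (is.na(cls)) 1 - p$test_chars$fit_specificity else p$test_chars$fit_sensitivity[[cls]]
  positive <- stats::runif(1) < p_pos
  person$cost_disc <- person$cost_disc + p$costs$fit * d
  person$cost_undisc <- person$cost_undisc + p$costs$fit
  list(person = person,
       event = list(year = person$year, modality = "FIT", attended = TRUE,
                    result = if (positive) "positive" else "negative",
                    complication = FALSE, cost_booked = p$costs$fit * d))
}

#' Perform a colonoscopy for one attending person
#'
#' Detects the person's lesion (if any) with the colonoscopy sensitivity
#' of its class. Detected polyps are resected: the person moves to the
#' post-polypectomy state and surveillance is scheduled per
#' [surveillance_next_due()]. Detected preclinical CRC becomes clinical
#' CRC at the same Dukes stage (treatment costs begin from the current
#' cycle's accrual). Perforation occurs with the configured probability,
#' booking its management cost and any configured one-off disutility.
#' The colonoscopy cost (plus polypectomy cost on resection) is booked
#' at the cycle's discount factor.
#'
#' @param person Attending `crc_person`.
#' @param p A `crc_parameters` object.
#' @param strategy A [strategy_spec()] (for the surveillance table).
#' @param context `"primary"`, `"followup"` or `"surveillance"`.
#' @return List `(person, event)` as in [perform_fit()]; `event$result`
#'   is `"negative"` or the detected lesion class.
#' @export
perform_tcs <- function(person, p, strategy,
                        context = c("primary", "followup", "surveillance")) {
  context <- match.arg(context)
  strategy <- validate_strategy(strategy)
  d <- 1 / (1 + p$econ$discount_rate)^person$year
  cost <- p$costs$tcs
  cls <- lesion_class_of_state(person$state)
  result <- "negative"
  if (!is.na(cls) && stats::runif(1) < p$test_chars$tcs_sensitivity[[cls]]) {
    result <- cls
    if (person$state %in% c(.S$lr_small, .S$lr_medium, .S$hr)) {
      cost <- cost + p$costs$polypectomy
      person$state <- .S$post_polyp
      person$surveillance_due_year <- person$year +
        as.integer(surveillance_next_due(cls, strategy$surveillance_intervals))
    } else {
      person$state <- person$state + 4L  # preclinical -> clinical, same stage
      person$ever_crc <- TRUE
      person$surveillance_due_year <- NA_integer_
    }
  }
  complication <- stats::runif(1) < p$test_chars$tcs_perforation_prob
  if (complication) {
    cost <- cost + p$costs$perforation_management
    person$pending_disutility <- person$pending_disutility +
      p$utilities$perforation_disutility
  }
  person$cost_disc <- person$cost_disc + cost * d
  person$cost_undisc <- person$cost_undisc + cost
  list(person = person,
       event = list(year = person$year, modality = paste0("TCS_", context),
                    attended = TRUE, result = result,
                    complication = complication, cost_booked = cost * d))
}

#' Apply one full screening cycle to one person
#'
#' Composes [plan_offer()], the uptake Bernoulli draw for the offered
#' modality, the test realization, and the same-cycle follow-up chain
#' (a positive FIT leads to colonoscopy attended with
#' `tcs_after_fit_uptake`; non-attenders simply return to the routine
#' schedule next round). Surveillance that falls due this year is
#' offered once: attended or not, the person afterwards returns to the
#' routine schedule unless new findings reschedule surveillance.
#'
#' @inheritParams plan_offer
#' @param p A `crc_parameters` object.
#' @return The updated `crc_person`.
#' @export
apply_screening_cycle <- function(person, strategy, p, year, arm = NULL) {
  strategy <- validate_strategy(strategy)
  if (strategy$kind == "Combined" && is.null(arm)) {
    person <- assign_combined_arm(person, strategy)
    arm <- person$arm
  }
  offer <- plan_offer(person, strategy, year, arm = arm)
  if (!is.na(person$surveillance_due_year) && year >= person$surveillance_due_year) {
    person$surveillance_due_year <- NA_integer_  # one offer per scheduled event
  }
  if (offer == "none") return(person)
  uptake <- switch(offer,
                   FIT = strategy$fit_uptake,
                   TCS_primary = strategy$primary_tcs_uptake,
                   TCS_surveillance = strategy$surveillance_uptake)
  if (stats::runif(1) >= uptake) return(person)
  if (offer == "FIT") {
    res <- perform_fit(person, p)
    person <- res$person
    if (res$event$result == "positive" &&
        stats::runif(1) < strategy$tcs_after_fit_uptake) {
      person <- perform_tcs(person, p, strategy, "followup")$person
    }
  } else {
    context <- if (offer == "TCS_primary") "primary" else "surveillance"
    person <- perform_tcs(person, p, strategy, context)$person
  }
  person
}

# ---- vectorized engine used by run_cohort() -------------------------------
# One cycle of screening for the whole cohort. P is the mutable person
# environment; draws are the five pre-drawn uniform vectors of the
# screening stream (fixed layout per cycle, so random-number consumption
# is identical across strategies: common random numbers).
screen_cycle_impl <- function(P, strategy, p, d, t, draws, counters) {
  alive <- P$state <= 13L
  eligible <- alive & !(P$state %in% .CLINICAL)

  # surveillance due supersedes routine screening
  surv_due <- eligible & !is.na(P$surv_due) & t >= P$surv_due &
    P$age <= strategy$surveillance_age_max
  # each scheduled event is offered once; afterwards routine resumes
  clear <- !is.na(P$surv_due) & t >= P$surv_due
  P$surv_due[clear] <- NA_integer_

  in_range <- eligible & !surv_due &
    P$age >= strategy$screening_age_range[1] &
    P$age <= strategy$screening_age_range[2]
  fit_arm <- switch(strategy$kind,
                    FIT_based = in_range,
                    TCS_based = rep(FALSE, P$n),
                    Combined = in_range & P$arm == 1L)
  tcs_arm <- switch(strategy$kind,
                    FIT_based = rep(FALSE, P$n),
                    TCS_based = in_range,
                    Combined = in_range & P$arm == 2L)
  offer_fit <- fit_arm & (t %% strategy$fit_interval == 0L)
  offer_tcs <- tcs_arm & (t %% strategy$tcs_interval == 0L)

  u_up <- if (strategy$uptake_mode == "persistent") {
    ifelse(surv_due, draws$u_uptake, P$u_persist)  # surveillance stays per-event
  } else draws$u_uptake

  attend_fit <- offer_fit & u_up < strategy$fit_uptake
  attend_tcs_primary <- offer_tcs & u_up < strategy$primary_tcs_uptake
  attend_surv <- surv_due & u_up < strategy$surveillance_uptake

  counters$n_surv_offered <- counters$n_surv_offered + sum(surv_due)
  counters$n_surv_attended <- counters$n_surv_attended + sum(attend_surv)

  # FIT realization
  if (any(attend_fit)) {
    idx <- which(attend_fit)
    counters$n_fit <- counters$n_fit + length(idx)
    counters$screen_cost_booked_undisc <- counters$screen_cost_booked_undisc +
      length(idx) * p$costs$fit
    P$cost_disc[idx] <- P$cost_disc[idx] + p$costs$fit * d
    P$cost_undisc[idx] <- P$cost_undisc[idx] + p$costs$fit
    cls <- lesion_class_of_state(P$state[idx])
    p_pos <- rep(1 - p$test_chars$fit_specificity, length(idx))
    has <- !is.na(cls)
    p_pos[has] <- p$test_chars$fit_sensitivity[match(cls[has], names(p$test_chars$fit_sensitivity))]
    positive <- draws$u_fit[idx] < p_pos
    followup <- idx[positive & draws$u_followup[idx] < strategy$tcs_after_fit_uptake]
  } else {
    followup <- integer(0)
  }

  tcs_idx <- c(which(attend_tcs_primary), followup, which(attend_surv))
  if (length(tcs_idx) > 0) {
    counters$n_tcs <- counters$n_tcs + length(tcs_idx)
    counters$screen_cost_booked_undisc <- counters$screen_cost_booked_undisc +
      length(tcs_idx) * p$costs$tcs
    P$cost_disc[tcs_idx] <- P$cost_disc[tcs_idx] + p$costs$tcs * d
    P$cost_undisc[tcs_idx] <- P$cost_undisc[tcs_idx] + p$costs$tcs

    st <- P$state[tcs_idx]
    cls <- lesion_class_of_state(st)
    sens <- rep(0, length(tcs_idx))
    has <- !is.na(cls)
    sens[has] <- p$test_chars$tcs_sensitivity[match(cls[has], names(p$test_chars$tcs_sensitivity))]
    detected <- draws$u_detect[tcs_idx] < sens

    polyp <- detected & st %in% c(.S$lr_small, .S$lr_medium, .S$hr)
    if (any(polyp)) {
      pi <- tcs_idx[polyp]
      counters$n_polypectomy <- counters$n_polypectomy + length(pi)
      counters$screen_cost_booked_undisc <- counters$screen_cost_booked_undisc +
        length(pi) * p$costs$polypectomy
      P$cost_disc[pi] <- P$cost_disc[pi] + p$costs$polypectomy * d
      P$cost_undisc[pi] <- P$cost_undisc[pi] + p$costs$polypectomy
      iv <- strategy$surveillance_intervals[cls[polyp]]
      P$surv_due[pi] <- t + as.integer(iv)
      P$state[pi] <- .S$post_polyp
    }
    crc_found <- detected & st %in% .PRECLIN
    if (any(crc_found)) {
      ci <- tcs_idx[crc_found]
      P$state[ci] <- P$state[ci] + 4L  # same Dukes stage, now clinical
      P$ever_crc[ci] <- TRUE
      P$surv_due[ci] <- NA_integer_
    }

    perf <- draws$u_perf[tcs_idx] < p$test_chars$tcs_perforation_prob
    if (any(perf)) {
      pfi <- tcs_idx[perf]
      counters$n_perforation <- counters$n_perforation + length(pfi)
      counters$screen_cost_booked_undisc <- counters$screen_cost_booked_undisc +
        length(pfi) * p$costs$perforation_management
      P$cost_disc[pfi] <- P$cost_disc[pfi] + p$costs$perforation_management * d
      P$cost_undisc[pfi] <- P$cost_undisc[pfi] + p$costs$perforation_management
      P$pend_dis[pfi] <- P$pend_dis[pfi] + p$utilities$perforation_disutility
    }
  }
  invisible(NULL)
}
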