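#' Configure a probabilistic sensitivity analysis
#'
#' Parameter uncertainty follows the usual convention for decision
#' models: probabilities backed by numerator/denominator data (test
#' sensitivities and specificity, colonoscopy perforation, the
#' post-polypectomy new-adenoma probability) get beta distributions;
#' the remaining quantities (costs, the other disease-transition
#' probabilities) get gamma distributions. Each distribution is
#' moment-matched so its mean equals the base value and the interval
#' base +/- `range_fraction` * base spans mean +/- 2 standard deviations
#' (i.e. sd = base * range_fraction / 2). A hard-bound alternative —
#' a scaled symmetric beta supported exactly on that interval — is
#' available via `bound_mode = "hard"`.
#'
#' @param n_draws Number of Monte Carlo parameter draws (default 2000).
#' @param range_fraction Relative uncertainty half-range (default 0.25).
#' @param n_individuals_per_draw Cohort size simulated per draw
#'   (default 20000).
#' @param seed Seed for the PSA parameter stream.
#' @param bound_mode `"moment"` (default) or `"hard"` (see above).
#' @param redraw_person_streams If `TRUE` (default) each draw simulates
#'   with a fresh person-level seed; if `FALSE`, every draw reuses the
#'   same person-level streams so only parameter uncertainty varies.
#' @param perturb Which blocks to perturb: any of `"test_chars"`,
#'   `"costs"`, `"transition"`.
#' @return A `crc_psa_config` list.
#' @export
psa_config <- function(n_draws = 2000L, range_fraction = 0.25,
                       n_individuals_per_draw = 20000L, seed = 1L,
                       bound_mode = c("moment", "hard"),
                       redraw_person_streams = TRUE,
                       perturb = c("test_chars", "costs", "transition")) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (range_fraction <= 0 || range_fraction >= 1) {
    stop("range_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(n_draws = as.integer(n_draws),
                 range_fraction = range_fraction,
                 n_individuals_per_draw = as.integer(n_individuals_per_draw),
                 seed = as.integer(seed),
                 bound_mode = match.arg(bound_mode),
                 redraw_person_streams = isTRUE(redraw_person_streams),
                 perturb = match.arg(perturb, several.ok = TRUE)),
            class = "crc_psa_config")
}

#' Draw one uncertain parameter value
#'
#' @param base Base-case value (> 0; beta additionally requires
#'   `base < 1`).
#' @param family `"beta"` or `"gamma"`.
#' @param range_fraction Relative half-range; sd = base * range_fraction / 2.
#' @param n Number of draws.
#' @param bound_mode `"moment"` (moment-matched beta/gamma) or `"hard"`
#'   (scaled symmetric beta on `[base * (1 - rf), base * (1 + rf)]`).
#' @return Numeric vector of `n` draws with mean `base`; beta draws lie
#'   in (0, 1), gamma draws are positive.
#' @export
#' @examples
#' set.seed(1)
#' mean(draw_parameter(0.8, "beta", 0.25, n = 1e4))
draw_parameter <- function(base, family = c("beta", "gamma"),
                           range_fraction = 0.25, n = 1L,
                           bound_mode = c("moment", "hard")) {
  family <- match.arg(family)
  bound_mode <- match.arg(bound_mode)
  if (!is.numeric(base) || length(base) != 1 || base <= 0) {
    stop("base must be a single value > 0", call. = FALSE)
  }
  if (family == "beta" && base >= 1) {
    stop("beta family requires base < 1", call. = FALSE)
  }
  sd <- base * range_fraction / 2
  if (bound_mode == "hard") {
    # symmetric Beta(1.5, 1.5) has sd 1/4 of its support width: matching
    half <- base * range_fraction
    x <- base - half + 2 * half * stats::rbeta(n, 1.5, 1.5)
    if (family == "beta") x <- pmin(pmax(x, 1e-12), 1 - 1e-12)
    return(x)
  }
  if (family == "gamma") {
    shape <- (base / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / base)
  } else {
    v <- sd^2
    if (v >= base * (1 - base)) {
      stop("beta family: variance too large for base ", base, call. = FALSE)
    }
    nu <- base * (1 - base) / v - 1
    pmin(pmax(stats::rbeta(n, base * nu, (1 - base) * nu), 1e-12), 1 - 1e-12)
  }
}

# perturb a full parameter set for one PSA draw (uses the session RNG,
# which run_psa seeds per draw)
perturb_parameters <- function(p, cfg) {
  rf <- cfg$range_fraction
  bm <- cfg$bound_mode
  draw_vec <- function(x, family) {
    vapply(x, function(b) {
      if (b <= 0) return(b)
      if (family == "beta") {
        if (b >= 1) return(b)
        # for probabilities above 1/2 a +/- 25% relative sd can exceed the
        # feasible beta variance; perturb the complement (the miss rate)
        # instead, which keeps the mean at b and the spread proportionate
        if (b > 0.5) return(1 - draw_parameter(1 - b, "beta", rf, 1L, bm))
      }
      draw_parameter(b, family, rf, 1L, bm)
    }, numeric(1))
  }

  if ("test_chars" %in% cfg$perturb) {
    tc <- p$test_chars
    tc$fit_sensitivity <- pmin(cummax(draw_vec(tc$fit_sensitivity, "beta")), 1 - 1e-9)
    tc$tcs_sensitivity <- pmin(cummax(draw_vec(tc$tcs_sensitivity, "beta")), 1 - 1e-9)
    tc$fit_specificity <- draw_vec(tc$fit_specificity, "beta")
    tc$tcs_perforation_prob <- draw_vec(tc$tcs_perforation_prob, "beta")
    p$test_chars <- tc
  }
  if ("costs" %in% cfg$perturb) {
    co <- p$costs
    co$fit <- draw_vec(co$fit, "gamma")
    co$tcs <- draw_vec(co$tcs, "gamma")
    co$polypectomy <- draw_vec(co$polypectomy, "gamma")
    co$perforation_management <- draw_vec(co$perforation_management, "gamma")
    co$crc_treatment <- draw_vec(co$crc_treatment, "gamma")
    p$costs <- co
  }
  if ("transition" %in% cfg$perturb) {
    tr <- p$transition
    for (b in seq_len(dim(tr)[1])) for (s in 1:2) for (f in .LIVE) {
      row <- tr[b, s, f, ]
      off <- which(row > 0 & seq_along(row) != f)
      if (length(off) == 0) next
      # post-polypectomy new-adenoma probability has count data: beta
      family <- if (f == .S$post_polyp) "beta" else "gamma"
      row[off] <- draw_vec(row[off], family)
      if (sum(row[off]) > 0.999) row[off] <- row[off] * 0.999 / sum(row[off])
      row[f] <- 1 - sum(row[off])
      tr[b, s, f, ] <- row
    }
    p$transition <- tr
  }
  validate_parameters(p)
}

#' Run a probabilistic sensitivity analysis
#'
#' For each of `cfg$n_draws` draws: perturb the uncertain parameters,
#' simulate both strategies on the same cohort with common random
#' numbers, and record the per-person cost and QALY differences
#' (strategy A minus strategy B), the net monetary benefit at the
#' willingness-to-pay threshold, and the cost-effective flag
#' (`NMB > 0`; an NMB of exactly 0 counts as not cost-effective). The
#' whole run is reproducible from `cfg$seed`.
#'
#' @param base A `crc_parameters` object (base-case values).
#' @param strategy_a,strategy_b [strategy_spec()] objects to compare
#'   (A is the intervention).
#' @param cfg A [psa_config()].
#' @param pop Optional fixed `crc_population`; by default one cohort of
#'   `cfg$n_individuals_per_draw` persons is sampled from the parameter
#'   set's population block.
#' @return A `crc_psa_result`: `draws` (data frame with `draw`,
#'   `delta_cost`, `delta_qaly`, `nmb`, `cost_effective`) and `summary`
#'   (probability cost-effective, quadrant counts, `n_draws`, `wtp`).
#' @export
run_psa <- function(base, strategy_a, strategy_b, cfg, pop = NULL) {
  validate_parameters(base)
  strategy_a <- validate_strategy(strategy_a)
  strategy_b <- validate_strategy(strategy_b)
  if (!inherits(cfg, "crc_psa_config")) stop("cfg must be a psa_config()", call. = FALSE)

  if (is.null(pop)) {
    spec <- population_spec(cfg$n_individuals_per_draw,
                            base$population$age_weights,
                            base$population$sex_weights,
                            seed = cfg$seed)
    pop <- sample_population(spec)
  }
  wtp <- base$econ$wtp

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  res <- vector("list", cfg$n_draws)
  for (j in seq_len(cfg$n_draws)) {
    set.seed((cfg$seed + 7919L * j) %% .Machine$integer.max)
    pj <- perturb_parameters(base, cfg)
    sim_seed <- if (cfg$redraw_person_streams) {
      (cfg$seed + 104729L * j) %% .Machine$integer.max
    } else cfg$seed
    out_a <- run_cohort(pop, pj, strategy_a, seed = sim_seed)
    out_b <- run_cohort(pop, pj, strategy_b, seed = sim_seed)
    dc <- out_a$mean_discounted_cost - out_b$mean_discounted_cost
    dq <- out_a$mean_discounted_qalys - out_b$mean_discounted_qalys
    res[[j]] <- c(dc, dq)
  }
  dc <- vapply(res, `[`, numeric(1), 1L)
  dq <- vapply(res, `[`, numeric(1), 2L)
  nmb <- wtp * dq - dc
  draws <- data.frame(draw = seq_len(cfg$n_draws), delta_cost = dc,
                      delta_qaly = dq, nmb = nmb, cost_effective = nmb > 0)
  structure(list(draws = draws,
                 summary = psa_summary(draws, wtp),
                 wtp = wtp, cfg = cfg),
            class = "crc_psa_result")
}

psa_summary <- function(draws, wtp) {
  list(prob_cost_effective = mean(draws$cost_effective),
       n_draws = nrow(draws),
       wtp = wtp,
       quadrants = c(
         NE = sum(draws$delta_qaly > 0 & draws$delta_cost > 0),
         NW = sum(draws$delta_qaly <= 0 & draws$delta_cost > 0),
         SE = sum(draws$delta_qaly > 0 & draws$delta_cost <= 0),
         SW = sum(draws$delta_qaly <= 0 & draws$delta_cost <= 0)))
}

#' Probability of cost-effectiveness at an arbitrary threshold
#'
#' Re-evaluates the stored draws at a new willingness-to-pay value. As
#' `wtp` grows the probability tends to the fraction of draws with a
#' QALY gain; at `wtp = 0` it is the fraction with a cost saving.
#'
#' @param result A `crc_psa_result`.
#' @param wtp Willingness-to-pay threshold, JPY/QALY.
#' @return Fraction of draws with `wtp * dQ - dC > 0`.
#' @export
prob_cost_effective <- function(result, wtp) {
  mean(wtp * result$draws$delta_qaly - result$draws$delta_cost > 0)
}

#' Export the cost-effectiveness plane
#'
#' One row per draw with the QALY difference, cost difference, and the
#' cost-effective flag at the stored threshold — the table behind the
#' usual CE-plane scatter plot where cost-effective draws are
#' highlighted.
#'
#' @param result A `crc_psa_result`.
#' @param path Optional CSV path; written with [utils::write.csv()].
#' @return A data frame `(draw, delta_qaly, delta_cost, cost_effective)`.
#' @export
ce_plane_export <- function(result, path = NULL) {
  tab <- result$draws[, c("draw", "delta_qaly", "delta_cost", "cost_effective")]
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' @export
print.crc_psa_result <- function(x, ...) {
  s <- x$summary
  cat("<crc_psa_result>", s$n_draws, "draws\n")
  cat(sprintf("  P(cost-effective at WTP %s JPY/QALY): %.1f%%\n",
              format(s$wtp, big.mark = ",", scientific = FALSE),
              100 * s$prob_cost_effective))
  cat("  CE-plane quadrants (NE/NW/SE/SW):",
      paste(s$quadrants, collapse = "/"), "\n")
  invisible(x)
}

#' Plot the cost-effectiveness plane
#'
#' Scatter of the PSA draws with the WTP line; requires ggplot2.
#'
#' @param result A `crc_psa_result`.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(result) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ce_plane needs the ggplot2 package", call. = FALSE)
  }
  d <- result$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost,
                                  colour = .data$cost_effective)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = result$wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen", `FALSE` = "grey40"),
                                 name = "cost-effective") +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost (JPY per person)")
}
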