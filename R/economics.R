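#' Discount factor for a model cycle
#'
#' @param year Non-negative integer cycle index (0 = first cycle).
#' @param rate Annual discount rate (fraction, >= 0; default 0.02).
#' @return `1 / (1 + rate)^year`.
#' @export
#' @examples
#' discount_factor(0, 0.02)   # 1
#' discount_factor(1, 0.02)   # 0.980392...
discount_factor <- function(year, rate = 0.02) {
  if (any(year < 0)) stop("year must be >= 0", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  1 / (1 + rate)^year
}

#' Convert JPY to USD
#'
#' Divides by the configured exchange rate (default 145.52 JPY/USD) and
#' rounds to one decimal, the convention used for reported USD values.
#' Internal computations keep full precision; only this reporting
#' helper rounds.
#'
#' @param amount Amount(s) in JPY.
#' @param econ An `econ` block (or full `crc_parameters`); uses its
#'   `jpy_per_usd`.
#' @param digits Decimal places for the reported value (default 1).
#' @return USD amount rounded to `digits`.
#' @export
#' @examples
#' jpy_to_usd(5e6)      # 34359.5
#' jpy_to_usd(120219)   # 826.1
jpy_to_usd <- function(amount, econ = list(jpy_per_usd = 145.52), digits = 1) {
  if (inherits(econ, "crc_parameters")) econ <- econ$econ
  if (!is.numeric(econ$jpy_per_usd) || econ$jpy_per_usd <= 0) {
    stop("jpy_per_usd must be > 0", call. = FALSE)
  }
  round(amount / econ$jpy_per_usd, digits)
}

#' Incremental comparison of two strategies
#'
#' Computes the per-person cost and QALY differences of an intervention
#' against a comparator evaluated on the same population with the same
#' discounting, and classifies the result:
#'
#' * **Dominant** — cheaper and more effective (`dC < 0`, `dQ > 0`).
#' * **Dominated** — dearer and less effective (`dC > 0`, `dQ < 0`).
#' * **ICER** — more effective and dearer: `ICER = dC / dQ` JPY per
#'   QALY gained. When both deltas are negative (cheaper and less
#'   effective) the ratio is still reported but flagged `southwest`,
#'   since its decision reading inverts (it is the saving per QALY
#'   forgone).
#' * **Equivalent** — both deltas inside tolerance.
#' * **Equal effect, cost differs** — QALY delta inside tolerance while
#'   the cost delta is not; reported instead of dividing by a
#'   numerically meaningless QALY difference.
#'
#' Tolerances default to 1e-9 QALY and 1e-6 JPY per person, far below
#' Monte-Carlo resolution. `cost_effective_at_wtp` is `TRUE` for a
#' dominant result or an ICER at or below the willingness-to-pay
#' threshold with a QALY gain.
#'
#' @param intervention,comparator [cohort_outcomes()] objects (printed
#'   summary values can be wrapped with `cohort_outcomes()` directly).
#' @param econ An `econ` block or `crc_parameters` (for `wtp`).
#' @param tol_qaly,tol_cost Equality tolerances.
#' @return A `crc_comparison` with `delta_cost`, `delta_qaly`, `icer`,
#'   `verdict`, `southwest`, `cost_effective_at_wtp`.
#' @export
#' @examples
#' a <- cohort_outcomes(120455, 20.4286)
#' b <- cohort_outcomes(120219, 20.3912)
#' compare_strategies(a, b)   # ICER about 6,310 JPY/QALY
compare_strategies <- function(intervention, comparator,
                               econ = list(wtp = 5e6),
                               tol_qaly = 1e-9, tol_cost = 1e-6) {
  if (inherits(econ, "crc_parameters")) econ <- econ$econ
  dc <- intervention$mean_discounted_cost - comparator$mean_discounted_cost
  dq <- intervention$mean_discounted_qalys - comparator$mean_discounted_qalys
  zero_c <- abs(dc) <= tol_cost
  zero_q <- abs(dq) <= tol_qaly
  icer <- NA_real_
  southwest <- FALSE
  if (zero_c && zero_q) {
    verdict <- "Equivalent"
    ce <- TRUE
  } else if (zero_q) {
    verdict <- "EqualEffectCostDiffers"
    ce <- dc < 0
  } else if (dq > 0 && dc < -tol_cost) {
    verdict <- "Dominant"
    ce <- TRUE
  } else if (dq < 0 && dc > tol_cost) {
    verdict <- "Dominated"
    ce <- FALSE
  } else if (dq > 0) {
    verdict <- "ICER"
    icer <- dc / dq
    ce <- icer <= econ$wtp
  } else {
    # cheaper and less effective: savings per QALY forgone
    verdict <- "ICER"
    southwest <- TRUE
    icer <- dc / dq
    ce <- icer >= econ$wtp
  }
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 verdict = verdict, southwest = southwest,
                 cost_effective_at_wtp = ce, wtp = econ$wtp),
            class = "crc_comparison")
}

#' @export
print.crc_comparison <- function(x, ...) {
  cat("<crc_comparison>\n")
  cat(sprintf("  delta cost:  %s JPY/person\n", format(round(x$delta_cost, 2), big.mark = ",")))
  cat(sprintf("  delta QALYs: %.6f /person\n", x$delta_qaly))
  lab <- x$verdict
  if (lab == "ICER") {
    lab <- sprintf("ICER = %s JPY/QALY%s", format(round(x$icer), big.mark = ","),
                   if (x$southwest) " (southwest: saving per QALY forgone)" else "")
  }
  cat("  verdict:    ", lab, "\n")
  cat("  cost-effective at WTP", format(x$wtp, big.mark = ",", scientific = FALSE),
      "JPY/QALY:", x$cost_effective_at_wtp, "\n")
  invisible(x)
}

#' Net monetary benefit of an intervention over a comparator
#'
#' `NMB = wtp * delta_QALY - delta_cost`, positive exactly when the
#' intervention is cost-effective at the willingness-to-pay threshold.
#' Accepts either two outcome objects or a `crc_comparison`.
#'
#' @param intervention,comparator [cohort_outcomes()] objects, or pass a
#'   `crc_comparison` as `intervention`.
#' @param wtp Willingness-to-pay threshold, JPY/QALY.
#' @return NMB in JPY per person.
#' @export
net_monetary_benefit <- function(intervention, comparator = NULL, wtp = 5e6) {
  if (inherits(intervention, "crc_comparison")) {
    return(wtp * intervention$delta_qaly - intervention$delta_cost)
  }
  dq <- intervention$mean_discounted_qalys - comparator$mean_discounted_qalys
  dc <- intervention$mean_discounted_cost - comparator$mean_discounted_cost
  wtp * dq - dc
}
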