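#' One-cycle transition distribution
#'
#' Returns the probability distribution over successor states for one
#' 1-year cycle, composing the disease-transition row for the person's
#' age band, sex and current state with the life table's other-cause
#' death hazard. Competing mortality is resolved by a sequential draw
#' with disease first: CRC death keeps its full probability `m`,
#' other-cause death gets `(1 - m) * h`, and every live successor is
#' scaled by `(1 - h)`, where `h` is the life-table hazard at the exact
#' current age.
#'
#' @param state Current health state (label or code); must not be an
#'   absorbing death state — the caller handles absorbing states.
#' @param age Current age in years, 40-100.
#' @param sex `"female"` or `"male"`.
#' @param p A `crc_parameters` object.
#' @return Named probability vector over all 15 states, summing to 1.
#' @export
#' @examples
#' p <- default_parameters()
#' d <- transition_distribution("Normal", 55, "female", p)
#' sum(d)
transition_distribution <- function(state, age, sex, p) {
  f <- state_code(state)
  if (f %in% .DEAD) {
    stop("transition_distribution: state '", crc_states()[f],
         "' is absorbing; the caller must not advance dead persons", call. = FALSE)
  }
  if (age < 40 || age > 100) {
    stop("no age band / life-table entry for age ", age,
         " (model covers 40-100)", call. = FALSE)
  }
  s <- sex_code(sex)
  q <- p$transition[age_band_index(age), s, f, ]
  h <- p$life_table[[.SEXES[s]]][as.integer(age) - 39L]
  compose_with_mortality(q, h)
}

# disease row q (sums to 1, CRC death in position 14) + hazard h -> full row
compose_with_mortality <- function(q, h) {
  m <- q[.S$dead_crc]
  out <- q * (1 - h)
  out[.S$dead_crc] <- m
  out[.S$dead_other] <- (1 - m) * h
  out
}

# Precompute the composed transition matrix for every (age 40..100, sex,
# live from-state): a (61 * 2 * 13) x 15 matrix plus its row-cumulative
# form for vectorized categorical draws.
# Row index: (from - 1) * 122 + (sex - 1) * 61 + (age - 39).
build_composed_transitions <- function(p) {
  ages <- 40:100
  n_age <- length(ages)
  prob <- matrix(0, nrow = n_age * 2L * 13L, ncol = .N_STATES)
  for (f in .LIVE) {
    for (s in 1:2) {
      q_band <- p$transition[, s, f, , drop = TRUE]       # 10 x 15
      q_age <- q_band[age_band_index(ages), , drop = FALSE] # 61 x 15
      h <- p$life_table[[.SEXES[s]]]
      m <- q_age[, .S$dead_crc]
      block <- q_age * (1 - h)
      block[, .S$dead_crc] <- m
      block[, .S$dead_other] <- (1 - m) * h
      rows <- (f - 1L) * 2L * n_age + (s - 1L) * n_age + seq_len(n_age)
      prob[rows, ] <- block
    }
  }
  cum <- row_cumsum(prob)
  cum[, .N_STATES] <- 1  # guard against rounding at the tail
  list(prob = prob, cum = cum, n_age = n_age)
}

composed_row_index <- function(age, sex, state, n_age = 61L) {
  (state - 1L) * 2L * n_age + (sex - 1L) * n_age + (as.integer(age) - 39L)
}
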