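# shared in-code fixtures

# parameter set with no disease at all: only life-table mortality acts
zero_disease_params <- function(utilities_one = TRUE, discount = NULL) {
  p <- default_parameters()
  tr <- p$transition
  tr[] <- 0
  for (f in 1:13) tr[, , f, f] <- 1
  p$transition <- tr
  if (utilities_one) p$utilities$states[] <- 1
  if (!is.null(discount)) p$econ$discount_rate <- discount
  validate_parameters(p)
}

# flat life table: constant annual hazard h for both sexes
constant_hazard_params <- function(h, ...) {
  p <- zero_disease_params(...)
  p$life_table$female[] <- h
  p$life_table$male[] <- h
  suppressWarnings(validate_parameters(p))
  p
}

# life-table remaining "QALYs" with accrual at cycle start and death
# forced after the accrual at max_age: sum over t of disc^t * S(t),
# S(0) = 1, S(t) = prod_{k<t} (1 - q(age0 + k))
life_table_qalys <- function(p, age0, sex, rate = 0, max_age = 100) {
  q <- p$life_table[[sex]]
  total <- 0; surv <- 1; t <- 0; age <- age0
  repeat {
    total <- total + surv / (1 + rate)^t
    if (age >= max_age) break
    surv <- surv * (1 - q[age - 39])
    t <- t + 1; age <- age + 1
  }
  total
}

small_pop <- function(n = 2000, seed = 42) {
  sample_population(population_spec(n, seed = seed))
}
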