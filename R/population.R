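#' Specify an initial screening population
#'
#' The simulated population emulates an average-risk screening cohort
#' aged 40-74. By default ages are uniform over 40-74 and sexes split
#' 50/50; both are overridable with arbitrary weights (the published
#' screening-attendance distribution is not public, so uniform weights
#' are the neutral default).
#'
#' @param n_individuals Number of persons to simulate.
#' @param age_weights Named numeric vector of sampling weights over ages
#'   40-74; must sum to 1.
#' @param sex_weights Named numeric vector `c(female = , male = )`
#'   summing to 1.
#' @param seed Integer seed used by [sample_population()].
#' @return A `crc_population_spec` list.
#' @export
population_spec <- function(n_individuals = 10000L,
                            age_weights = NULL,
                            sex_weights = c(female = 0.5, male = 0.5),
                            seed = 1L) {
  if (is.null(age_weights)) {
    age_weights <- stats::setNames(rep(1 / 35, 35), 40:74)
  }
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 0) stop("n_individuals must be >= 0", call. = FALSE)
  ages <- as.integer(names(age_weights))
  if (anyNA(ages) || any(ages < 40 | ages > 74)) {
    stop("age_weights: ages must lie in 40..74", call. = FALSE)
  }
  if (any(age_weights < 0) || abs(sum(age_weights) - 1) > 1e-9) {
    stop("age_weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (!identical(sort(names(sex_weights)), c("female", "male")) ||
      any(sex_weights < 0) || abs(sum(sex_weights) - 1) > 1e-9) {
    stop("sex_weights must be c(female=, male=) and sum to 1", call. = FALSE)
  }
  structure(list(n_individuals = n_individuals,
                 age_weights = age_weights,
                 sex_weights = sex_weights[c("female", "male")],
                 seed = as.integer(seed)),
            class = "crc_population_spec")
}

#' Sample an initial population
#'
#' Draws `n_individuals` persons with ages and sexes from the spec's
#' weights. Everyone starts in the Normal state, alive, never screened.
#' The draw is a pure function of `spec$seed`.
#'
#' @param spec A [population_spec()], or a `crc_parameters` object whose
#'   `population` block is used.
#' @return A data frame of class `crc_population` with columns `age`
#'   (integer years), `sex` (`"female"`/`"male"`) and `state`
#'   (`"Normal"`).
#' @export
#' @examples
#' pop <- sample_population(population_spec(5, seed = 42))
#' nrow(pop)
sample_population <- function(spec) {
  if (inherits(spec, "crc_parameters")) {
    spec <- population_spec(spec$population$n_individuals,
                            spec$population$age_weights,
                            spec$population$sex_weights,
                            spec$population$seed)
  }
  if (!inherits(spec, "crc_population_spec")) {
    stop("spec must be a population_spec() or crc_parameters object", call. = FALSE)
  }
  n <- spec$n_individuals
  rng <- rng_streams(spec$seed)
  ages <- as.integer(names(spec$age_weights))
  if (n == 0L) {
    out <- data.frame(age = integer(0), sex = character(0), state = character(0))
  } else {
    u_age <- stream_runif(rng, "nh", n)
    u_sex <- stream_runif(rng, "nh", n)
    age <- ages[1L + rowSums(outer(u_age, cumsum(spec$age_weights), `>`))]
    sex <- .SEXES[1L + (u_sex >= spec$sex_weights[["female"]])]
    out <- data.frame(age = age, sex = sex, state = "Normal")
  }
  class(out) <- c("crc_population", class(out))
  out
}
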