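#' Load a parameter file
#'
#' Reads a structured-text parameter file (YAML or JSON, decided by the
#' file extension) against the versioned schema and returns a fully
#' populated, validated parameter set. Every block or field that the
#' file omits is filled from the package defaults and flagged
#' `"synthetic"` in `meta`; blocks the file provides are flagged
#' `"loaded"`. Unknown fields are rejected (fail-closed) so a typo in a
#' config cannot silently fall back to a default.
#'
#' The schema mirrors the blocks of [default_parameters()]:
#' `transition` (nested age band > sex > from-state > successor
#' probabilities; the stay probability may be omitted, in which case it
#' is the remainder of the row, or given explicitly, in which case the
#' row must sum to 1), `test_chars`, `costs`, `utilities`, `life_table`
#' (complete vectors `age`, `female`, `male` over ages 40-100), `econ`
#' and `population`. A complete annotated example ships at
#' `system.file("extdata", "params_example.yaml", package = "crcscreen")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` parameter file.
#' @return A validated `crc_parameters` object.
#' @seealso [write_parameters()] for the inverse; the pair round-trips.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- read_structured(path)
  if (!is.list(raw)) stop("parameter file must contain a mapping at top level", call. = FALSE)

  known <- c("schema_version", "transition", "test_chars", "costs",
             "utilities", "life_table", "econ", "population", "meta")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown top-level field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(raw$schema_version) && as.integer(raw$schema_version) != 1L) {
    stop("unsupported schema_version: ", raw$schema_version, call. = FALSE)
  }

  p <- default_parameters()

  if (!is.null(raw$transition)) {
    p$transition <- merge_transition(p$transition, raw$transition)
    p$meta[["transition"]] <- "loaded"
  }
  if (!is.null(raw$test_chars)) {
    p$test_chars <- merge_named_block(p$test_chars, raw$test_chars, "test_chars")
    p$meta[["test_chars"]] <- "loaded"
  }
  if (!is.null(raw$costs)) {
    p$costs <- merge_named_block(p$costs, raw$costs, "costs")
    p$meta[["costs"]] <- "loaded"
  }
  if (!is.null(raw$utilities)) {
    p$utilities <- merge_named_block(p$utilities, raw$utilities, "utilities")
    p$meta[["utilities"]] <- "loaded"
  }
  if (!is.null(raw$life_table)) {
    lt <- raw$life_table
    unknown <- setdiff(names(lt), c("age", "female", "male"))
    if (length(unknown) > 0) stop("life_table: unknown field(s): ",
                                  paste(unknown, collapse = ", "), call. = FALSE)
    if (!all(c("age", "female", "male") %in% names(lt))) {
      stop("life_table: must provide age, female and male in full", call. = FALSE)
    }
    p$life_table <- list(age = as.integer(unlist(lt$age)),
                         female = as.numeric(unlist(lt$female)),
                         male = as.numeric(unlist(lt$male)))
    p$meta[["life_table"]] <- "loaded"
  }
  if (!is.null(raw$econ)) {
    p$econ <- merge_named_block(p$econ, raw$econ, "econ")
    p$meta[["econ"]] <- "loaded"
  }
  if (!is.null(raw$population)) {
    po <- raw$population
    unknown <- setdiff(names(po), names(p$population))
    if (length(unknown) > 0) stop("population: unknown field(s): ",
                                  paste(unknown, collapse = ", "), call. = FALSE)
    if (!is.null(po$n_individuals)) p$population$n_individuals <- as.integer(po$n_individuals)
    if (!is.null(po$seed)) p$population$seed <- as.integer(po$seed)
    if (!is.null(po$age_weights)) {
      p$population$age_weights <- unlist(po$age_weights)
    }
    if (!is.null(po$sex_weights)) {
      p$population$sex_weights <- unlist(po$sex_weights)[c("female", "male")]
    }
    p$meta[["population"]] <- "loaded"
  }

  # files written by write_parameters() carry their provenance flags;
  # honoring them makes load -> write -> load the identity
  if (!is.null(raw$meta)) {
    m <- unlist(raw$meta)
    unknown <- setdiff(names(m), names(p$meta))
    if (length(unknown) > 0) stop("meta: unknown block(s): ",
                                  paste(unknown, collapse = ", "), call. = FALSE)
    p$meta[names(m)] <- m
  }

  validate_parameters(p)
}

read_structured <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    stop("unsupported parameter-file extension: .", ext,
         " (use .yaml, .yml or .json)", call. = FALSE)
  }
}

# merge a flat or one-level-nested block of named numerics, fail-closed
merge_named_block <- function(base, user, block) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0) {
    stop(block, ": unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    val <- user[[nm]]
    if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]]))) {
      val <- unlist(val)
      unknown <- setdiff(names(val), names(base[[nm]]))
      if (length(unknown) > 0) {
        stop(block, "$", nm, ": unknown entr",
             if (length(unknown) > 1) "ies: " else "y: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      base[[nm]][names(val)] <- as.numeric(val)
    } else {
      base[[nm]] <- as.numeric(val)
    }
  }
  base
}

# overlay user-specified transition rows onto the default array
merge_transition <- function(tr, user) {
  states <- crc_states()
  for (band in names(user)) {
    b <- match(band, .AGE_BANDS)
    if (is.na(b)) stop("transition: unknown age band '", band, "' (use ",
                       paste(.AGE_BANDS, collapse = ", "), ")", call. = FALSE)
    for (sx in names(user[[band]])) {
      s <- sex_code(sx)
      for (from in names(user[[band]][[sx]])) {
        f <- match(from, states)
        if (is.na(f) || !(f %in% .LIVE)) {
          stop("transition: unknown or absorbing from-state '", from, "'", call. = FALSE)
        }
        row_in <- unlist(user[[band]][[sx]][[from]])
        to <- match(names(row_in), states)
        if (anyNA(to)) stop("transition: unknown successor state(s) in row ",
                            band, "/", sx, "/", from, call. = FALSE)
        if (any(row_in < 0 | row_in > 1)) {
          stop("transition: probability out of [0, 1] in row ",
               band, "/", sx, "/", from, call. = FALSE)
        }
        v <- numeric(.N_STATES)
        v[to] <- as.numeric(row_in)
        if (f %in% to) {
          if (abs(sum(v) - 1) > 1e-9) {
            stop(sprintf("transition: row %s/%s/%s sums to %.6f, not 1",
                         band, sx, from, sum(v)), call. = FALSE)
          }
        } else {
          stay <- 1 - sum(v)
          if (stay < -1e-9) {
            stop(sprintf("transition: row %s/%s/%s sums to %.6f, exceeding 1",
                         band, sx, from, sum(v)), call. = FALSE)
          }
          v[f] <- max(stay, 0)
        }
        tr[b, s, f, ] <- v
      }
    }
  }
  tr
}

#' Write a parameter set to a file
#'
#' Serializes a parameter set to YAML or JSON (by extension). JSON is
#' written at full double precision, so
#' `load_parameters(write_parameters(p, f))` reproduces `p` exactly;
#' YAML output is rounded to 15 significant digits.
#'
#' @param p A validated `crc_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  validate_parameters(p)
  states <- crc_states()

  tr_out <- list()
  for (b in seq_along(.AGE_BANDS)) {
    band <- list()
    for (s in 1:2) {
      rows <- list()
      for (f in .LIVE) {
        v <- p$transition[b, s, f, ]
        nz <- which(v != 0)
        rows[[states[f]]] <- as.list(stats::setNames(v[nz], states[nz]))
      }
      band[[.SEXES[s]]] <- rows
    }
    tr_out[[.AGE_BANDS[b]]] <- band
  }

  out <- list(
    schema_version = 1L,
    transition = tr_out,
    test_chars = list(
      fit_sensitivity = as.list(p$test_chars$fit_sensitivity),
      fit_specificity = p$test_chars$fit_specificity,
      tcs_sensitivity = as.list(p$test_chars$tcs_sensitivity),
      tcs_perforation_prob = p$test_chars$tcs_perforation_prob
    ),
    costs = list(
      fit = p$costs$fit, tcs = p$costs$tcs, polypectomy = p$costs$polypectomy,
      perforation_management = p$costs$perforation_management,
      crc_treatment = as.list(p$costs$crc_treatment),
      dukes_d_multiplier = p$costs$dukes_d_multiplier
    ),
    utilities = list(states = as.list(p$utilities$states),
                     perforation_disutility = p$utilities$perforation_disutility),
    life_table = list(age = p$life_table$age,
                      female = p$life_table$female,
                      male = p$life_table$male),
    econ = p$econ,
    population = list(n_individuals = p$population$n_individuals,
                      age_weights = as.list(p$population$age_weights),
                      sex_weights = as.list(p$population$sex_weights),
                      seed = p$population$seed),
    meta = as.list(p$meta)
  )

  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(out, precision = 15), path)
  } else if (ext == "json") {
    # digits = I(17): full double precision, so the round-trip is exact
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else {
    stop("unsupported output extension: .", ext, call. = FALSE)
  }
  invisible(path)
}
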