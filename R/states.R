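#' Health states of the colorectal cancer natural-history model
#'
#' The model follows the adenoma-carcinoma sequence: normal epithelium
#' progresses through small (1-4 mm) and medium (5-9 mm) low-risk polyps
#' (non-advanced adenomas) and high-risk polyps (advanced adenomas:
#' diameter >= 10 mm, high-grade dysplasia, or substantial villous
#' component) to preclinical colorectal cancer staged Dukes A-D, which
#' can present clinically (or be detected by screening) at the same
#' stage. Persons whose polyps are resected enter a post-polypectomy
#' state with its own new-adenoma probability. Death from CRC and death
#' from other causes are absorbing.
#'
#' `crc_states()` returns the ordered state labels; the integer codes
#' used internally are the positions in this vector.
#'
#' @return Character vector of the 15 state labels, in model order.
#' @export
#' @examples
#' crc_states()
crc_states <- function() {
  c("Normal",
    "LowRiskPolyp_1_4mm", "LowRiskPolyp_5_9mm", "HighRiskPolyp",
    "PreclinicalCRC_DukesA", "PreclinicalCRC_DukesB",
    "PreclinicalCRC_DukesC", "PreclinicalCRC_DukesD",
    "ClinicalCRC_DukesA", "ClinicalCRC_DukesB",
    "ClinicalCRC_DukesC", "ClinicalCRC_DukesD",
    "PostPolypectomy",
    "DeadCRC", "DeadOther")
}

# integer state codes (positions in crc_states())
.S <- list(
  normal = 1L,
  lr_small = 2L, lr_medium = 3L, hr = 4L,
  pre_a = 5L, pre_b = 6L, pre_c = 7L, pre_d = 8L,
  clin_a = 9L, clin_b = 10L, clin_c = 11L, clin_d = 12L,
  post_polyp = 13L,
  dead_crc = 14L, dead_other = 15L
)

.PRECLIN <- 5:8
.CLINICAL <- 9:12
.DEAD <- 14:15
.LIVE <- 1:13
.N_STATES <- 15L

#' Is a state absorbing (dead)?
#'
#' @param state State label or integer code.
#' @return Logical vector.
#' @export
is_absorbing_state <- function(state) {
  state_code(state) %in% .DEAD
}

# map labels or codes to integer codes, with validation
state_code <- function(state) {
  if (is.character(state)) {
    idx <- match(state, crc_states())
    if (anyNA(idx)) {
      stop("unknown health state(s): ",
           paste(unique(state[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  state <- as.integer(state)
  if (any(state < 1L | state > .N_STATES, na.rm = TRUE)) {
    stop("state code out of range 1..", .N_STATES, call. = FALSE)
  }
  state
}

# lesion class of each state, used to index test sensitivities;
# NA for states with nothing for a stool test or scope to find
.LESION_CLASSES <- c("lr_small", "lr_medium", "hr",
                     "crc_a", "crc_b", "crc_c", "crc_d")

lesion_class_of_state <- function(state) {
  code <- state_code(state)
  cls <- rep(NA_character_, length(code))
  cls[code == .S$lr_small] <- "lr_small"
  cls[code == .S$lr_medium] <- "lr_medium"
  cls[code == .S$hr] <- "hr"
  cls[code %in% .PRECLIN] <- c("crc_a", "crc_b", "crc_c", "crc_d")[code[code %in% .PRECLIN] - 4L]
  cls
}

# sexes are coded 1 = female, 2 = male throughout
.SEXES <- c("female", "male")

sex_code <- function(sex) {
  if (is.character(sex)) {
    idx <- match(tolower(sex), .SEXES)
    if (anyNA(idx)) stop("sex must be 'female' or 'male'", call. = FALSE)
    return(idx)
  }
  idx <- as.integer(sex)
  if (any(idx < 1L | idx > 2L, na.rm = TRUE)) stop("sex code must be 1 or 2", call. = FALSE)
  idx
}

# 5-year age bands 40-44 ... 80-84, 85+
.AGE_BANDS <- c("40-44", "45-49", "50-54", "55-59", "60-64",
                "65-69", "70-74", "75-79", "80-84", "85+")

age_band_index <- function(age) {
  if (any(age < 40)) stop("model ages start at 40", call. = FALSE)
  pmin(as.integer((age - 40) %/% 5), 9L) + 1L
}
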