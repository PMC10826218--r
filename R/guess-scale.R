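#' The five-level intervention-perception scale
#'
#' Respondents (trial participants or outcome assessors) report how strongly
#' they believe the active or the control intervention was received, or that
#' they do not know. These five tokens are the only admissible values of the
#' `response` column throughout the package; anything else is rejected at
#' parse time.
#'
#' @return Character vector of the five admissible response tokens, ordered
#'   from strong active belief to strong control belief with `dont_know`
#'   in the middle.
#' @examples
#' guess_levels()
#' @export
guess_levels <- function() {
  c("strongly_active", "somewhat_active", "dont_know",
    "somewhat_control", "strongly_control")
}

#' @rdname guess_levels
#' @return Character vector of the two admissible arm labels.
#' @export
arm_levels <- function() {
  c("active", "control")
}

#' Validate and normalise response tokens
#'
#' @param x Character vector (or factor) of candidate response tokens.
#' @return `x` as a character vector, guaranteed to contain only admissible
#'   tokens. Invalid entries abort with the offending positions.
#' @examples
#' as_guess(c("dont_know", "strongly_active"))
#' @export
as_guess <- function(x) {
  x <- as.character(x)
  bad <- which(!x %in% guess_levels())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Invalid response token(s) %s at position(s) %s; admissible tokens are: %s",
      paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 5), collapse = ", "),
      paste(guess_levels(), collapse = ", ")
    ), class = "blindex_invalid_response")
  }
  x
}

#' @rdname as_guess
#' @export
as_arm <- function(x) {
  x <- as.character(x)
  bad <- which(!x %in% arm_levels())
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Invalid arm label(s) %s at position(s) %s; use 'active' or 'control'",
      paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 5), collapse = ", ")
    ), class = "blindex_invalid_arm")
  }
  x
}

#' Direction and strength of a guess
#'
#' `guess_direction()` classifies a response against the actual arm as
#' `"correct"`, `"incorrect"` or `"dont_know"`; a guess is correct when its
#' direction (active vs control) matches the arm the respondent was actually
#' evaluating, regardless of strength of belief. `guess_strength()` extracts
#' `"strongly"` / `"somewhat"` (`NA` for `dont_know`).
#'
#' @param arm Character vector of actual arm labels (`"active"`/`"control"`).
#' @param response Character vector of response tokens (see [guess_levels()]).
#' @return Character vector of the same length.
#' @examples
#' guess_direction("active", c("somewhat_active", "strongly_control", "dont_know"))
#' @export
guess_direction <- function(arm, response) {
  arm <- as_arm(arm)
  response <- as_guess(response)
  guessed <- dplyr::case_when(
    response %in% c("strongly_active", "somewhat_active") ~ "active",
    response %in% c("strongly_control", "somewhat_control") ~ "control",
    .default = NA_character_
  )
  dplyr::case_when(
    is.na(guessed) ~ "dont_know",
    guessed == arm ~ "correct",
    .default = "incorrect"
  )
}

#' @rdname guess_direction
#' @export
guess_strength <- function(response) {
  response <- as_guess(response)
  dplyr::case_when(
    startsWith(response, "strongly") ~ "strongly",
    startsWith(response, "somewhat") ~ "somewhat",
    .default = NA_character_
  )
}

# round half away from zero, the convention used for all displayed indices
round_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round half away from zero
#'
#' Display rounding used for all indices in the package (and in trial-report
#' tables): ties round away from zero rather than to even, so 0.125 becomes
#' 0.13 at two digits. Internal computation is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, the index convention).
#' @return Rounded numeric vector; `NaN`/`NA` pass through.
#' @examples
#' bi_round(6 / 11)   # 0.55
#' bi_round(0.125)    # 0.13
#' @export
bi_round <- function(x, digits = 2) round_away(x, digits)

# two-sided normal quantile for a confidence level
z_quantile <- function(level) {
  stopifnot(is.numeric(level), level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}
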