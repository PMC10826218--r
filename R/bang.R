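#' Cross-tabulate respondent-level guesses
#'
#' Builds the arm-by-response count table that the blinding indices consume,
#' completing the grid so every (arm, response) cell is present even when its
#' count is zero. Extra grouping columns (typically `role`) are preserved and
#' the grid is completed within each group.
#'
#' @param data Data frame with one row per respondent, containing at least
#'   `arm` and `response` columns (see [guess_levels()]).
#' @param by Optional character vector of additional grouping columns to
#'   tabulate within (e.g. `"role"`, `"stratum"`).
#' @return A tibble with columns `by...`, `arm`, `response`, `count`.
#' @examples
#' d <- tibble::tibble(
#'   arm = c("active", "active", "control"),
#'   response = c("strongly_active", "dont_know", "somewhat_control")
#' )
#' tally_responses(d)
#' @export
tally_responses <- function(data, by = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("arm", "response") %in% names(data))) {
    rlang::abort("`data` must contain `arm` and `response` columns")
  }
  data <- dplyr::mutate(
    data,
    arm = as_arm(.data$arm),
    response = as_guess(.data$response)
  )
  keys <- c(by, "arm", "response")
  counts <- data |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "count")
  counts <- tidyr::complete(
    counts,
    !!!rlang::syms(by),
    arm = arm_levels(),
    response = guess_levels(),
    fill = list(count = 0L)
  )
  dplyr::arrange(
    counts,
    dplyr::across(dplyr::all_of(by)),
    factor(.data$arm, levels = arm_levels()),
    factor(.data$response, levels = guess_levels())
  )
}

#' Collapse a five-level response table to correct / incorrect / don't know
#'
#' The Bang index does not use strength of belief: within each actual-arm
#' group, strongly and somewhat guesses in the direction of the actual arm
#' merge into `r_correct`, guesses in the opposite direction into
#' `r_incorrect`, and `dont_know` is preserved as `r_dontknow`. Total-zero
#' tables are allowed and collapse to all-zero counts.
#'
#' @param counts Count table as produced by [tally_responses()]: columns
#'   `arm`, `response`, `count`, plus any grouping columns, one row per cell.
#' @return A tibble with one row per (group, arm): columns `r_correct`,
#'   `r_incorrect`, `r_dontknow`, `n` (their sum).
#' @examples
#' d <- study_fixture()
#' tally_responses(d[d$role == "participant", ]) |> collapse_responses()
#' @export
collapse_responses <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (!all(c("arm", "response", "count") %in% names(counts))) {
    rlang::abort("`counts` must contain `arm`, `response` and `count` columns")
  }
  if (any(counts$count < 0)) rlang::abort("counts must be non-negative")
  extra <- setdiff(names(counts), c("arm", "response", "count"))
  counts |>
    dplyr::mutate(direction = guess_direction(.data$arm, .data$response)) |>
    dplyr::summarise(
      r_correct = sum(.data$count[.data$direction == "correct"]),
      r_incorrect = sum(.data$count[.data$direction == "incorrect"]),
      r_dontknow = sum(.data$count[.data$direction == "dont_know"]),
      n = sum(.data$count),
      .by = dplyr::all_of(c(extra, "arm"))
    )
}

#' Bang blinding index: point estimate and variance
#'
#' The arm-specific Bang blinding index is the difference between the
#' proportions of correct and incorrect guesses within an actual-arm group,
#' `BI = p_c - p_i = (r_correct - r_incorrect) / n`. It ranges from -1
#' (complete opposite perception) to 1 (complete correct perception), with 0
#' indicating balanced "random guessing". Its variance is
#' `[p_c + p_i - (p_c - p_i)^2] / n`.
#'
#' When nobody in the group ventured a guess (`r_correct + r_incorrect = 0`)
#' the index is mathematically undefinable and both functions return `NaN`.
#'
#' @param r_correct,r_incorrect,n Non-negative integer vectors (recycled):
#'   correct guesses, incorrect guesses, and group size. `n` must be at
#'   least 1 and at least `r_correct + r_incorrect`.
#' @return Numeric vector; `NaN` where the group contains no guessers.
#' @examples
#' bang_point(6, 0, 11)     # 0.5455
#' bang_point(0, 0, 24)     # NaN: everyone answered "I do not know"
#' bang_variance(5, 4, 13)  # 0.0528
#' @export
bang_point <- function(r_correct, r_incorrect, n) {
  check_collapsed(r_correct, r_incorrect, n)
  out <- (r_correct - r_incorrect) / n
  out[r_correct + r_incorrect == 0] <- NaN
  out
}

#' @rdname bang_point
#' @export
bang_variance <- function(r_correct, r_incorrect, n) {
  check_collapsed(r_correct, r_incorrect, n)
  p_c <- r_correct / n
  p_i <- r_incorrect / n
  out <- (p_c + p_i - (p_c - p_i)^2) / n
  out[r_correct + r_incorrect == 0] <- NaN
  out
}

check_collapsed <- function(r_correct, r_incorrect, n) {
  if (any(n < 1)) rlang::abort("empty group: n must be >= 1")
  if (any(r_correct < 0 | r_incorrect < 0)) {
    rlang::abort("guess counts must be non-negative")
  }
  if (any(r_correct + r_incorrect > n)) {
    rlang::abort("r_correct + r_incorrect may not exceed n")
  }
  invisible(NULL)
}

#' Wald confidence interval
#'
#' Symmetric normal-quantile interval `point +/- z * sqrt(variance)`. The
#' interval is deliberately not truncated to the index range: a summed Bang
#' index can legitimately report an upper bound above 1. Undefined (`NaN`)
#' inputs propagate.
#'
#' @param point Numeric vector of point estimates.
#' @param variance Numeric vector of variances (non-negative; recycled).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Tibble with columns `ci_lower`, `ci_upper`.
#' @examples
#' wald_ci(6 / 11, bang_variance(6, 0, 11))
#' @export
wald_ci <- function(point, variance, level = 0.95) {
  if (any(variance < 0, na.rm = TRUE)) rlang::abort("variance must be >= 0")
  hw <- z_quantile(level) * sqrt(variance)
  tibble::tibble(ci_lower = point - hw, ci_upper = point + hw)
}

#' Arm-specific Bang blinding estimates
#'
#' Composes [bang_point()], [bang_variance()] and [wald_ci()] over the rows
#' of a collapsed count table, producing one estimate per actual-arm group.
#' Groups with no guessers are flagged `undefined` and carry `NaN` for the
#' point, variance and interval, mirroring how trial reports print such
#' cells.
#'
#' @param collapsed Collapsed count table from [collapse_responses()]
#'   (columns `r_correct`, `r_incorrect`, `r_dontknow`, `n`, plus grouping
#'   columns such as `arm` or `role`, which are carried through).
#' @param level Confidence level, default 0.95.
#' @return Tibble with one row per input row: grouping columns, then
#'   `index` (`"bang_arm"`), `point`, `variance`, `ci_lower`, `ci_upper`,
#'   `level`, `n`, `undefined`.
#' @examples
#' counts <- tibble::tibble(
#'   arm = c("active", "control"),
#'   r_correct = c(6, 5), r_incorrect = c(0, 4), r_dontknow = c(5, 4),
#'   n = c(11, 13)
#' )
#' bang_estimate(counts)
#' @export
bang_estimate <- function(collapsed, level = 0.95) {
  stopifnot(is.data.frame(collapsed))
  need <- c("r_correct", "r_incorrect", "n")
  if (!all(need %in% names(collapsed))) {
    rlang::abort("`collapsed` must contain r_correct, r_incorrect and n columns")
  }
  point <- bang_point(collapsed$r_correct, collapsed$r_incorrect, collapsed$n)
  variance <- bang_variance(collapsed$r_correct, collapsed$r_incorrect, collapsed$n)
  undef <- is.nan(point)
  ci <- wald_ci(ifelse(undef, NaN, point), ifelse(undef, 0, variance), level)
  ci$ci_lower[undef] <- NaN
  ci$ci_upper[undef] <- NaN
  keep <- setdiff(names(collapsed), c("r_correct", "r_incorrect", "r_dontknow", "n"))
  dplyr::bind_cols(
    collapsed[keep],
    tibble::tibble(
      index = "bang_arm", point = point, variance = variance,
      ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
      level = level, n = collapsed$n, undefined = undef
    )
  )
}

#' Summed study-level Bang index
#'
#' The two arm-specific Bang indices can be summed (`BI_active +
#' BI_control`) into a study-level measure of the between-arm difference in
#' proportions holding the same intervention perception; its variance is the
#' sum of the arm variances. By the reporting convention used in trial
#' tables the summands are first rounded to two decimals (so the printed sum
#' equals the sum of the printed arm indices); `rounded = FALSE` gives the
#' exact sum instead. Either arm being undefined makes the sum undefined.
#'
#' @param estimates A two-row `bang_arm` estimate tibble from
#'   [bang_estimate()] (one row per arm).
#' @param rounded Use the rounded-summand reporting convention (default
#'   `TRUE`).
#' @param level Confidence level; defaults to the level of the inputs.
#' @return One-row tibble with `index = "bang_summed"` and the same estimate
#'   columns as [bang_estimate()].
#' @export
summed_bang <- function(estimates, rounded = TRUE, level = NULL) {
  stopifnot(is.data.frame(estimates))
  if (nrow(estimates) != 2 || !all(estimates$index == "bang_arm")) {
    rlang::abort("`estimates` must be exactly two arm-specific Bang estimates")
  }
  level <- level %||% estimates$level[1]
  undef <- any(estimates$undefined)
  if (undef) {
    point <- variance <- lo <- hi <- NaN
  } else {
    point <- if (rounded) sum(round_away(estimates$point, 2)) else sum(estimates$point)
    variance <- sum(estimates$variance)
    ci <- wald_ci(point, variance, level)
    lo <- ci$ci_lower
    hi <- ci$ci_upper
  }
  tibble::tibble(
    index = "bang_summed", point = point, variance = variance,
    ci_lower = lo, ci_upper = hi, level = level,
    n = sum(estimates$n), undefined = undef
  )
}

#' Classify blinding adequacy
#'
#' Operational adequacy thresholds: an arm-specific Bang index between -0.2
#' and 0.2 (boundaries inclusive) suggests adequate blinding; a summed Bang
#' index between -0.3 and 0.3 likewise; for the James index, lack of
#' adequate blinding is suggested when the upper confidence bound falls
#' below 0.5. Undefined estimates classify as `undetermined`.
#'
#' @param estimates Estimate tibble with columns `index`, `point`,
#'   `ci_upper`, `undefined` (as produced by [bang_estimate()],
#'   [summed_bang()] or [james_estimate()]).
#' @return The input with a `classification` column appended
#'   (`"adequate"`, `"not_adequate"` or `"undetermined"`).
#' @examples
#' counts <- tibble::tibble(
#'   arm = c("active", "control"),
#'   r_correct = c(6, 5), r_incorrect = c(0, 4), r_dontknow = c(5, 4),
#'   n = c(11, 13)
#' )
#' bang_estimate(counts) |> classify_blinding()
#' @export
classify_blinding <- function(estimates) {
  stopifnot(is.data.frame(estimates))
  need <- c("index", "point", "ci_upper", "undefined")
  if (!all(need %in% names(estimates))) {
    rlang::abort("`estimates` must carry index, point, ci_upper and undefined columns")
  }
  dplyr::mutate(
    estimates,
    classification = dplyr::case_when(
      .data$undefined ~ "undetermined",
      .data$index == "bang_arm" & abs(.data$point) <= 0.2 ~ "adequate",
      .data$index == "bang_arm" ~ "not_adequate",
      .data$index == "bang_summed" & abs(.data$point) <= 0.3 ~ "adequate",
      .data$index == "bang_summed" ~ "not_adequate",
      .data$index == "james" & .data$ci_upper < 0.5 ~ "not_adequate",
      .data$index == "james" ~ "adequate",
      .default = NA_character_
    )
  )
}
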