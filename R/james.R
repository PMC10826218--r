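#' Signed weights for the James blinding index
#'
#' The weighted James index scores every non-"don't know" response cell by a
#' signed weight: correct guesses pull the index down (towards unblinding),
#' incorrect guesses push it up, and strong beliefs count twice as much as
#' somewhat beliefs. The default scheme is antisymmetric (-1, -0.5, +0.5,
#' +1); custom weights are accepted but a warning is raised if they break
#' antisymmetry, since the index's swap identity then no longer holds.
#'
#' @param w_strong_correct,w_somewhat_correct,w_somewhat_incorrect,w_strong_incorrect
#'   Numeric weights for the four guess cells.
#' @return Named list of the four weights.
#' @export
james_weights <- function(w_strong_correct = -1, w_somewhat_correct = -0.5,
                          w_somewhat_incorrect = 0.5, w_strong_incorrect = 1) {
  w <- list(
    w_strong_correct = w_strong_correct,
    w_somewhat_correct = w_somewhat_correct,
    w_somewhat_incorrect = w_somewhat_incorrect,
    w_strong_incorrect = w_strong_incorrect
  )
  if (!isTRUE(all.equal(w$w_strong_correct, -w$w_strong_incorrect)) ||
      !isTRUE(all.equal(w$w_somewhat_correct, -w$w_somewhat_incorrect))) {
    rlang::warn("James weights are not antisymmetric; the swap identity will not hold")
  }
  w
}

# per-respondent James score: dont_know scores +1, guesses score their
# signed cell weight; the index is (1 + mean(score)) / 2
james_scores <- function(arm, response, weights = james_weights()) {
  direction <- guess_direction(arm, response)
  strength <- guess_strength(response)
  dplyr::case_when(
    direction == "dont_know" ~ 1,
    direction == "correct" & strength == "strongly" ~ weights$w_strong_correct,
    direction == "correct" & strength == "somewhat" ~ weights$w_somewhat_correct,
    direction == "incorrect" & strength == "somewhat" ~ weights$w_somewhat_incorrect,
    direction == "incorrect" & strength == "strongly" ~ weights$w_strong_incorrect
  )
}

#' James blinding index point estimate
#'
#' A study-level blinding index on the pooled respondents of both arms:
#' `BI_J = [1 + P_do + sum_ij w_ij p_ij] / 2`, where `P_do` is the overall
#' "don't know" proportion, `p_ij` the joint proportions of the four
#' non-"don't know" guess cells and `w_ij` the signed weights of
#' [james_weights()]. Under the default weights the index lies in `[0, 1]`:
#' 1 is complete ambivalence (all "don't know"), 0 complete strongly-correct
#' perception, and values near 0.5 are compatible with random guessing.
#'
#' @param counts Count table (columns `arm`, `response`, `count`) pooled
#'   over both arms, e.g. from [tally_responses()]. Pooled `n` must be at
#'   least 1.
#' @param weights Weight scheme from [james_weights()].
#' @return Single numeric value.
#' @examples
#' d <- study_fixture()
#' james_point(tally_responses(d[d$role == "participant", ]))  # 0.53125
#' @export
james_point <- function(counts, weights = james_weights()) {
  stopifnot(is.data.frame(counts))
  if (!all(c("arm", "response", "count") %in% names(counts))) {
    rlang::abort("`counts` must contain arm, response and count columns")
  }
  n <- sum(counts$count)
  if (n < 1) rlang::abort("empty pooled table: no respondents")
  s <- james_scores(counts$arm, counts$response, weights)
  (1 + sum(s * counts$count) / n) / 2
}

#' Percentile-bootstrap confidence interval for the James index
#'
#' The trial literature prints confidence intervals for the James index
#' without a universally agreed closed form; this implementation resamples
#' respondents (with their arm attached) with replacement and takes
#' percentile bounds of the resampled index. Constant data — for example a
#' group whose every answer is "I do not know" — yield a degenerate interval
#' at the point estimate.
#'
#' @param data Respondent-level data frame with `arm` and `response`
#'   columns; one row per respondent.
#' @param level Confidence level, default 0.95.
#' @param n_resamples Number of bootstrap resamples (default 10000; fewer
#'   than 100 triggers a warning).
#' @param seed Optional integer seed for reproducibility.
#' @param weights Weight scheme from [james_weights()].
#' @return Tibble with columns `ci_lower`, `ci_upper`.
#' @export
james_ci <- function(data, level = 0.95, n_resamples = 10000, seed = NULL,
                     weights = james_weights()) {
  stopifnot(is.data.frame(data))
  s <- james_scores(as_arm(data$arm), as_guess(data$response), weights)
  n <- length(s)
  if (n < 1) rlang::abort("empty data: no respondents")
  if (n_resamples < 100) {
    rlang::warn("fewer than 100 bootstrap resamples; interval will be unstable")
  }
  point <- (1 + mean(s)) / 2
  if (length(unique(s)) == 1L) {
    return(tibble::tibble(ci_lower = point, ci_upper = point))
  }
  if (n < 2) rlang::abort("need at least 2 respondents unless data are constant")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  boot <- (1 + colMeans(matrix(s[idx], nrow = n))) / 2
  alpha <- (1 - level) / 2
  q <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(ci_lower = q[1], ci_upper = q[2])
}

#' Study-level James blinding estimate
#'
#' Combines [james_point()] with the percentile bootstrap of [james_ci()]
#' into the same estimate shape as [bang_estimate()], so James rows can sit
#' in the same report table and be classified by [classify_blinding()].
#'
#' @inheritParams james_ci
#' @return One-row tibble with `index = "james"`, `point`, `variance`
#'   (`NA`; no closed form is computed), `ci_lower`, `ci_upper`, `level`,
#'   `n`, `undefined` (always `FALSE`: the James index exists whenever the
#'   pooled table is non-empty).
#' @examples
#' d <- study_fixture()
#' james_estimate(d[d$role == "participant", ], seed = 1, n_resamples = 500)
#' @export
james_estimate <- function(data, level = 0.95, n_resamples = 10000,
                           seed = NULL, weights = james_weights()) {
  counts <- tally_responses(data)
  point <- james_point(counts, weights)
  ci <- james_ci(data, level = level, n_resamples = n_resamples,
                 seed = seed, weights = weights)
  tibble::tibble(
    index = "james", point = point, variance = NA_real_,
    ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
    level = level, n = nrow(data), undefined = FALSE
  )
}
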