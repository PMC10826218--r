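#' Welch unequal-variance mean difference from group summaries
#'
#' Between-group mean difference with an unequal-variance confidence
#' interval computed from the group means, standard deviations and sizes
#' alone: `md = mean1 - mean2`, standard error `sqrt(sd1^2/n1 + sd2^2/n2)`,
#' and degrees of freedom by the Welch-Satterthwaite approximation. This is
#' the interval a two-sample `t.test(..., var.equal = FALSE)` produces on
#' raw data with the same summaries, and it reproduces published
#' range-of-motion contrasts from reported mean (SD) columns. When both
#' standard deviations are zero the interval degenerates to the point
#' difference.
#'
#' @param mean1,sd1,n1 Summary of the first group (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary of the second group.
#' @param level Confidence level, default 0.95.
#' @return One-row tibble: `md`, `se`, `df`, `ci_lower`, `ci_upper`, `level`.
#' @examples
#' # lumbar flexion range of motion, degrees
#' welch_mean_diff(127.9, 18.7, 11, 139.5, 11.5, 13)
#' @export
welch_mean_diff <- function(mean1, sd1, n1, mean2, sd2, n2, level = 0.95) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0, level > 0, level < 1)
  md <- mean1 - mean2
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  if (se == 0) {
    return(tibble::tibble(md = md, se = 0, df = NA_real_,
                          ci_lower = md, ci_upper = md, level = level))
  }
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  hw <- stats::qt(1 - (1 - level) / 2, df) * se
  tibble::tibble(md = md, se = se, df = df,
                 ci_lower = md - hw, ci_upper = md + hw, level = level)
}

#' Summarise a numeric sample the trial-report way
#'
#' Median and interquartile range (type-7 linearly interpolated quantiles,
#' R's default), the summary convention for quantitative baseline and
#' process variables in trial tables.
#'
#' @param x Non-empty numeric vector; `NA`s are dropped with a warning.
#' @return One-row tibble: `n`, `median`, `q25`, `q75`.
#' @examples
#' describe_numeric(c(1, 2, 3, 4))
#' @export
describe_numeric <- function(x) {
  if (anyNA(x)) {
    rlang::warn("dropping NA values")
    x <- x[!is.na(x)]
  }
  if (length(x) == 0) rlang::abort("empty sample")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(n = length(x), median = stats::median(x),
                 q25 = q[1], q75 = q[2])
}

#' Summarise a categorical sample as counts and percentages
#'
#' @param x Non-empty vector of category labels.
#' @param digits Decimal places for the percentage; default 0 (whole
#'   percentages, the trial-table convention).
#' @return Tibble with one row per observed level: `value`, `count`, `pct`.
#'   Percentages sum to 100 up to rounding.
#' @examples
#' describe_categorical(c(rep("female", 7), rep("male", 4)))
#' @export
describe_categorical <- function(x, digits = 0) {
  if (length(x) == 0) rlang::abort("empty sample")
  tibble::tibble(value = x) |>
    dplyr::count(.data$value, name = "count") |>
    dplyr::mutate(pct = round_away(100 * .data$count / sum(.data$count), digits))
}

#' Group summary of a numeric vector
#'
#' Mean, standard deviation and size — the inputs [welch_mean_diff()]
#' expects, for use when raw measurements are available.
#'
#' @param x Numeric vector; `NA`s dropped.
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @export
group_summary <- function(x) {
  x <- x[!is.na(x)]
  tibble::tibble(mean = mean(x), sd = stats::sd(x), n = length(x))
}
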