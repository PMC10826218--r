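#' Precision of a Bang-index estimate: confidence-interval half-width
#'
#' In feasibility settings where the sample size is fixed by circumstance,
#' design thinking is precision-based: rather than powering a test, one asks
#' how wide the confidence interval around the blinding index will be. For
#' assumed correct/incorrect guess proportions the Wald half-width is
#' `z * sqrt([p_c + p_i - (p_c - p_i)^2] / n)`, maximised (for fixed `n`)
#' at `p_c = p_i = 0.5`, the conservative planning default.
#'
#' @param n Sample size per group (vectorised).
#' @param p_correct,p_incorrect Assumed guess proportions; non-negative with
#'   sum at most 1. Defaults 0.5/0.5 (worst case).
#' @param level Confidence level, default 0.95.
#' @return Numeric vector of half-widths (same length as `n`).
#' @examples
#' bi_halfwidth(26)                      # worst case at n = 26: 0.384
#' bi_halfwidth(26, 0.7865, 0.2135)      # narrower under informative guessing
#' @export
bi_halfwidth <- function(n, p_correct = 0.5, p_incorrect = 0.5, level = 0.95) {
  check_assumption(p_correct, p_incorrect)
  if (any(n < 1)) rlang::abort("n must be >= 1")
  v1 <- p_correct + p_incorrect - (p_correct - p_incorrect)^2
  z_quantile(level) * sqrt(v1 / n)
}

#' @rdname bi_halfwidth
#' @param target_halfwidth Desired maximum half-width (> 0).
#' @return `bi_required_n()`: the smallest integer `n` whose half-width does
#'   not exceed the target (1 when the assumed variance is zero).
#' @examples
#' bi_required_n(0.1)                    # 385 under the worst case
#' @export
bi_required_n <- function(target_halfwidth, p_correct = 0.5,
                          p_incorrect = 0.5, level = 0.95) {
  check_assumption(p_correct, p_incorrect)
  if (target_halfwidth <= 0) rlang::abort("target_halfwidth must be > 0")
  v1 <- p_correct + p_incorrect - (p_correct - p_incorrect)^2
  if (v1 == 0) return(1L)
  # half-width is z*sqrt(v1/n) <= t  <=>  n >= z^2 v1 / t^2; fuzz guards the
  # exact fixed point required_n(halfwidth(n)) == n against float noise
  as.integer(max(1, ceiling(z_quantile(level)^2 * v1 / target_halfwidth^2 - 1e-9)))
}

check_assumption <- function(p_correct, p_incorrect) {
  if (any(p_correct < 0) || any(p_incorrect < 0) ||
      any(p_correct + p_incorrect > 1 + 1e-12)) {
    rlang::abort("need p_correct, p_incorrect >= 0 with p_correct + p_incorrect <= 1")
  }
  invisible(NULL)
}

#' Design table and plot: half-width against sample size
#'
#' @param n Integer vector of sample sizes to tabulate.
#' @inheritParams bi_halfwidth
#' @return `design_grid()`: tibble with columns `n`, `halfwidth`,
#'   `ci_width` (twice the half-width), `p_correct`, `p_incorrect`, `level`.
#' @examples
#' design_grid(c(10, 26, 50, 100))
#' @export
design_grid <- function(n, p_correct = 0.5, p_incorrect = 0.5, level = 0.95) {
  hw <- bi_halfwidth(n, p_correct, p_incorrect, level)
  tibble::tibble(
    n = as.integer(n), halfwidth = hw, ci_width = 2 * hw,
    p_correct = p_correct, p_incorrect = p_incorrect, level = level
  )
}

#' @rdname design_grid
#' @return `plot_design_curve()`: a ggplot of half-width versus `n`.
#' @export
plot_design_curve <- function(n, p_correct = 0.5, p_incorrect = 0.5,
                              level = 0.95) {
  grid <- design_grid(n, p_correct, p_incorrect, level)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$n, y = .data$halfwidth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "sample size per group",
      y = sprintf("%d%% CI half-width of the Bang index", round(level * 100)),
      title = "Precision-based design for the Bang blinding index",
      subtitle = sprintf("assumed p_correct = %.2f, p_incorrect = %.2f",
                         p_correct, p_incorrect)
    ) +
    ggplot2::theme_minimal()
}
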