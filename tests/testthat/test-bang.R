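test_that("collapsing merges strength levels by direction and keeps don't knows", {
  counts <- tibble::tibble(
    arm = "active",
    response = guess_levels(),
    count = c(6, 0, 5, 0, 0)
  )
  out <- collapse_responses(counts)
  expect_equal(out$r_correct, 6)
  expect_equal(out$r_incorrect, 0)
  expect_equal(out$r_dontknow, 5)
  expect_equal(out$n, 11)

  counts2 <- tibble::tibble(
    arm = "control",
    response = guess_levels(),
    count = c(3, 1, 4, 5, 0)
  )
  out2 <- collapse_responses(counts2)
  expect_equal(
    unlist(out2[c("r_correct", "r_incorrect", "r_dontknow", "n")]),
    c(r_correct = 5, r_incorrect = 4, r_dontknow = 4, n = 13)
  )

  all_dk <- tibble::tibble(arm = "active", response = guess_levels(),
                           count = c(0, 0, 7, 0, 0))
  out3 <- collapse_responses(all_dk)
  expect_equal(unlist(out3[c("r_correct", "r_incorrect", "r_dontknow")]),
               c(r_correct = 0, r_incorrect = 0, r_dontknow = 7))

  zero <- tibble::tibble(arm = "control", response = guess_levels(), count = 0)
  expect_equal(collapse_responses(zero)$n, 0)
})

test_that("Bang point estimate follows (correct - incorrect)/n with a NaN sentinel", {
  expect_equal(bang_point(6, 0, 11), 6 / 11, tolerance = 1e-12)
  expect_equal(bi_round(bang_point(6, 0, 11)), 0.55)
  expect_true(is.nan(bang_point(0, 0, 24)))
  expect_equal(bang_point(11, 0, 11), 1)
  expect_error(bang_point(0, 0, 0), "empty group")
  expect_error(bang_point(7, 7, 10), "exceed")
})

test_that("Bang variance matches the plug-in formula", {
  # exact rational forms: (r_c + r_i - (r_c - r_i)^2/n) / n^2
  expect_equal(bang_variance(6, 0, 11), 30 / 1331, tolerance = 1e-12)
  expect_equal(bang_variance(5, 4, 13), 116 / 2197, tolerance = 1e-12)
  expect_equal(bang_variance(11, 0, 11), 0)
  expect_true(is.nan(bang_variance(0, 0, 5)))
})

test_that("Wald intervals reproduce the published participant CIs", {
  ci <- wald_ci(bang_point(6, 0, 11), bang_variance(6, 0, 11))
  expect_equal(c(ci$ci_lower, ci$ci_upper), c(0.2512025, 0.8397066),
               tolerance = 1e-6)
  expect_equal(bi_round(c(ci$ci_lower, ci$ci_upper)), c(0.25, 0.84))

  ci2 <- wald_ci(bang_point(5, 4, 13), bang_variance(5, 4, 13))
  expect_equal(bi_round(c(ci2$ci_lower, ci2$ci_upper)), c(-0.37, 0.53))

  degenerate <- wald_ci(0.4, 0)
  expect_equal(c(degenerate$ci_lower, degenerate$ci_upper), c(0.4, 0.4))
  expect_error(wald_ci(0, -1), "variance")
})

test_that("bang_estimate composes the pipeline and flags undefined groups", {
  counts <- study_counts() |> dplyr::filter(role == "participant") |>
    dplyr::select(-role)
  est <- bang_estimate(counts)
  expect_equal(bi_round(est$point), c(0.55, 0.08))
  expect_equal(bi_round(est$ci_lower), c(0.25, -0.37))
  expect_equal(bi_round(est$ci_upper), c(0.84, 0.53))
  expect_false(any(est$undefined))
  expect_true(all(est$ci_lower <= est$point & est$point <= est$ci_upper))

  silent <- bang_estimate(tibble::tibble(
    arm = "active", r_correct = 0, r_incorrect = 0, r_dontknow = 24, n = 24))
  expect_true(silent$undefined)
  expect_true(is.nan(silent$point) && is.nan(silent$ci_upper))
})

test_that("summed Bang index follows the rounded-summand reporting convention", {
  counts <- study_counts() |> dplyr::filter(role == "participant") |>
    dplyr::select(-role)
  est <- bang_estimate(counts)
  s <- summed_bang(est)
  expect_equal(s$point, 0.63)
  expect_equal(bi_round(c(s$ci_lower, s$ci_upper)), c(0.09, 1.17))
  expect_gt(s$ci_upper, 1) # intervals are not clipped to the index range

  exact <- summed_bang(est, rounded = FALSE)
  expect_equal(exact$point, 6 / 11 + 1 / 13, tolerance = 1e-12)

  # either arm undefined poisons the sum
  undef <- bang_estimate(tibble::tibble(
    arm = c("active", "control"),
    r_correct = c(0, 5), r_incorrect = c(0, 4), r_dontknow = c(11, 4),
    n = c(11, 13)))
  expect_true(summed_bang(undef)$undefined)

  # degenerate zero-point, zero-variance arms sum to a degenerate zero
  zero <- tibble::tibble(
    index = "bang_arm", point = 0, variance = 0, ci_lower = 0, ci_upper = 0,
    level = 0.95, n = c(10L, 10L), undefined = FALSE)
  z <- summed_bang(zero)
  expect_equal(c(z$point, z$ci_lower, z$ci_upper), c(0, 0, 0))
})

test_that("adequacy classification applies the index-specific thresholds", {
  est <- tibble::tibble(
    index = c("bang_arm", "bang_arm", "bang_arm", "bang_summed",
              "bang_summed", "james", "james"),
    point = c(0.55, 0.08, 0.2, 0.63, 0.3, 1, 0.3),
    ci_upper = c(0.84, 0.53, 0.5, 1.17, 0.6, 1, 0.45),
    undefined = FALSE
  )
  got <- classify_blinding(est)$classification
  expect_equal(got, c("not_adequate", "adequate", "adequate", "not_adequate",
                      "adequate", "adequate", "not_adequate"))

  undef <- classify_blinding(tibble::tibble(
    index = "bang_arm", point = NaN, ci_upper = NaN, undefined = TRUE))
  expect_equal(undef$classification, "undetermined")
})

test_that("Bang index is bounded, antisymmetric under guess reversal, and
           relabelling-invariant in variance", {
  set.seed(101)
  for (i in 1:200) {
    tb <- random_collapsed()
    if (tb$r_correct + tb$r_incorrect == 0) next
    p <- bang_point(tb$r_correct, tb$r_incorrect, tb$n)
    v <- bang_variance(tb$r_correct, tb$r_incorrect, tb$n)
    p_sw <- bang_point(tb$r_incorrect, tb$r_correct, tb$n)
    v_sw <- bang_variance(tb$r_incorrect, tb$r_correct, tb$n)
    expect_gte(p, -1); expect_lte(p, 1)
    expect_equal(p_sw, -p, tolerance = 1e-12)
    expect_equal(v_sw, v, tolerance = 1e-12)
    expect_gte(v, 0)
  }
  # zero variance iff all guessers agree and p_c + p_i = (p_c - p_i)^2
  expect_equal(bang_variance(9, 0, 9), 0)
  expect_gt(bang_variance(8, 0, 9), 0)
  expect_gt(bang_variance(4, 4, 8), 0)
})
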