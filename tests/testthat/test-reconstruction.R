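test_that("published participant estimates reconstruct to unique count triples", {
  r1 <- reconstruct_counts(0.55, 0.25, 0.84, n = 11)
  expect_equal(nrow(r1), 1)
  expect_true(all(r1$unique))
  expect_equal(unlist(r1[1, c("r_correct", "r_incorrect", "r_dontknow")]),
               c(r_correct = 6L, r_incorrect = 0L, r_dontknow = 5L))

  r2 <- reconstruct_counts(0.08, -0.37, 0.53, n = 13)
  expect_equal(unlist(r2[1, c("r_correct", "r_incorrect", "r_dontknow")]),
               c(r_correct = 5L, r_incorrect = 4L, r_dontknow = 4L))
  expect_true(all(r2$unique))

  r3 <- reconstruct_counts(1.00, 1.00, 1.00, n = 11)
  expect_equal(nrow(r3), 1)
  expect_equal(r3$r_correct, 11L)
})

test_that("every published per-assessor estimate reconstructs uniquely", {
  queries <- list(
    list(0.27, -0.09, 0.64, 11, c(4, 1, 6)),
    list(-0.23, -0.54, 0.08, 13, c(1, 4, 8)),
    list(0.00, -0.50, 0.50, 11, c(4, 4, 3)),
    list(-0.08, -0.53, 0.37, 13, c(4, 5, 4))
  )
  for (q in queries) {
    r <- reconstruct_counts(q[[1]], q[[2]], q[[3]], n = q[[4]])
    expect_equal(nrow(r), 1)
    expect_equal(c(r$r_correct, r$r_incorrect, r$r_dontknow), q[[5]])
  }
})

test_that("pooling the per-assessor reconstructions reproduces the pooled indices", {
  fixture <- study_fixture() |>
    dplyr::filter(role != "participant") |>
    tally_responses() |>
    collapse_responses()
  pooled <- fixture |>
    dplyr::summarise(dplyr::across(c(r_correct, r_incorrect, r_dontknow, n), sum),
                     .by = arm)
  expect_equal(pooled$r_correct[pooled$arm == "active"], 8)
  expect_equal(pooled$r_incorrect[pooled$arm == "active"], 5)
  expect_equal(pooled$n[pooled$arm == "active"], 33)
  expect_equal(pooled$r_correct[pooled$arm == "control"], 5)
  expect_equal(pooled$r_incorrect[pooled$arm == "control"], 9)
  expect_equal(pooled$n[pooled$arm == "control"], 39)

  est <- bang_estimate(pooled)
  expect_equal(bi_round(est$point), c(0.09, -0.10))
  expect_equal(bi_round(est$ci_lower), c(-0.12, -0.29))
  expect_equal(bi_round(est$ci_upper), c(0.30, 0.08))
})

test_that("reconstruction round-trips random tables", {
  set.seed(303)
  for (i in 1:200) {
    tb <- random_collapsed(30)
    if (tb$r_correct + tb$r_incorrect == 0) next
    pt <- bang_point(tb$r_correct, tb$r_incorrect, tb$n)
    ci <- wald_ci(pt, bang_variance(tb$r_correct, tb$r_incorrect, tb$n))
    r <- reconstruct_counts(bi_round(pt), bi_round(ci$ci_lower),
                            bi_round(ci$ci_upper), n = tb$n)
    expect_true(any(r$r_correct == tb$r_correct &
                      r$r_incorrect == tb$r_incorrect))
  }
})

test_that("the packaged fixture has the documented structure and counts", {
  d <- study_fixture()
  expect_equal(nrow(d), 96)
  expect_equal(length(unique(d$participant_id)), 24)
  expect_equal(sort(unique(d$role)),
               c("assessor_1", "assessor_2", "assessor_3", "participant"))
  # one row per participant per role; arm and stratum fixed within participant
  expect_equal(nrow(dplyr::distinct(d, participant_id, role)), 96)
  per_id <- dplyr::summarise(d, arms = dplyr::n_distinct(arm),
                             strata = dplyr::n_distinct(stratum),
                             .by = participant_id)
  expect_true(all(per_id$arms == 1) && all(per_id$strata == 1))
  expect_equal(sum(d$stratum[d$role == "participant"]), 7)

  collapsed <- d |> tally_responses(by = "role") |> collapse_responses() |>
    dplyr::arrange(role, arm)
  a1 <- dplyr::filter(collapsed, role == "assessor_1")
  expect_equal(a1$r_dontknow, a1$n)
  expected <- study_counts() |> dplyr::arrange(role, arm)
  got <- collapsed |> dplyr::filter(role != "assessor_1") |>
    dplyr::arrange(role, arm)
  expect_equal(got[c("role", "arm", "r_correct", "r_incorrect", "r_dontknow", "n")],
               expected, ignore_attr = TRUE)
})

test_that("the fixture's strength splits reproduce every printed James value", {
  d <- study_fixture()
  for (r in names(printed_james())) {
    sub <- if (r == "assessors_pooled") {
      dplyr::filter(d, role != "participant")
    } else {
      dplyr::filter(d, role == r)
    }
    expect_equal(bi_round(james_point(tally_responses(sub))),
                 unname(printed_james()[r]), info = r)
  }
})
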