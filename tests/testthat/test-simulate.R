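test_that("permuted blocks balance arms and bound prefix imbalance", {
  one_block <- permuted_block_randomize(rep(0, 4), block_sizes = 4, seed = 1)
  expect_equal(sort(table(one_block$arm)), sort(c(active = 2, control = 2)),
               ignore_attr = TRUE)

  a <- permuted_block_randomize(rep(0:1, 12), seed = 99)
  b <- permuted_block_randomize(rep(0:1, 12), seed = 99)
  expect_identical(a, b)

  set.seed(808)
  strata <- sample(0:1, 5000, replace = TRUE)
  alloc <- permuted_block_randomize(strata, block_sizes = c(2, 4))
  for (s in 0:1) {
    arm_s <- alloc$arm[alloc$stratum == s]
    imbalance <- abs(cumsum(arm_s == "active") - cumsum(arm_s == "control"))
    expect_lte(max(imbalance), 2) # max(block_sizes) / 2
  }

  expect_error(permuted_block_randomize(1:4, block_sizes = c(2, 3)), "even")
  expect_error(permuted_block_randomize(integer(0)), "at least one")
})

test_that("guess simulation hits its deterministic corners and recovers theta", {
  all_dk <- simulate_guesses(rep("active", 30),
                             guess_behaviour(0, 0, 1), seed = 1)
  expect_true(all(all_dk == "dont_know"))

  sure <- simulate_guesses(c(rep("active", 10), rep("control", 10)),
                           guess_behaviour(1, 0, 0, strong_fraction = 1),
                           seed = 1)
  d <- tibble::tibble(arm = c(rep("active", 10), rep("control", 10)),
                      response = sure)
  est <- bang_estimate(collapse_responses(tally_responses(d)))
  expect_equal(est$point, c(1, 1))

  # law of large numbers: the Bang index estimates theta_c - theta_i
  arm <- rep("active", 10000)
  g <- simulate_guesses(arm, guess_behaviour(0.55, 0, 0.45), seed = 11)
  col <- collapse_responses(tally_responses(tibble::tibble(arm = arm, response = g)))
  col <- col[col$arm == "active", ]
  bi <- bang_point(col$r_correct, col$r_incorrect, col$n)
  expect_lt(abs(bi - 0.55), 0.03)
  se3 <- 3 * sqrt(bang_variance(col$r_correct, col$r_incorrect, col$n))
  expect_lt(abs(bi - 0.55), se3)

  expect_error(guess_behaviour(0.5, 0.5, 0.5), "sum to 1")
  expect_error(guess_behaviour(0.5, 0.3, 0.2, strong_fraction = 2), "strong_fraction")
})

test_that("ROM simulation respects its degenerate and stochastic contracts", {
  exact <- simulate_rom(5, 100, 0, effect = 0, resid_sd = 0, seed = 3)
  expect_equal(exact$post, exact$pre)
  expect_true(all(exact$pre == 100))

  draws <- simulate_rom(10000, 127, 17, effect = 3.5, resid_sd = 7.9, seed = 4)
  expect_equal(mean(draws$post - draws$pre), 3.5, tolerance = 0.3 / 3.5)

  expect_error(simulate_rom(5, 100, -1, 0, 1), "deviations")
})

test_that("simulate_trial composes a valid, reproducible respondent-level dataset", {
  cfg <- scenario_config(seed = 42)
  d1 <- simulate_trial(cfg)
  d2 <- simulate_trial(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 24 * 4)
  expect_silent(validate_trial_data(d1))
  expect_equal(nrow(dplyr::distinct(d1, participant_id, role)), 96)
  # arm fixed across roles; ROM only on participant rows
  expect_true(all(tapply(d1$arm, d1$participant_id,
                         function(a) length(unique(a))) == 1))
  expect_true(all(is.na(d1$rom_post_flexion[d1$role != "participant"])))
  expect_true(all(!is.na(d1$rom_post_flexion[d1$role == "participant"])))

  # byte-identical CSV round trip for a fixed seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_responses_csv(simulate_trial(cfg), f1)
  write_responses_csv(simulate_trial(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  empty <- simulate_trial(scenario_config(n_participants = 0, seed = 1))
  expect_equal(nrow(empty), 0)
  expect_error(run_analysis(empty), "empty")
})

test_that("Wald intervals attain nominal coverage under the multinomial guess model", {
  set.seed(909)
  reps <- 2000; n <- 200; theta <- c(0.5, 0.3, 0.2)
  counts <- stats::rmultinom(reps, n, theta)
  pt <- bang_point(counts[1, ], counts[2, ], n)
  ci <- wald_ci(pt, bang_variance(counts[1, ], counts[2, ], n))
  covered <- ci$ci_lower <= 0.2 & 0.2 <= ci$ci_upper
  expect_equal(mean(covered), 0.95, tolerance = 0.02 / 0.95)
})

test_that("a strongly unblinded scenario is flagged not_adequate almost surely", {
  set.seed(110)
  reps <- 1000; n <- 100
  counts <- stats::rmultinom(reps, n, c(0.9, 0.05, 0.05))
  est <- tibble::tibble(
    index = "bang_arm",
    point = bang_point(counts[1, ], counts[2, ], n),
    ci_upper = NA_real_, undefined = FALSE
  ) |> classify_blinding()
  expect_gte(mean(est$classification == "not_adequate"), 0.95)
})

test_that("scenario configs validate their fields and read from JSON", {
  expect_error(scenario_config(block_sizes = c(3, 4)), "even")
  expect_error(scenario_config(stratum_prevalence = 1.5), "prevalence")
  expect_error(scenario_config(roles = list(a = guess_behaviour(1, 0, 0))),
               "participant")

  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_participants = 12, seed = 7), f, auto_unbox = TRUE)
  cfg <- scenario_from_json(f)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$n_participants, 12L)
  expect_equal(nrow(simulate_trial(cfg)), 12 * 4)

  jsonlite::write_json(list(bogus = 1), f, auto_unbox = TRUE)
  expect_error(scenario_from_json(f), "unknown scenario keys")
})
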