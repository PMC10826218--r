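#' Guess-behaviour parameters for one respondent role
#'
#' A respondent's answer to the perception question is modelled as a
#' multinomial draw: with probability `theta_correct` the guess points at
#' the actual arm, with `theta_incorrect` at the other arm, and with
#' `theta_dontknow` the answer is "I do not know". A directional guess is
#' "strongly" held with probability `strong_fraction`, else "somewhat".
#' Under this model the Bang index estimates `theta_correct -
#' theta_incorrect`; the strength split moves only the James index.
#'
#' @param theta_correct,theta_incorrect,theta_dontknow Probabilities summing
#'   to 1.
#' @param strong_fraction Probability a directional guess is strong;
#'   default 0.5.
#' @return Named list with class `"guess_behaviour"`.
#' @examples
#' guess_behaviour(0.55, 0, 0.45)
#' @export
guess_behaviour <- function(theta_correct, theta_incorrect, theta_dontknow,
                            strong_fraction = 0.5) {
  theta <- c(theta_correct, theta_incorrect, theta_dontknow)
  if (any(theta < 0) || abs(sum(theta) - 1) > 1e-8) {
    rlang::abort("theta_correct, theta_incorrect and theta_dontknow must be non-negative and sum to 1")
  }
  if (strong_fraction < 0 || strong_fraction > 1) {
    rlang::abort("strong_fraction must lie in [0, 1]")
  }
  structure(
    list(theta_correct = theta_correct, theta_incorrect = theta_incorrect,
         theta_dontknow = theta_dontknow, strong_fraction = strong_fraction),
    class = "guess_behaviour"
  )
}

#' Scenario configuration for the synthetic trial generator
#'
#' Defaults emulate the source feasibility trial: 24 participants allocated
#' 1:1 by permuted blocks of sizes 2 and 4 within two strata of a binary
#' covariate (prior manual-therapy experience, prevalence 7/24); one
#' participant role and three outcome-assessor roles whose guess behaviour
#' defaults to the study's observed pooled proportions; and normally
#' distributed flexion/extension range-of-motion outcomes (degrees) with
#' per-arm pre-intervention distributions and additive intervention effects
#' taken from the published group summaries.
#'
#' @param n_participants Number of participants (default 24).
#' @param stratum_prevalence Probability of the stratum-1 covariate
#'   (default 7/24).
#' @param block_sizes Even block sizes for the permuted-block scheme
#'   (default `c(2, 4)`).
#' @param roles Named list of [guess_behaviour()] objects, one per
#'   respondent role.
#' @param rom Nested list: per measure (`flexion`, `extension`), per arm,
#'   a list with `pre_mean`, `pre_sd`, `effect`, `resid_sd` (degrees).
#' @param seed Optional integer seed used by [simulate_trial()].
#' @return Validated list with class `"scenario_config"`.
#' @export
scenario_config <- function(n_participants = 24,
                            stratum_prevalence = 7 / 24,
                            block_sizes = c(2, 4),
                            roles = default_roles(),
                            rom = default_rom(),
                            seed = NULL) {
  if (n_participants < 0) rlang::abort("n_participants must be >= 0")
  if (stratum_prevalence < 0 || stratum_prevalence > 1) {
    rlang::abort("stratum_prevalence must lie in [0, 1]")
  }
  check_block_sizes(block_sizes)
  if (!is.list(roles) || is.null(names(roles)) || !"participant" %in% names(roles)) {
    rlang::abort("roles must be a named list including a 'participant' entry")
  }
  roles <- purrr::map(roles, function(b) {
    if (inherits(b, "guess_behaviour")) b else do.call(guess_behaviour, b)
  })
  for (m in rom) {
    for (a in m) {
      if (a$pre_sd < 0 || a$resid_sd < 0) {
        rlang::abort("ROM standard deviations must be >= 0")
      }
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         stratum_prevalence = stratum_prevalence,
         block_sizes = as.integer(block_sizes),
         roles = roles, rom = rom, seed = seed),
    class = "scenario_config"
  )
}

check_block_sizes <- function(block_sizes) {
  if (length(block_sizes) == 0 || any(block_sizes < 2) ||
      any(block_sizes %% 2 != 0)) {
    rlang::abort("block_sizes must be even integers >= 2")
  }
  invisible(NULL)
}

#' @rdname scenario_config
#' @export
default_roles <- function() {
  list(
    participant = guess_behaviour(11 / 24, 4 / 24, 9 / 24),
    assessor_1 = guess_behaviour(0, 0, 1),
    assessor_2 = guess_behaviour(5 / 24, 5 / 24, 14 / 24),
    assessor_3 = guess_behaviour(8 / 24, 9 / 24, 7 / 24)
  )
}

#' @rdname scenario_config
#' @export
default_rom <- function() {
  list(
    flexion = list(
      active = list(pre_mean = 127.0, pre_sd = 17.0, effect = 3.5, resid_sd = 7.9),
      control = list(pre_mean = 132.0, pre_sd = 9.0, effect = 3.7, resid_sd = 4.3)
    ),
    extension = list(
      active = list(pre_mean = 43.0, pre_sd = 19.0, effect = 2.0, resid_sd = 5.7),
      control = list(pre_mean = 44.0, pre_sd = 13.5, effect = 1.5, resid_sd = 5.3)
    )
  )
}

#' Read a scenario configuration from JSON
#'
#' @param path Path to a JSON file whose keys mirror the arguments of
#'   [scenario_config()]; absent keys keep their defaults.
#' @return A `"scenario_config"` object.
#' @export
scenario_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("n_participants", "stratum_prevalence", "block_sizes",
             "roles", "rom", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown scenario keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, raw)
}

#' Stratified permuted-block randomisation
#'
#' Within each stratum, allocation proceeds in blocks whose sizes are drawn
#' uniformly at random from `block_sizes`; each block is a random
#' permutation of an equal number of active and control labels, so arm
#' imbalance within a stratum never exceeds half the largest block size at
#' any point in the allocation sequence. The final block is truncated at
#' the stratum's size.
#'
#' @param strata Vector of stratum labels, one per subject, in enrolment
#'   order.
#' @param block_sizes Even block sizes (default `c(2, 4)`).
#' @param seed Optional integer seed.
#' @return Tibble with columns `id` (position in `strata`), `stratum`,
#'   `arm`.
#' @examples
#' permuted_block_randomize(rep(0, 8), seed = 1)
#' @export
permuted_block_randomize <- function(strata, block_sizes = c(2, 4), seed = NULL) {
  if (length(strata) < 1) rlang::abort("need at least one subject")
  check_block_sizes(block_sizes)
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::tibble(id = seq_along(strata), stratum = strata,
                        arm = NA_character_)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    seq_arm <- character(0)
    while (length(seq_arm) < length(idx)) {
      b <- if (length(block_sizes) == 1) block_sizes else sample(block_sizes, 1)
      seq_arm <- c(seq_arm, sample(rep(arm_levels(), b / 2)))
    }
    out$arm[idx] <- seq_arm[seq_along(idx)]
  }
  out
}

#' Simulate five-level guesses for one role
#'
#' @param arm Character vector of actual arms, one per respondent.
#' @param behaviour A [guess_behaviour()] object.
#' @param seed Optional integer seed.
#' @return Character vector of response tokens.
#' @examples
#' simulate_guesses(rep("active", 5), guess_behaviour(1, 0, 0), seed = 1)
#' @export
simulate_guesses <- function(arm, behaviour, seed = NULL) {
  arm <- as_arm(arm)
  if (!inherits(behaviour, "guess_behaviour")) {
    behaviour <- do.call(guess_behaviour, behaviour)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(arm)
  direction <- sample(
    c("correct", "incorrect", "dont_know"), n, replace = TRUE,
    prob = c(behaviour$theta_correct, behaviour$theta_incorrect,
             behaviour$theta_dontknow)
  )
  strong <- stats::runif(n) < behaviour$strong_fraction
  guessed_arm <- dplyr::case_when(
    direction == "correct" ~ arm,
    direction == "incorrect" & arm == "active" ~ "control",
    direction == "incorrect" ~ "active",
    .default = NA_character_
  )
  dplyr::case_when(
    direction == "dont_know" ~ "dont_know",
    strong ~ paste0("strongly_", guessed_arm),
    .default = paste0("somewhat_", guessed_arm)
  )
}

#' Simulate pre/post range-of-motion measurements
#'
#' Pre-intervention values are normal with the given mean and sd; post
#' equals pre plus the additive intervention effect plus normal residual
#' noise, so zero effect and zero noise reproduce the pre values exactly.
#'
#' @param n Number of participants.
#' @param pre_mean,pre_sd Pre-intervention distribution (degrees).
#' @param effect Additive intervention effect on the post value (degrees).
#' @param resid_sd Residual sd of the change score (degrees).
#' @param seed Optional integer seed.
#' @return Tibble with columns `pre`, `post`.
#' @export
simulate_rom <- function(n, pre_mean, pre_sd, effect, resid_sd, seed = NULL) {
  if (pre_sd < 0 || resid_sd < 0) rlang::abort("standard deviations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  pre <- stats::rnorm(n, pre_mean, pre_sd)
  post <- pre + effect + stats::rnorm(n, 0, resid_sd)
  tibble::tibble(pre = pre, post = post)
}

#' Simulate a complete blinding-assessment trial
#'
#' End-to-end composition: binary stratum draws, stratified permuted-block
#' 1:1 randomisation, one five-level guess per participant per role, and
#' pre/post flexion and extension range-of-motion measurements for
#' participants. The output is the long respondent-level format the
#' analysis pipeline ingests (one row per participant-role; ROM columns
#' populated on participant rows only). All randomness flows through a
#' single seeded generator, so identical config and seed reproduce the
#' dataset exactly.
#'
#' @param config A [scenario_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return Tibble with columns `participant_id`, `stratum`, `arm`, `role`,
#'   `response`, `rom_pre_flexion`, `rom_post_flexion`,
#'   `rom_pre_extension`, `rom_post_extension`. Zero participants yield a
#'   zero-row tibble with the same columns.
#' @examples
#' d <- simulate_trial(scenario_config(seed = 42))
#' dplyr::count(d, role, arm)
#' @export
simulate_trial <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  cols <- c("participant_id", "stratum", "arm", "role", "response",
            "rom_pre_flexion", "rom_post_flexion",
            "rom_pre_extension", "rom_post_extension")
  if (n == 0) {
    return(tibble::as_tibble(stats::setNames(
      c(list(character(0), integer(0), character(0), character(0), character(0)),
        rep(list(numeric(0)), 4)), cols)))
  }
  stratum <- stats::rbinom(n, 1, config$stratum_prevalence)
  alloc <- permuted_block_randomize(stratum, config$block_sizes)
  ids <- sprintf("S%03d", seq_len(n))

  rom <- purrr::imap(config$rom, function(m, measure) {
    out <- tibble::tibble(pre = rep(NA_real_, n), post = rep(NA_real_, n))
    for (a in arm_levels()) {
      idx <- which(alloc$arm == a)
      p <- m[[a]]
      draws <- simulate_rom(length(idx), p$pre_mean, p$pre_sd, p$effect, p$resid_sd)
      out$pre[idx] <- draws$pre
      out$post[idx] <- draws$post
    }
    out
  })

  purrr::imap(config$roles, function(behaviour, role) {
    rec <- tibble::tibble(
      participant_id = ids, stratum = stratum, arm = alloc$arm, role = role,
      response = simulate_guesses(alloc$arm, behaviour),
      rom_pre_flexion = NA_real_, rom_post_flexion = NA_real_,
      rom_pre_extension = NA_real_, rom_post_extension = NA_real_
    )
    if (role == "participant") {
      rec$rom_pre_flexion <- rom$flexion$pre
      rec$rom_post_flexion <- rom$flexion$post
      rec$rom_pre_extension <- rom$extension$pre
      rec$rom_post_extension <- rom$extension$post
    }
    rec
  }) |>
    dplyr::bind_rows()
}
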