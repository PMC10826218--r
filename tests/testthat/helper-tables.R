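# collapsed count tables uniquely reconstructed from the published report,
# shared across test files
study_counts <- function() {
  tibble::tibble(
    role = rep(c("participant", "assessor_2", "assessor_3"), each = 2),
    arm = rep(c("active", "control"), 3),
    r_correct = c(6, 5, 4, 1, 4, 4),
    r_incorrect = c(0, 4, 1, 4, 4, 5),
    r_dontknow = c(5, 4, 6, 8, 3, 4),
    n = c(11, 13, 11, 13, 11, 13)
  )
}

# printed two-decimal Bang values: point, ci_lower, ci_upper per (role, arm)
printed_bang <- function() {
  tibble::tibble(
    role = c("participant", "participant", "assessor_1", "assessor_1",
             "assessor_2", "assessor_2", "assessor_3", "assessor_3",
             "assessors_pooled", "assessors_pooled"),
    arm = rep(c("active", "control"), 5),
    point = c(0.55, 0.08, NaN, NaN, 0.27, -0.23, 0.00, -0.08, 0.09, -0.10),
    ci_lower = c(0.25, -0.37, NaN, NaN, -0.09, -0.54, -0.50, -0.53, -0.12, -0.29),
    ci_upper = c(0.84, 0.53, NaN, NaN, 0.64, 0.08, 0.50, 0.37, 0.30, 0.08)
  )
}

# printed James point values per role (study level, pooled arms)
printed_james <- function() {
  c(participant = 0.53, assessor_1 = 1.00, assessor_2 = 0.79,
    assessor_3 = 0.67, assessors_pooled = 0.82)
}

# a random collapsed table: n respondents split over (correct, incorrect, dk)
random_collapsed <- function(n_max = 40) {
  n <- sample(1:n_max, 1)
  counts <- as.vector(stats::rmultinom(1, n, c(1, 1, 1) / 3))
  list(r_correct = counts[1], r_incorrect = counts[2],
       r_dontknow = counts[3], n = n)
}
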