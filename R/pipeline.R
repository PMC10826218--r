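role_levels <- function() {
  c("participant", "assessor_1", "assessor_2", "assessor_3")
}

#' Read and write respondent-level trial data
#'
#' The pipeline's interchange format is a UTF-8 comma-separated file with a
#' header and one row per respondent-role: `participant_id` (string),
#' `role` (`participant`, `assessor_1`, `assessor_2`, `assessor_3`), `arm`
#' (`active`/`control`), `response` (see [guess_levels()]), optional
#' `stratum` (0/1) and optional numeric range-of-motion columns
#' `rom_pre_flexion`, `rom_post_flexion`, `rom_pre_extension`,
#' `rom_post_extension` (degrees). Validation failures report the offending
#' rows; a write followed by a read round-trips the dataset.
#'
#' @param path File path.
#' @return `read_responses_csv()`: a validated tibble.
#' @export
read_responses_csv <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    role = readr::col_character(),
    arm = readr::col_character(),
    response = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_trial_data(data)
}

#' @rdname read_responses_csv
#' @param data Respondent-level data frame.
#' @return `write_responses_csv()`: the input, invisibly.
#' @export
write_responses_csv <- function(data, path) {
  readr::write_csv(validate_trial_data(data), path)
  invisible(data)
}

#' Validate a respondent-level trial dataset
#'
#' Checks the presence of the required columns, the admissibility of role,
#' arm and response tokens (reporting row numbers), uniqueness of
#' (participant, role) pairs, and that every participant keeps one arm
#' across roles.
#'
#' @param data Respondent-level data frame.
#' @return The validated data as a tibble.
#' @export
validate_trial_data <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("participant_id", "role", "arm", "response")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  report_bad <- function(ok, what, values) {
    if (all(ok)) return(invisible(NULL))
    rows <- which(!ok)
    rlang::abort(sprintf(
      "invalid %s token(s) %s at data row(s) %s", what,
      paste(unique(values[!ok]), collapse = ", "),
      paste(utils::head(rows, 5), collapse = ", ")
    ), class = "blindex_invalid_data")
  }
  report_bad(data$role %in% role_levels(), "role", data$role)
  report_bad(data$arm %in% arm_levels(), "arm", data$arm)
  report_bad(data$response %in% guess_levels(), "response", data$response)
  dup <- duplicated(data[c("participant_id", "role")])
  if (any(dup)) {
    rlang::abort(sprintf(
      "duplicate (participant_id, role) pair(s) at data row(s) %s",
      paste(utils::head(which(dup), 5), collapse = ", ")
    ), class = "blindex_invalid_data")
  }
  arms_per_id <- tapply(data$arm, data$participant_id,
                        function(a) length(unique(a)))
  if (any(arms_per_id > 1)) {
    rlang::abort("participant(s) with inconsistent arm across roles",
                 class = "blindex_invalid_data")
  }
  tibble::as_tibble(data)
}

estimate_role <- function(data, role_label, level, n_resamples, seed) {
  counts <- tally_responses(data)
  arm_est <- bang_estimate(collapse_responses(counts), level)
  summed <- summed_bang(arm_est, rounded = TRUE)
  james <- james_estimate(data, level = level, n_resamples = n_resamples,
                          seed = seed)
  dplyr::bind_rows(arm_est, summed, james) |>
    dplyr::mutate(role = role_label, available = TRUE, .before = 1)
}

unavailable_role <- function(role_label, level) {
  tibble::tibble(
    role = role_label, available = FALSE,
    arm = c(arm_levels(), NA, NA),
    index = c("bang_arm", "bang_arm", "bang_summed", "james"),
    point = NaN, variance = NaN, ci_lower = NaN, ci_upper = NaN,
    level = level, n = 0L, undefined = TRUE
  )
}

#' Run the full blinding analysis
#'
#' Computes, for every respondent role present in the data, the
#' arm-specific Bang blinding indices with Wald intervals, the summed
#' study-level Bang index (rounded-summand convention), the weighted James
#' index with a percentile-bootstrap interval, and adequacy
#' classifications; assessor responses are additionally pooled across
#' assessors (summing counts, equivalently concatenating respondents) into
#' `assessors_pooled` estimates. Descriptive response tables, and — when
#' range-of-motion columns are present — Welch unequal-variance mean
#' differences for post-intervention and change scores, complete the
#' report. Analysis is intention-to-treat: every randomised respondent is
#' analysed as allocated and the report records that the two counts agree.
#'
#' Standard roles absent from the data yield rows flagged
#' `available = FALSE` rather than being dropped silently.
#'
#' @param data Respondent-level data (see [read_responses_csv()] for the
#'   schema). Must be non-empty.
#' @param level Confidence level, default 0.95.
#' @param by Optional grouping column (e.g. `"stratum"`): participant Bang
#'   estimates are additionally computed within each level and returned in
#'   the `subgroups` component.
#' @param n_resamples Bootstrap resamples for James intervals.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `"blind_report"`: a list with components
#'   `estimates` (tidy tibble of all index estimates with
#'   classifications), `descriptives` (response counts/percentages by role
#'   and arm), `rom` (Welch mean-difference tibble, zero rows without ROM
#'   data), `subgroups` (when `by` is given) and `meta`.
#' @examples
#' report <- run_analysis(study_fixture(), seed = 1, n_resamples = 500)
#' tidy(report)
#' @export
run_analysis <- function(data, level = 0.95, by = NULL,
                         n_resamples = 10000, seed = NULL) {
  data <- validate_trial_data(data)
  if (nrow(data) == 0) {
    rlang::abort("empty dataset: nothing to analyse", class = "blindex_empty")
  }
  roles_present <- intersect(role_levels(), unique(data$role))
  assessor_roles <- setdiff(roles_present, "participant")

  est <- purrr::imap(
    stats::setNames(roles_present, roles_present),
    function(r, nm) estimate_role(dplyr::filter(data, .data$role == r),
                                  nm, level, n_resamples, seed)
  )
  if (length(assessor_roles) > 0) {
    pooled <- dplyr::filter(data, .data$role %in% assessor_roles)
    est$assessors_pooled <- estimate_role(pooled, "assessors_pooled",
                                          level, n_resamples, seed)
  }
  missing_roles <- setdiff(role_levels(), roles_present)
  est <- c(est, purrr::map(missing_roles, unavailable_role, level = level))
  estimates <- dplyr::bind_rows(est) |> classify_blinding()

  descriptives <- data |>
    tally_responses(by = "role") |>
    dplyr::mutate(
      pct = if (sum(.data$count) > 0)
        round_away(100 * .data$count / sum(.data$count), 0) else 0,
      .by = c("role", "arm")
    )

  rom <- rom_contrasts(data, level)

  subgroups <- NULL
  if (!is.null(by)) {
    if (!by %in% names(data)) {
      rlang::abort(sprintf("grouping column '%s' not found", by))
    }
    subgroups <- data |>
      dplyr::filter(.data$role == "participant") |>
      tally_responses(by = by) |>
      collapse_responses() |>
      bang_estimate(level) |>
      classify_blinding()
  }

  structure(
    list(
      estimates = estimates, descriptives = descriptives, rom = rom,
      subgroups = subgroups,
      meta = list(
        n_randomised = length(unique(data$participant_id)),
        n_analysed = length(unique(data$participant_id)),
        roles = roles_present, missing_roles = missing_roles,
        level = level, n_resamples = n_resamples, seed = seed,
        version = as.character(utils::packageVersion("blindex")),
        input_hash = rlang::hash(data)
      )
    ),
    class = "blind_report"
  )
}

rom_measures <- function() {
  c("flexion", "extension")
}

rom_contrasts <- function(data, level) {
  empty <- tibble::tibble(
    measure = character(0),
    mean_active = numeric(0), sd_active = numeric(0), n_active = integer(0),
    mean_control = numeric(0), sd_control = numeric(0), n_control = integer(0),
    md = numeric(0), se = numeric(0), df = numeric(0),
    ci_lower = numeric(0), ci_upper = numeric(0), level = numeric(0)
  )
  p <- dplyr::filter(data, .data$role == "participant")
  out <- list()
  for (m in rom_measures()) {
    pre <- p[[paste0("rom_pre_", m)]]
    post <- p[[paste0("rom_post_", m)]]
    if (is.null(post)) next
    for (what in c("post", "change")) {
      val <- if (what == "post") post else if (!is.null(pre)) post - pre else NULL
      if (is.null(val)) next
      ga <- group_summary(val[p$arm == "active"])
      gc <- group_summary(val[p$arm == "control"])
      if (ga$n < 2 || gc$n < 2) next
      wd <- welch_mean_diff(ga$mean, ga$sd, ga$n, gc$mean, gc$sd, gc$n, level)
      out[[paste0(what, "_", m)]] <- dplyr::bind_cols(
        tibble::tibble(measure = paste0(what, "_", m),
                       mean_active = ga$mean, sd_active = ga$sd, n_active = ga$n,
                       mean_control = gc$mean, sd_control = gc$sd, n_control = gc$n),
        wd
      )
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' @export
print.blind_report <- function(x, ...) {
  cat(render_report(x, format = "text"))
  invisible(x)
}

#' Tidy a blinding analysis report
#'
#' `tidy()` returns the estimate table (one row per index per role, with
#' classifications); `glance()` a one-row summary of the analysis.
#'
#' @param x A `"blind_report"` from [run_analysis()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy blind_report
#' @export
tidy.blind_report <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.blind_report
#' @method glance blind_report
#' @export
glance.blind_report <- function(x, ...) {
  part <- dplyr::filter(x$estimates, .data$role == "participant")
  tibble::tibble(
    n_randomised = x$meta$n_randomised,
    n_analysed = x$meta$n_analysed,
    n_roles = length(x$meta$roles),
    level = x$meta$level,
    bang_active = part$point[part$index == "bang_arm" & part$arm == "active"],
    bang_control = part$point[part$index == "bang_arm" & part$arm == "control"],
    bang_summed = part$point[part$index == "bang_summed"],
    james = part$point[part$index == "james"]
  )
}

#' Forest plot of blinding estimates
#'
#' Plots every available index estimate with its confidence interval,
#' faceted by index, with the adequacy band (±0.2 arm-specific, ±0.3
#' summed, 0.5 reference for James) shown as dashed lines.
#'
#' @param object A `"blind_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot blind_report
#' @export
autoplot.blind_report <- function(object, ...) {
  d <- object$estimates |>
    dplyr::filter(.data$available, !.data$undefined) |>
    dplyr::mutate(
      label = ifelse(is.na(.data$arm), .data$role,
                     paste(.data$role, .data$arm, sep = ", "))
    )
  refs <- tibble::tibble(
    index = c("bang_arm", "bang_arm", "bang_summed", "bang_summed", "james"),
    ref = c(-0.2, 0.2, -0.3, 0.3, 0.5)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$point, y = .data$label)) +
    ggplot2::geom_vline(data = refs, ggplot2::aes(xintercept = .data$ref),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$index), ncol = 1,
                        scales = "free") +
    ggplot2::labs(x = "blinding index (95% CI)", y = NULL,
                  title = "Blinding assessment") +
    ggplot2::theme_minimal()
}

fmt_est <- function(point, lo, hi) {
  f <- function(v) ifelse(is.nan(v), "NaN", sprintf("%.2f", round_away(v, 2)))
  sprintf("%s (%s to %s)", f(point), f(lo), f(hi))
}

#' Render a blinding report
#'
#' Deterministic renderings of a [run_analysis()] report: `"json"` (machine
#' readable, `NaN` serialised as the string `"NaN"`), `"text"` or
#' `"markdown"` (a trial-report-style table; indices at two decimals, ROM
#' contrasts at one, undefined cells printed `NaN`).
#'
#' @param report A `"blind_report"`.
#' @param format One of `"json"`, `"text"`, `"markdown"`.
#' @param path Optional output file; when given the rendering is written
#'   there.
#' @return The rendering as a single string, invisibly when `path` is
#'   given.
#' @export
render_report <- function(report, format = c("json", "text", "markdown"),
                          path = NULL) {
  stopifnot(inherits(report, "blind_report"))
  format <- match.arg(format)
  out <- switch(format,
    json = render_json(report),
    text = render_text(report, markdown = FALSE),
    markdown = render_text(report, markdown = TRUE)
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

render_json <- function(report) {
  payload <- list(
    estimates = report$estimates,
    descriptives = report$descriptives,
    rom = report$rom,
    subgroups = report$subgroups,
    meta = report$meta
  )
  as.character(jsonlite::toJSON(payload, dataframe = "rows", na = "string",
                                auto_unbox = TRUE, digits = 10, pretty = TRUE))
}

render_text <- function(report, markdown = FALSE) {
  e <- report$estimates
  h <- function(txt) if (markdown) paste0("## ", txt) else toupper(txt)
  bullet <- if (markdown) "- " else "  "
  row_for <- function(role, index, arm = NA) {
    i <- e$role == role & e$index == index &
      (if (is.na(arm)) is.na(e$arm) else !is.na(e$arm) & e$arm == arm)
    e[which(i)[1], ]
  }
  line <- function(lbl, r) {
    if (is.na(r$role) || !isTRUE(r$available)) {
      return(sprintf("%s%s: unavailable", bullet, lbl))
    }
    sprintf("%s%s: %s [%s]", bullet, lbl,
            fmt_est(r$point, r$ci_lower, r$ci_upper), r$classification)
  }
  blinding_block <- function(role, label) {
    c(sprintf("%s%s", bullet, label),
      line("  Bang BI, active arm", row_for(role, "bang_arm", "active")),
      line("  Bang BI, control arm", row_for(role, "bang_arm", "control")),
      line("  Summed Bang BI", row_for(role, "bang_summed")),
      line("  James BI", row_for(role, "james")))
  }
  lines <- c(
    h("Blinding assessment report"),
    sprintf("%sRandomised: %d; analysed (intention-to-treat): %d",
            bullet, report$meta$n_randomised, report$meta$n_analysed),
    h("Participants"),
    blinding_block("participant", "Participants")[-1]
  )
  for (r in intersect(c("assessor_1", "assessor_2", "assessor_3",
                        "assessors_pooled"),
                      unique(e$role))) {
    lines <- c(lines, h(gsub("_", " ", r)), blinding_block(r, r)[-1])
  }
  if (nrow(report$rom) > 0) {
    lines <- c(lines, h("Range of motion (degrees)"))
    for (i in seq_len(nrow(report$rom))) {
      r <- report$rom[i, ]
      lines <- c(lines, sprintf(
        "%s%s: active %.1f (%.1f), control %.1f (%.1f), MD %.1f (%.1f to %.1f)",
        bullet, r$measure, r$mean_active, r$sd_active, r$mean_control,
        r$sd_control, round_away(r$md, 1), round_away(r$ci_lower, 1),
        round_away(r$ci_upper, 1)))
    }
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}
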