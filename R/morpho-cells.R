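#' Calcein pulse-chase growth rate
#'
#' Converts the measured distance between the calcein label front and the
#' chondro-osseous junction into a daily elongation rate:
#' `rate = distance / (elapsed_hours / 24)`. Under the 48-hour protocol this
#' is the distance divided by two.
#'
#' @param distance_um Measured front distance(s), microns (non-negative).
#' @param elapsed_hours Chase duration, hours (48 by default).
#' @return Elongation rate(s) in microns per day.
#' @export
#' @examples
#' calcein_growth_rate(100) # 48-h protocol: 50 um/day
calcein_growth_rate <- function(distance_um,
                                elapsed_hours = tailprop_defaults()$calcein_hours) {
  if (any(elapsed_hours <= 0)) abort("`elapsed_hours` must be positive.")
  if (any(distance_um < 0, na.rm = TRUE)) {
    abort("`distance_um` must be non-negative.")
  }
  distance_um / (elapsed_hours / 24)
}

#' EdU proliferative index per specimen
#'
#' Per section, the index is the fraction of EdU-positive cells among all
#' cells in the region of interest; the specimen value is the mean across
#' its sections (the fixed averaging order: sections, then specimen).
#'
#' @param table Tibble with `specimen`, `edu_pos`, `edu_total` (one row per
#'   section).
#' @return A tibble with `specimen`, `n_sections`, `proliferative_index`.
#' @export
#' @examples
#' proliferative_index(tibble::tibble(specimen = "a",
#'   edu_pos = c(10, 20, 30), edu_total = 100))
proliferative_index <- function(table) {
  stopifnot(all(c("specimen", "edu_pos", "edu_total") %in% names(table)))
  if (any(table$edu_total <= 0)) {
    abort("Every section must contain at least one counted cell.")
  }
  if (any(table$edu_pos < 0 | table$edu_pos > table$edu_total)) {
    abort("`edu_pos` must lie in [0, edu_total].")
  }
  table |>
    group_by(.data$specimen) |>
    summarise(
      n_sections = dplyr::n(),
      proliferative_index = mean(.data$edu_pos / .data$edu_total),
      .groups = "drop"
    )
}

#' Mean maximum hypertrophic chondrocyte height per specimen
#'
#' Per section, the mean of the three largest cell heights in the axis of
#' elongation; the specimen value is the mean across its sections.
#'
#' @param cells Tibble with `specimen`, `section`, `height_um` (one row per
#'   measured cell; at least 3 cells per section).
#' @return A tibble with `specimen`, `n_sections`, `max_height_um`.
#' @export
max_hypertrophic_height <- function(cells) {
  stopifnot(all(c("specimen", "section", "height_um") %in% names(cells)))
  per_section <- cells |>
    group_by(.data$specimen, .data$section) |>
    summarise(n_cells = dplyr::n(),
              top3 = mean(sort(.data$height_um, decreasing = TRUE)[1:3]),
              .groups = "drop")
  if (any(per_section$n_cells < 3)) {
    abort("Every section needs at least 3 measured cells.")
  }
  per_section |>
    group_by(.data$specimen) |>
    summarise(n_sections = dplyr::n(),
              max_height_um = mean(.data$top3), .groups = "drop")
}

#' Welch's unequal-variances t-test
#'
#' Two-sided t-test with the Welch-Satterthwaite degrees of freedom, the
#' package's standard comparison between group means.
#'
#' @param group_a,group_b Numeric vectors (each of length at least 2).
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `undefined` (TRUE when both variances are zero so the statistic does
#'   not exist).
#' @export
#' @examples
#' welch_t(rnorm(5), rnorm(5, 1))
welch_t <- function(group_a, group_b) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 observations.")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    warn("Both group variances are zero; the t statistic is undefined.")
    return(tibble(t = NA_real_, df = NA_real_,
                  p = if (mean(group_a) == mean(group_b)) 1 else 0,
                  mean_a = mean(group_a), mean_b = mean(group_b),
                  undefined = TRUE))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b),
    undefined = FALSE
  )
}
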