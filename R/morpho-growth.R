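#' Normalize vertebral lengths to body length
#'
#' Adds the per-animal proportion `rel_length = length_um / naso_anal_um` to
#' a length series. All downstream proportion analyses (weekly change, peak
#' detection) operate on this normalized scale.
#'
#' @param series Tibble with `length_um` and `naso_anal_um` columns (e.g.
#'   from [simulate_growth_series()]).
#' @return `series` with a `rel_length` column appended.
#' @export
normalize_to_body <- function(series) {
  stopifnot(all(c("length_um", "naso_anal_um") %in% names(series)))
  if (any(series$naso_anal_um <= 0, na.rm = TRUE)) {
    abort("`naso_anal_um` must be positive.")
  }
  series |> mutate(rel_length = .data$length_um / .data$naso_anal_um)
}

#' Tail-length to body-length ratio
#'
#' Sums the vertebral lengths of each animal (plus inter-vertebral gaps when
#' provided) and divides by the animal's naso-anal length.
#'
#' @param series Tibble with `animal_id`, `timepoint_days` (optional),
#'   `length_um`, `naso_anal_um`.
#' @param gap_um Total unmineralized gap length to add per animal, microns.
#' @return A tibble with one row per animal: grouping columns plus `ratio`.
#' @export
#' @examples
#' gs <- simulate_growth_series("jerboa", noise_sd = 0)
#' tb <- tail_body_ratio(gs)
#' mean(tb$ratio[tb$timepoint_days == 42])
tail_body_ratio <- function(series, gap_um = 0) {
  stopifnot(all(c("animal_id", "length_um", "naso_anal_um") %in%
                  names(series)))
  if (any(series$naso_anal_um <= 0, na.rm = TRUE)) {
    abort("`naso_anal_um` must be positive.")
  }
  keys <- intersect(c("animal_id", "species", "timepoint_days"),
                    names(series))
  series |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      ratio = (sum(.data$length_um) + gap_um) / .data$naso_anal_um[1],
      .groups = "drop"
    )
}

#' Weekly change in normalized vertebral length
#'
#' For each vertebra, averages the normalized length over animals within
#' each timepoint, then takes differences between consecutive timepoints:
#' `delta_i(t_k) = mean rel_length_i(t_{k+1}) - mean rel_length_i(t_k)`.
#' With `rate = TRUE` the difference is divided by the interval length in
#' weeks.
#'
#' @param series Tibble with `timepoint_days`, `vertebra`, `length_um`,
#'   `naso_anal_um` (and optionally `animal_id`).
#' @param rate Report per-week rates instead of raw differences.
#' @return A tibble with `vertebra`, `from_day`, `to_day`, `delta`
#'   (heatmap-ready long form).
#' @export
weekly_relative_change <- function(series, rate = FALSE) {
  stopifnot(all(c("timepoint_days", "vertebra") %in% names(series)))
  tp <- sort(unique(series$timepoint_days))
  if (length(tp) < 2) abort("At least 2 timepoints are required.")
  if (any(diff(tp) <= 0)) abort("Timepoints must be strictly increasing.")
  means <- series |>
    normalize_to_body() |>
    group_by(.data$vertebra, .data$timepoint_days) |>
    summarise(rel = mean(.data$rel_length), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "timepoint_days", values_from = "rel")
  mat <- as.matrix(means[, as.character(tp)])
  d <- mat[, -1, drop = FALSE] - mat[, -ncol(mat), drop = FALSE]
  if (rate) d <- sweep(d, 2, diff(tp) / 7, "/")
  tibble(
    vertebra = rep(means$vertebra, ncol(d)),
    from_day = rep(tp[-length(tp)], each = nrow(d)),
    to_day = rep(tp[-1], each = nrow(d)),
    delta = as.vector(d)
  )
}

#' Vertebra with the greatest cumulative change
#'
#' Sums the weekly change of each vertebra over a window of intervals and
#' returns the index of the maximum. Exact ties break toward the smaller
#' index and are reported.
#'
#' @param changes Change table from [weekly_relative_change()].
#' @param window Optional numeric vector of `from_day` values to include;
#'   the full window by default.
#' @return A one-row tibble: `peak_vertebra`, `total_change`, `tie`.
#' @export
#' @examples
#' gs <- simulate_growth_series("mouse", noise_sd = 0)
#' peak_vertebra(weekly_relative_change(gs))$peak_vertebra
peak_vertebra <- function(changes, window = NULL) {
  stopifnot(all(c("vertebra", "from_day", "delta") %in% names(changes)))
  if (!is.null(window)) {
    changes <- changes |> filter(.data$from_day %in% window)
  }
  if (nrow(changes) == 0) abort("The requested window is empty.")
  totals <- changes |>
    group_by(.data$vertebra) |>
    summarise(total_change = sum(.data$delta), .groups = "drop") |>
    arrange(.data$vertebra)
  best <- max(totals$total_change)
  hits <- totals$vertebra[totals$total_change == best]
  tibble(
    peak_vertebra = min(hits),
    total_change = best,
    tie = length(hits) > 1
  )
}
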