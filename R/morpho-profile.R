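profile_intensity <- function(profile) {
  if (is.data.frame(profile)) {
    if (!"intensity" %in% names(profile)) {
      abort("`profile` must contain an `intensity` column.")
    }
    if ("pixel_index" %in% names(profile)) {
      profile <- profile[order(profile$pixel_index), , drop = FALSE]
    }
    as.numeric(profile$intensity)
  } else if (is.numeric(profile)) {
    as.numeric(profile)
  } else {
    abort("`profile` must be a data frame or a numeric vector.")
  }
}

smooth_3px <- function(v) {
  n <- length(v)
  out <- v
  out[2:(n - 1)] <- (v[1:(n - 2)] + v[2:(n - 1)] + v[3:n]) / 3
  out
}

#' Segment vertebral elements from a 1D intensity profile
#'
#' Finds maximal runs of the profile above the half-range threshold
#' `(min + max) / 2`, ordered cranial to caudal and labelled TV1..TVn. Runs
#' separated by sub-threshold gaps shorter than `min_gap_px` pixels are
#' merged (such a dip cannot be an inter-vertebral gap). An optional centered
#' 3-pixel moving average can be applied before thresholding for noisy
#' scans.
#'
#' @param profile Tibble with `pixel_index` and `intensity` (or a numeric
#'   vector of intensities).
#' @param smooth Apply the 3-pixel moving average before thresholding.
#' @param min_gap_px Minimum sub-threshold gap, in pixels, that separates
#'   two elements.
#' @return A tibble with `vertebra` (label `TV1`...), `start_px`, `end_px`
#'   (1-based pixel indices of the first and last supra-threshold pixel).
#' @export
#' @examples
#' ph <- simulate_tail_phantom(phantom_config("mouse"))
#' nrow(segment_elements(ph$profile))
segment_elements <- function(profile, smooth = FALSE, min_gap_px = 2) {
  v <- profile_intensity(profile)
  if (length(v) < 3) abort("The profile is too short to segment.")
  if (smooth) v <- smooth_3px(v)
  thr <- (min(v) + max(v)) / 2
  above <- v > thr
  if (!any(above)) abort("No supra-threshold run found (flat profile?).")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start_px = starts[r$values], end_px = ends[r$values])
  # merge runs separated by sub-threshold gaps shorter than min_gap_px
  if (nrow(runs) > 1) {
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap <- runs$start_px[i] - last$end_px - 1
      if (gap < min_gap_px) {
        merged[[length(merged)]]$end_px <- runs$end_px[i]
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
    runs <- bind_rows(merged)
  }
  runs |>
    mutate(vertebra = paste0("TV", dplyr::row_number()), .before = 1)
}

#' Measure a diaphysis length by the half-height midpoint rule
#'
#' Implements the sub-pixel length measurement: within a window spanning the
#' element plus its flanking gaps, the local minimum m (background) and
#' maximum M (bone) define the half height `(m + M) / 2`; the element begins
#' at the linearly interpolated half-height crossing on the leading rising
#' edge and ends at the interpolated crossing on the trailing falling edge.
#' The length is the crossing distance times the effective pixel size
#' `voxel * resize` (microns).
#'
#' @param profile Tibble with `pixel_index`, `intensity` (or numeric vector).
#' @param start_px,end_px Pixel bounds of the supra-threshold run (from
#'   [segment_elements()]).
#' @param voxel Voxel size in microns.
#' @param resize Integer viewing resize factor.
#' @param window_px How far beyond the run the min/max window extends
#'   (defaults to the flanking gaps, bounded by neighbouring runs when the
#'   profile is segmented; a plain numeric bound in pixels here).
#' @return Length in microns (a single number).
#' @export
measure_diaphysis_length <- function(profile, start_px, end_px,
                                     voxel = tailprop_defaults()$voxel_um,
                                     resize = tailprop_defaults()$resize_factor,
                                     window_px = 5) {
  v <- profile_intensity(profile)
  n <- length(v)
  if (start_px < 1 || end_px > n || start_px > end_px) {
    abort("The element interval must lie within the profile.")
  }
  w_lo <- max(1, floor(start_px - window_px))
  w_hi <- min(n, ceiling(end_px + window_px))
  w <- v[w_lo:w_hi]
  m <- min(w)
  M <- max(w)
  if (M <= m) abort("No contrast in the measurement window (M <= m).")
  half <- (m + M) / 2
  # leading rising edge: last crossing at or before the run start
  cross_up <- function() {
    for (i in seq(start_px, w_lo + 1)) {
      if (v[i] >= half && v[i - 1] < half) {
        return((i - 1) + (half - v[i - 1]) / (v[i] - v[i - 1]))
      }
    }
    start_px # degenerate: run starts at window edge
  }
  cross_dn <- function() {
    for (i in seq(end_px, w_hi - 1)) {
      if (v[i] >= half && v[i + 1] < half) {
        return(i + (v[i] - half) / (v[i] - v[i + 1]))
      }
    }
    end_px
  }
  (cross_dn() - cross_up()) * voxel * resize
}

#' Segment and measure every element of a profile
#'
#' Convenience wrapper: [segment_elements()] followed by
#' [measure_diaphysis_length()] on each element, with each element's
#' measurement window bounded by its neighbours.
#'
#' @inheritParams segment_elements
#' @inheritParams measure_diaphysis_length
#' @return A tibble with `vertebra`, `start_px`, `end_px`, `length_um`.
#' @export
#' @examples
#' ph <- simulate_tail_phantom(phantom_config("jerboa"))
#' head(measure_profile(ph$profile))
measure_profile <- function(profile,
                            voxel = tailprop_defaults()$voxel_um,
                            resize = tailprop_defaults()$resize_factor,
                            smooth = FALSE, min_gap_px = 2) {
  v <- profile_intensity(profile)
  segs <- segment_elements(v, smooth = smooth, min_gap_px = min_gap_px)
  prev_end <- c(0, segs$end_px[-nrow(segs)])
  next_start <- c(segs$start_px[-1], length(v) + 1)
  segs |>
    mutate(length_um = purrr::pmap_dbl(
      list(.data$start_px, .data$end_px, prev_end, next_start),
      function(s, e, pe, ns) {
        w <- max(s - pe - 1, ns - e - 1, 2)
        measure_diaphysis_length(v, s, e, voxel = voxel, resize = resize,
                                 window_px = w)
      }
    ))
}
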