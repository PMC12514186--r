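#' Configuration for the synthetic growth-plate histology tables
#'
#' Zone heights and cell heights are drawn from normal laws, EdU labels are
#' Bernoulli per cell, and the calcein front distance equals twice the
#' planted daily elongation rate (the 48-hour pulse-chase protocol) plus
#' noise. Ground truth is stored alongside the draws.
#'
#' @param n_specimens Number of animals.
#' @param n_sections Histological sections per specimen (3 by default, the
#'   averaging unit of all downstream summaries).
#' @param cells_per_section Cells counted per EdU region of interest.
#' @param edu_p Planted proliferative index (Bernoulli probability).
#' @param daily_rate_um Planted daily elongation rate, microns/day.
#' @param rate_noise_sd Noise on the calcein distance, microns.
#' @param zone_means,zone_sds Named means/sds for `total`, `resting`,
#'   `proliferative`, `hypertrophic` zone heights, microns.
#' @param cell_height_mean,cell_height_sd Hypertrophic cell height law,
#'   microns.
#' @param n_cells_heights Measured cell heights per section.
#' @param seed Integer seed.
#' @return A list of class `"growth_plate_config"`.
#' @export
growth_plate_config <- function(n_specimens = 8,
                                n_sections = 3,
                                cells_per_section = 100,
                                edu_p = 0.3,
                                daily_rate_um = 50,
                                rate_noise_sd = 0,
                                zone_means = c(total = 350, resting = 80,
                                               proliferative = 150,
                                               hypertrophic = 120),
                                zone_sds = c(total = 20, resting = 8,
                                             proliferative = 12,
                                             hypertrophic = 10),
                                cell_height_mean = 18,
                                cell_height_sd = 4,
                                n_cells_heights = 12,
                                seed = 1) {
  stopifnot(n_specimens >= 1, n_sections >= 1, cells_per_section >= 1,
            edu_p >= 0, edu_p <= 1, daily_rate_um >= 0, rate_noise_sd >= 0,
            n_cells_heights >= 3)
  if (any(zone_means < 0) || cell_height_mean < 0) {
    abort("Configured means must be non-negative.")
  }
  structure(
    list(n_specimens = as.integer(n_specimens),
         n_sections = as.integer(n_sections),
         cells_per_section = as.integer(cells_per_section),
         edu_p = edu_p, daily_rate_um = daily_rate_um,
         rate_noise_sd = rate_noise_sd,
         zone_means = zone_means, zone_sds = zone_sds,
         cell_height_mean = cell_height_mean, cell_height_sd = cell_height_sd,
         n_cells_heights = as.integer(n_cells_heights), seed = seed),
    class = "growth_plate_config"
  )
}

#' Simulate growth-plate histomorphometry tables
#'
#' @param config A [growth_plate_config()].
#' @return A list with tibbles `sections` (per-section zone heights, EdU
#'   counts, calcein front distance), `cells` (per-cell hypertrophic heights),
#'   and `truth` (the planted parameters).
#' @export
#' @examples
#' gp <- simulate_growth_plate(growth_plate_config(n_specimens = 2, seed = 5))
#' gp$truth$daily_rate_um
simulate_growth_plate <- function(config = growth_plate_config()) {
  stopifnot(inherits(config, "growth_plate_config"))
  with_seed(fan_out_seed(config$seed, "growth_plate"), {
    grid <- tidyr::expand_grid(
      specimen = sprintf("sp%02d", seq_len(config$n_specimens)),
      section = seq_len(config$n_sections)
    )
    ns <- nrow(grid)
    zm <- config$zone_means
    zs <- config$zone_sds
    sections <- grid |>
      mutate(
        total_um = pmax(0, rnorm(ns, zm[["total"]], zs[["total"]])),
        resting_um = pmax(0, rnorm(ns, zm[["resting"]], zs[["resting"]])),
        proliferative_um = pmax(0, rnorm(ns, zm[["proliferative"]],
                                         zs[["proliferative"]])),
        hypertrophic_um = pmax(0, rnorm(ns, zm[["hypertrophic"]],
                                        zs[["hypertrophic"]])),
        edu_total = config$cells_per_section,
        edu_pos = rbinom(ns, config$cells_per_section, config$edu_p),
        calcein_distance_um = pmax(0, 2 * config$daily_rate_um +
                                     rnorm(ns, 0, config$rate_noise_sd))
      )
    cells <- tidyr::expand_grid(grid,
                                cell = seq_len(config$n_cells_heights)) |>
      mutate(height_um = pmax(0.1, rnorm(dplyr::n(), config$cell_height_mean,
                                         config$cell_height_sd)))
    truth <- tibble(
      edu_p = config$edu_p, daily_rate_um = config$daily_rate_um,
      cell_height_mean = config$cell_height_mean,
      zone_total_um = zm[["total"]], zone_resting_um = zm[["resting"]],
      zone_proliferative_um = zm[["proliferative"]],
      zone_hypertrophic_um = zm[["hypertrophic"]]
    )
    list(sections = sections, cells = cells, truth = truth)
  })
}
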