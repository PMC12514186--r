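#' Configuration for a one-dimensional tail micro-CT phantom
#'
#' Describes a synthetic intensity profile along the cranial-to-caudal tail
#' axis: a high plateau over each ossified vertebral diaphysis, a low
#' background plateau over inter-vertebral gaps and unossified elements, and
#' linear one-pixel edge ramps, so the half-height midpoint rule has an exact
#' analytic answer. The effective pixel is `voxel * resize` microns (27 by
#' default, matching 9 micron voxels viewed at a resize factor of 3).
#'
#' @param species `"mouse"` (31 vertebrae) or `"jerboa"` (28); sets defaults.
#' @param n_vertebrae Number of vertebral elements.
#' @param true_lengths Per-vertebra diaphysis lengths in microns; the default
#'   is a neonatal-like decreasing series from ~2 mm.
#' @param gap Inter-vertebral unmineralized gap, microns.
#' @param voxel Scan voxel size, microns.
#' @param resize Integer viewing resize factor.
#' @param intensity_noise_sd Additive Gaussian noise on the profile.
#' @param ossified_mask Logical per vertebra; unossified elements render as
#'   background.
#' @param bone,background Plateau intensities.
#' @param seed Integer seed (used only when noise is non-zero).
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(species = c("mouse", "jerboa"),
                           n_vertebrae = NULL,
                           true_lengths = NULL,
                           gap = tailprop_defaults()$phantom_gap_um,
                           voxel = tailprop_defaults()$voxel_um,
                           resize = tailprop_defaults()$resize_factor,
                           intensity_noise_sd = 0,
                           ossified_mask = NULL,
                           bone = tailprop_defaults()$bone_intensity,
                           background = tailprop_defaults()$background_intensity,
                           seed = 1) {
  species <- match.arg(species)
  if (is.null(n_vertebrae)) {
    n_vertebrae <- tailprop_defaults()$n_vertebrae[[species]]
  }
  n_vertebrae <- as.integer(n_vertebrae)
  if (is.null(true_lengths)) {
    true_lengths <- 2000 * exp(-0.08 * (seq_len(n_vertebrae) - 1))
  }
  if (is.null(ossified_mask)) ossified_mask <- rep(TRUE, n_vertebrae)
  stopifnot(length(true_lengths) == n_vertebrae,
            length(ossified_mask) == n_vertebrae,
            all(true_lengths > 0), gap > 0, voxel > 0, resize >= 1,
            intensity_noise_sd >= 0, bone > background)
  structure(
    list(species = species, n_vertebrae = n_vertebrae,
         true_lengths = as.numeric(true_lengths), gap = gap,
         voxel = voxel, resize = as.integer(resize),
         intensity_noise_sd = intensity_noise_sd,
         ossified_mask = as.logical(ossified_mask),
         bone = bone, background = background, seed = seed),
    class = "phantom_config"
  )
}

#' Simulate a one-dimensional tail micro-CT intensity profile
#'
#' Renders the phantom described by a [phantom_config()]: each ossified
#' diaphysis occupies a continuous interval on the pixel axis, with intensity
#' rising linearly across one pixel at each boundary. The half-height
#' crossing of each ramp sits exactly at the planted element boundary, so
#' with zero noise the measurement stage recovers the planted lengths
#' exactly (up to the pixel sampling grid).
#'
#' @param config A [phantom_config()].
#' @return A list with `profile` (tibble: `pixel_index`, `intensity`) and
#'   `truth` (tibble: `vertebra`, `true_length_um`, `start_um`, `ossified`).
#' @export
#' @examples
#' ph <- simulate_tail_phantom(phantom_config("jerboa"))
#' nrow(ph$truth)
simulate_tail_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  eff <- config$voxel * config$resize
  len_px <- config$true_lengths / eff
  gap_px <- config$gap / eff
  if (any(len_px < 2)) {
    abort("Every element must be at least 2 effective pixels long.")
  }
  if (gap_px < 3) {
    abort("The inter-vertebral gap must span at least 3 effective pixels.")
  }
  # half-integer start positions align ramp midpoints with pixel boundaries,
  # so an element of w pixels yields exactly w supra-threshold samples
  starts <- gap_px + 0.5 + c(0, cumsum(len_px[-length(len_px)] + gap_px))
  ends <- starts + len_px
  total_px <- ceiling(ends[length(ends)] + gap_px)
  px <- seq_len(total_px)
  intensity <- rep(config$background, total_px)
  ramp <- function(x, s, e) {
    # piecewise-linear bump: background outside [s-0.5, e+0.5], bone inside
    # [s+0.5, e-0.5], linear one-pixel ramps at both edges
    up <- pmin(pmax((x - (s - 0.5)), 0), 1)
    dn <- pmin(pmax(((e + 0.5) - x), 0), 1)
    pmin(up, dn)
  }
  for (k in seq_len(config$n_vertebrae)) {
    if (!config$ossified_mask[k]) next
    intensity <- pmax(
      intensity,
      config$background +
        (config$bone - config$background) * ramp(px, starts[k], ends[k])
    )
  }
  if (config$intensity_noise_sd > 0) {
    intensity <- with_seed(fan_out_seed(config$seed, "phantom"), {
      intensity + rnorm(total_px, 0, config$intensity_noise_sd)
    })
  }
  list(
    profile = tibble(pixel_index = px, intensity = intensity),
    truth = tibble(
      vertebra = seq_len(config$n_vertebrae),
      true_length_um = config$true_lengths,
      start_um = starts * eff,
      ossified = config$ossified_mask
    )
  )
}
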