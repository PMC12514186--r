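#' Calibration defaults for the synthetic study design
#'
#' One place for every numeric constant the generators default to. The slope
#' of the planted TV6-versus-TV1 log2 fold-change relation (0.883), the
#' replicate count (4 per species and vertebra), the vertebral counts at birth
#' (31 mouse, 28 jerboa), the adult tail:body ratios (1.0 mouse, 1.5 jerboa),
#' the newborn tail:body ratio (0.5), and the micro-CT pixel geometry
#' (9 micron voxels resized by a factor of 3) describe the biological system
#' being emulated. The remaining constants (noise scales, fraction of
#' one-to-zero orthologs, size-factor range, expression baseline) are synthetic
#' choices documented in the methods vignette.
#'
#' @return A named list of default constants.
#' @export
#' @examples
#' tailprop_defaults()$slope_b
tailprop_defaults <- function() {
  list(
    # transcriptome simulation
    n_genes           = 2000L,
    n_reps            = 4L,
    baseline_log_mean = 7,      # log2 scale; mean count ~ 128
    baseline_log_sd   = 1.5,    # spread of per-gene baselines, log2
    dispersion        = 0.05,   # NB dispersion alpha
    frac_equivalent   = 0.25,
    frac_A            = 0.05,   # DE in TV6 only
    frac_B            = 0.03,   # disproportionate residual
    slope_b           = 0.883,
    intercept_a       = 0,
    resid_sd          = 0.25,
    outlier_sd        = 1.5,
    x_sd              = 1.5,    # spread of interspecies TV1 log2FCs
    delta_vert_sd     = 0.3,    # intra-species TV6 - TV1 baseline shift
    effect_min        = 1,      # A-type |log2FC| range
    effect_max        = 3,
    length_log_sd     = 0.3,
    frac_one_to_zero  = 0.02,
    size_factor_range = c(0.7, 1.3),
    frac_outlier      = 0.062,  # ~ 421 / 6786 pairs outside the interval
    # thresholds
    alpha             = 0.05,
    pi_level          = 0.95,
    # micro-CT phantom geometry
    voxel_um          = 9,
    resize_factor     = 3L,
    n_vertebrae       = c(mouse = 31L, jerboa = 28L),
    phantom_gap_um    = 300,
    bone_intensity    = 100,
    background_intensity = 10,
    # growth series
    birth_ratio       = 0.5,
    adult_ratio       = c(mouse = 1.0, jerboa = 1.5),
    naso_anal_birth_um = c(mouse = 30000, jerboa = 25000),
    naso_anal_adult_um = c(mouse = 85000, jerboa = 80000),
    timepoints_days   = seq(0L, 42L, by = 7L),
    n_animals         = 6L,
    growth_noise_sd   = 0.02,
    # calcein protocol
    calcein_hours     = 48
  )
}
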