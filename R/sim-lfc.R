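#' Simulate paired interspecies log2 fold changes with planted outliers
#'
#' Generates the (TV1, TV6) log2 fold-change pairs that the
#' prediction-interval stage consumes: `x ~ N(0, x_sd^2)`, inliers
#' `y = a + b x + N(0, resid_sd^2)`, and a fraction of outliers that receive
#' an additional residual of random sign and magnitude
#' `outlier_sd + |N(0, (outlier_sd/3)^2)|`. The defaults calibrate the slope
#' to 0.883 and the outlier fraction to roughly 421 of 6786 pairs.
#'
#' @param n Number of pairs (at least 10).
#' @param a,b Intercept and slope of the planted relation.
#' @param resid_sd Inlier residual standard deviation.
#' @param frac_outlier Fraction of pairs planted as outliers.
#' @param outlier_sd Scale of the extra outlier residual.
#' @param x_sd Standard deviation of the x (TV1) log2 fold changes.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_id`, `lfc_tv1`, `lfc_tv6`,
#'   `is_outlier`.
#' @export
#' @examples
#' pairs <- simulate_lfc_pairs(200, seed = 3)
#' mean(pairs$is_outlier)
simulate_lfc_pairs <- function(n = 6786,
                               a = tailprop_defaults()$intercept_a,
                               b = tailprop_defaults()$slope_b,
                               resid_sd = tailprop_defaults()$resid_sd,
                               frac_outlier = tailprop_defaults()$frac_outlier,
                               outlier_sd = tailprop_defaults()$outlier_sd,
                               x_sd = tailprop_defaults()$x_sd,
                               seed = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 10) {
    abort("`n` must be at least 10.")
  }
  stopifnot(resid_sd >= 0, outlier_sd >= 0,
            frac_outlier >= 0, frac_outlier <= 1)
  n <- as.integer(n)
  with_seed(fan_out_seed(seed, "lfc_pairs"), {
    x <- rnorm(n, 0, x_sd)
    y <- a + b * x + rnorm(n, 0, resid_sd)
    n_out <- round(frac_outlier * n)
    is_out <- rep(FALSE, n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      is_out[idx] <- TRUE
      extra <- sample(c(-1, 1), n_out, replace = TRUE) *
        (outlier_sd + abs(rnorm(n_out, 0, outlier_sd / 3)))
      y[idx] <- y[idx] + extra
    }
    tibble(
      gene_id = sprintf("g%05d", seq_len(n)),
      lfc_tv1 = x, lfc_tv6 = y, is_outlier = is_out
    )
  })
}
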