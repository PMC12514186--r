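parse_contrast <- function(contrast) {
  known <- list(
    jTV6_vs_mTV6 = list(num = c("jerboa", "TV6"), den = c("mouse", "TV6"),
                        interspecies = TRUE),
    jTV1_vs_mTV1 = list(num = c("jerboa", "TV1"), den = c("mouse", "TV1"),
                        interspecies = TRUE),
    jTV6_vs_jTV1 = list(num = c("jerboa", "TV6"), den = c("jerboa", "TV1"),
                        interspecies = FALSE)
  )
  if (!contrast %in% names(known)) {
    abort(paste0("Unknown contrast '", contrast, "'. Use one of: ",
                 paste(names(known), collapse = ", "), "."))
  }
  c(known[[contrast]], list(label = contrast))
}

contrast_samples <- function(metadata, side) {
  metadata$sample_id[metadata$species == side[1] &
                       metadata$vertebra == side[2]]
}

#' Negative-binomial Wald test for one contrast
#'
#' Fits, per gene, the NB GLM with log link and mean
#' `s_j * exp(o_gj) * q_{g,group(j)}` for the two groups of the contrast,
#' with the dispersion held fixed at the supplied estimate. The reported
#' log2 fold change is `log2(q_num / q_den)`, its standard error comes from
#' the observed Fisher information of the two group log-means, and the
#' two-sided p-value from the standard normal reference for `lfc / se`.
#'
#' Genes whose counts are all zero in both groups are flagged
#' (`status = "all_zero"`) and get missing statistics; genes all zero in one
#' group get a half-count floor for that group mean and are flagged
#' `"zero_group"`.
#'
#' @param counts Data frame: `gene_id` plus one column per sample.
#' @param metadata Sample table with `sample_id`, `species`, `vertebra`.
#' @param size_factors Tibble with `sample_id`, `size_factor`.
#' @param dispersions Tibble with `gene_id`, `dispersion` (from
#'   [estimate_dispersions()]).
#' @param contrast One of `"jTV6_vs_mTV6"`, `"jTV1_vs_mTV1"`,
#'   `"jTV6_vs_jTV1"`; the first group is the numerator.
#' @param offsets Optional long offset table from [length_offsets()].
#' @return A tibble with `gene_id`, `base_mean`, `lfc`, `se`, `wald_z`, `p`,
#'   `status`, `contrast` (no multiplicity adjustment; see [adjust_bh()]).
#' @export
fit_contrast <- function(counts, metadata, size_factors, dispersions,
                         contrast, offsets = NULL) {
  spec <- parse_contrast(contrast)
  K <- counts_to_matrix(counts)
  num_ids <- intersect(colnames(K), contrast_samples(metadata, spec$num))
  den_ids <- intersect(colnames(K), contrast_samples(metadata, spec$den))
  if (length(num_ids) == 0 || length(den_ids) == 0) {
    abort("Both contrast groups must be present in the counts.")
  }
  sf <- size_factors$size_factor[match(colnames(K), size_factors$sample_id)]
  if (anyNA(sf)) abort("`size_factors` must cover every sample.")
  alpha <- dispersions$dispersion[match(rownames(K), dispersions$gene_id)]
  if (anyNA(alpha)) abort("`dispersions` must cover every gene.")
  O <- offsets_to_matrix(offsets, rownames(K), colnames(K))
  Cc <- sweep(exp(O), 2, sf, "*")

  fit_side <- function(ids) {
    Ks <- K[, ids, drop = FALSE]
    Cs <- Cc[, ids, drop = FALSE]
    zero <- rowSums(Ks) == 0
    eta <- nb_fit_group_eta(Ks, Cs, alpha)
    eta[zero] <- log(0.5 / rowSums(Cs)[zero])
    mu <- Cs * exp(eta)
    info <- rowSums(mu / (1 + alpha * mu))
    list(eta = eta, info = info, zero = zero)
  }
  num <- fit_side(num_ids)
  den <- fit_side(den_ids)

  lfc <- (num$eta - den$eta) / log(2)
  se <- sqrt(1 / num$info + 1 / den$info) / log(2)
  z <- lfc / se
  p <- 2 * pnorm(-abs(z))
  status <- rep("ok", nrow(K))
  status[num$zero | den$zero] <- "zero_group"
  both_zero <- num$zero & den$zero
  status[both_zero] <- "all_zero"
  lfc[both_zero] <- NA_real_
  se[both_zero] <- NA_real_
  z[both_zero] <- NA_real_
  p[both_zero] <- NA_real_

  base_mean <- rowMeans(K[, c(num_ids, den_ids), drop = FALSE] /
                          Cc[, c(num_ids, den_ids), drop = FALSE])
  tibble(
    gene_id = rownames(K), base_mean = unname(base_mean),
    lfc = unname(lfc), se = unname(se), wald_z = unname(z), p = unname(p),
    status = status, contrast = spec$label
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1. Missing p-values are excluded from the number of tests and
#' returned as missing.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (missing allowed).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
adjust_bh <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}
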