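#' Configuration for the count simulator
#'
#' Collects the parameters of the planted-truth RNA-seq simulation: the study
#' design (4 replicates per species and vertebra by default), the
#' negative-binomial noise model, and the four gene classes. Gene classes are:
#'
#' * `null` - no expression difference anywhere;
#' * `equivalent` - differentially expressed between species in both TV1 and
#'   TV6, with TV6 log2FC following the planted linear relation
#'   `y = a + b x` plus residual scatter;
#' * `A_type` - differentially expressed between species in TV6 only
#'   (`lfc_TV1 = 0`);
#' * `B_type` - differentially expressed in both, but with a large extra
#'   residual off the line (disproportionate).
#'
#' The four group means per gene are parameterized so that the interspecies
#' TV1 and TV6 contrasts and the intra-jerboa TV6-versus-TV1 contrast are all
#' derivable from one ground truth: `mouseTV1 = baseline`,
#' `mouseTV6 = baseline + delta_vert`, `jerboaTV1 = mouseTV1 + lfc_TV1`,
#' `jerboaTV6 = mouseTV6 + lfc_TV6` (log2 scale), so the intra-jerboa log2FC
#' equals `delta_vert + lfc_TV6 - lfc_TV1`.
#'
#' @param n_genes,n_reps Design size.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log2 expression
#'   is drawn `N(baseline_log_mean, baseline_log_sd^2)`.
#' @param dispersion NB dispersion, a scalar or per-gene vector.
#' @param frac_equivalent,frac_A,frac_B Gene-class fractions; the rest are null.
#' @param slope_b,intercept_a Planted TV6-versus-TV1 log2FC relation.
#' @param resid_sd Residual scatter of equivalent genes around the line.
#' @param outlier_sd Scale of the extra residual of B-type genes: their extra
#'   offset is `sign * (outlier_sd + |N(0, (outlier_sd/3)^2)|)`.
#' @param x_sd Spread of interspecies TV1 log2FCs for equivalent/B-type genes.
#' @param delta_vert_sd Spread of the shared TV6-minus-TV1 baseline shift.
#' @param effect_min,effect_max A-type |log2FC| is uniform on this range.
#' @param length_log_sd Passed to [simulate_ortholog_table()] when no table is
#'   supplied.
#' @param size_factor_range Sample-specific size factors are uniform on this
#'   range.
#' @param seed Master seed for the simulation.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = tailprop_defaults()$n_genes,
                       n_reps = tailprop_defaults()$n_reps,
                       baseline_log_mean = tailprop_defaults()$baseline_log_mean,
                       baseline_log_sd = tailprop_defaults()$baseline_log_sd,
                       dispersion = tailprop_defaults()$dispersion,
                       frac_equivalent = tailprop_defaults()$frac_equivalent,
                       frac_A = tailprop_defaults()$frac_A,
                       frac_B = tailprop_defaults()$frac_B,
                       slope_b = tailprop_defaults()$slope_b,
                       intercept_a = tailprop_defaults()$intercept_a,
                       resid_sd = tailprop_defaults()$resid_sd,
                       outlier_sd = tailprop_defaults()$outlier_sd,
                       x_sd = tailprop_defaults()$x_sd,
                       delta_vert_sd = tailprop_defaults()$delta_vert_sd,
                       effect_min = tailprop_defaults()$effect_min,
                       effect_max = tailprop_defaults()$effect_max,
                       length_log_sd = tailprop_defaults()$length_log_sd,
                       size_factor_range = tailprop_defaults()$size_factor_range,
                       seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion = dispersion,
    frac_equivalent = frac_equivalent, frac_A = frac_A, frac_B = frac_B,
    slope_b = slope_b, intercept_a = intercept_a, resid_sd = resid_sd,
    outlier_sd = outlier_sd, x_sd = x_sd, delta_vert_sd = delta_vert_sd,
    effect_min = effect_min, effect_max = effect_max,
    length_log_sd = length_log_sd, size_factor_range = size_factor_range,
    seed = seed
  )
  if (cfg$n_genes < 1) abort("`n_genes` must be positive.")
  if (cfg$n_reps < 2) abort("`n_reps` must be at least 2.")
  if (frac_equivalent + frac_A + frac_B > 1) {
    abort("Gene-class fractions must sum to at most 1.")
  }
  if (any(c(resid_sd, outlier_sd, baseline_log_sd, delta_vert_sd,
            length_log_sd) < 0) || any(dispersion < 0)) {
    abort("Standard deviations and dispersions must be non-negative.")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate gene-level counts with planted ground truth
#'
#' Draws a negative-binomial count matrix for the 2 species x 2 vertebrae x
#' `n_reps` design. The mean for gene g in sample j is
#' `s_j * (L_gs / Lbar_g) * 2^(baseline_g + effect)`, where `s_j` is the
#' sample size factor, `L_gs` the transcript length in the sample's species,
#' `Lbar_g` the geometric mean of the two lengths (genes lacking a jerboa
#' length contribute no length factor), and the group effect follows the
#' ground-truth parameterization described in [sim_config()].
#'
#' @param config A [sim_config()] object.
#' @param ortholog_table Optional table from [simulate_ortholog_table()]; one
#'   row per gene. Generated from the config when omitted.
#' @return A list with tibbles `counts` (gene_id plus one column per sample),
#'   `metadata` (sample_id, species, vertebra, replicate), `truth` (per-gene
#'   class and planted log2 fold changes), and `orthologs`.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 50, seed = 7))
#' dplyr::count(sim$truth, class)
simulate_counts <- function(config = sim_config(), ortholog_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (is.null(ortholog_table)) {
    ortholog_table <- simulate_ortholog_table(
      n, length_log_sd = config$length_log_sd, seed = config$seed
    )
  }
  if (nrow(ortholog_table) != n) {
    abort("`ortholog_table` must have one row per gene in the config.")
  }
  gene_id <- ortholog_table$gene_id

  truth <- with_seed(fan_out_seed(config$seed, "truth"), {
    n_eq <- round(config$frac_equivalent * n)
    n_a <- round(config$frac_A * n)
    n_b <- round(config$frac_B * n)
    cls <- rep("null", n)
    idx <- sample.int(n, n_eq + n_a + n_b)
    cls[idx[seq_len(n_eq)]] <- "equivalent"
    cls[idx[n_eq + seq_len(n_a)]] <- "A_type"
    cls[idx[n_eq + n_a + seq_len(n_b)]] <- "B_type"
    lfc_tv1 <- numeric(n)
    lfc_tv6 <- numeric(n)
    eq <- cls == "equivalent"
    lfc_tv1[eq] <- rnorm(sum(eq), 0, config$x_sd)
    lfc_tv6[eq] <- config$intercept_a + config$slope_b * lfc_tv1[eq] +
      rnorm(sum(eq), 0, config$resid_sd)
    aa <- cls == "A_type"
    lfc_tv6[aa] <- sample(c(-1, 1), sum(aa), replace = TRUE) *
      runif(sum(aa), config$effect_min, config$effect_max)
    bb <- cls == "B_type"
    lfc_tv1[bb] <- rnorm(sum(bb), 0, config$x_sd)
    extra <- sample(c(-1, 1), sum(bb), replace = TRUE) *
      (config$outlier_sd + abs(rnorm(sum(bb), 0, config$outlier_sd / 3)))
    lfc_tv6[bb] <- config$intercept_a + config$slope_b * lfc_tv1[bb] + extra
    delta_vert <- rnorm(n, 0, config$delta_vert_sd)
    tibble(
      gene_id = gene_id, class = cls,
      lfc_TV1 = lfc_tv1, lfc_TV6 = lfc_tv6, delta_vert = delta_vert,
      lfc_intra = delta_vert + lfc_tv6 - lfc_tv1
    )
  })

  groups <- tidyr::expand_grid(
    species = c("mouse", "jerboa"), vertebra = c("TV1", "TV6")
  )
  metadata <- tidyr::expand_grid(groups, replicate = seq_len(config$n_reps)) |>
    mutate(sample_id = paste(substr(.data$species, 1, 1), .data$vertebra,
                             .data$replicate, sep = "_")) |>
    select("sample_id", "species", "vertebra", "replicate")

  counts <- with_seed(fan_out_seed(config$seed, "counts"), {
    baseline <- config$baseline_log_mean +
      rnorm(n, 0, config$baseline_log_sd)
    lbar <- ifelse(
      is.na(ortholog_table$length_jerboa),
      ortholog_table$length_mouse,
      sqrt(ortholog_table$length_mouse * ortholog_table$length_jerboa)
    )
    lfac <- cbind(
      mouse = ortholog_table$length_mouse / lbar,
      jerboa = ifelse(is.na(ortholog_table$length_jerboa), 1,
                      ortholog_table$length_jerboa / lbar)
    )
    effect <- cbind(
      mouse_TV1 = rep(0, n),
      mouse_TV6 = truth$delta_vert,
      jerboa_TV1 = truth$lfc_TV1,
      jerboa_TV6 = truth$delta_vert + truth$lfc_TV6
    )
    s <- runif(nrow(metadata), config$size_factor_range[1],
               config$size_factor_range[2])
    size <- 1 / pmax(config$dispersion, 1e-12)
    K <- matrix(0L, n, nrow(metadata))
    for (j in seq_len(nrow(metadata))) {
      grp <- paste(metadata$species[j], metadata$vertebra[j], sep = "_")
      mu <- s[j] * lfac[, metadata$species[j]] *
        2^(baseline + effect[, grp])
      K[, j] <- rnbinom(n, mu = mu, size = size)
    }
    colnames(K) <- metadata$sample_id
    bind_cols(tibble(gene_id = gene_id), as_tibble(K))
  })

  list(counts = counts, metadata = metadata, truth = truth,
       orthologs = ortholog_table)
}
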