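# Shared fixtures, built in code.

# 5-gene x 3-sample toy count matrix with non-proportional columns
toy_counts <- function() {
  tibble::tibble(
    gene_id = paste0("g", 1:5),
    s1 = c(12L, 100L, 40L, 7L, 500L),
    s2 = c(30L, 210L, 44L, 16L, 900L),
    s3 = c(25L, 160L, 80L, 9L, 1100L)
  )
}

# minimal two-group metadata (jerboa TV6 vs mouse TV6)
two_group_meta <- function(n_reps) {
  tibble::tibble(
    sample_id = c(paste0("m", seq_len(n_reps)), paste0("j", seq_len(n_reps))),
    species = rep(c("mouse", "jerboa"), each = n_reps),
    vertebra = "TV6",
    replicate = rep(seq_len(n_reps), 2)
  )
}

# NB counts for a two-group design with per-gene log2 fold changes
nb_two_group_counts <- function(n_genes, n_reps, lfc, dispersion,
                                base_mean = 200, size_factors = NULL,
                                seed = 1) {
  set.seed(seed)
  stopifnot(length(lfc) %in% c(1, n_genes))
  lfc <- rep_len(lfc, n_genes)
  sf <- size_factors %||% rep(1, 2 * n_reps)
  mu_m <- base_mean * 2^(-lfc / 2)
  mu_j <- base_mean * 2^(lfc / 2)
  size <- 1 / max(dispersion, 1e-12)
  K <- sapply(seq_len(2 * n_reps), function(j) {
    mu <- if (j <= n_reps) mu_m else mu_j
    rnbinom(n_genes, mu = mu * sf[j], size = size)
  })
  meta <- two_group_meta(n_reps)
  colnames(K) <- meta$sample_id
  list(
    counts = dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes))),
      tibble::as_tibble(K)
    ),
    metadata = meta
  )
}

unit_size_factors <- function(metadata) {
  tibble::tibble(sample_id = metadata$sample_id, size_factor = 1)
}

`%||%` <- rlang::`%||%`
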