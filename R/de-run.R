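#' Run one differential-expression contrast end to end
#'
#' Composes the DE stage: median-of-ratios size factors, cross-species
#' gene-length offsets (interspecies contrasts only), dispersion estimation
#' on the contrast's samples, the NB Wald test, and Benjamini-Hochberg
#' adjustment. Interspecies contrasts are restricted to genes with lengths in
#' both species (one-to-one orthologs); one-to-zero genes are retained for
#' the intra-jerboa contrast. Genes with fewer than 2 samples reaching 10
#' counts within the contrast are filtered before testing and carry missing
#' p-values (`status = "low_counts"`).
#'
#' @param counts Data frame: `gene_id` plus one column per sample.
#' @param metadata Sample table with `sample_id`, `species`, `vertebra`.
#' @param ortholog_table Ortholog table with per-species lengths; required
#'   for interspecies contrasts.
#' @param contrast `"jTV6_vs_mTV6"`, `"jTV1_vs_mTV1"` or `"jTV6_vs_jTV1"`.
#' @param alpha Significance threshold recorded alongside the result.
#' @param shrink Use trend-shrunken dispersions (recommended; see
#'   [estimate_dispersions()]).
#' @param min_count,min_samples Expression filter: keep genes with at least
#'   `min_count` counts in at least `min_samples` samples of the contrast.
#' @param path Optional path; when given the result is also written as TSV.
#' @return A tibble with `gene_id`, `base_mean`, `lfc`, `se`, `wald_z`, `p`,
#'   `padj`, `significant`, `status`, `contrast`.
#' @export
run_de <- function(counts, metadata, ortholog_table = NULL,
                   contrast = "jTV6_vs_mTV6",
                   alpha = tailprop_defaults()$alpha,
                   shrink = TRUE, min_count = 10, min_samples = 2,
                   path = NULL) {
  spec <- parse_contrast(contrast)
  sample_ids <- c(contrast_samples(metadata, spec$num),
                  contrast_samples(metadata, spec$den))
  sample_ids <- intersect(names(counts), sample_ids)
  sub_counts <- counts[, c("gene_id", sample_ids)]
  sub_meta <- metadata[metadata$sample_id %in% sample_ids, , drop = FALSE]

  excluded <- tibble(gene_id = character(0), status = character(0))
  offsets <- NULL
  if (spec$interspecies) {
    if (is.null(ortholog_table)) {
      abort("Interspecies contrasts need an `ortholog_table` with lengths.")
    }
    has_len <- !is.na(ortholog_table$length_mouse) &
      !is.na(ortholog_table$length_jerboa)
    keep_ids <- ortholog_table$gene_id[has_len]
    dropped <- setdiff(sub_counts$gene_id, keep_ids)
    excluded <- bind_rows(excluded,
                          tibble(gene_id = dropped, status = "no_length"))
    sub_counts <- sub_counts[sub_counts$gene_id %in% keep_ids, , drop = FALSE]
    offsets <- length_offsets(
      ortholog_table[has_len & ortholog_table$gene_id %in% sub_counts$gene_id,
                     , drop = FALSE],
      sub_meta
    )
  }

  size_factors <- compute_size_factors(sub_counts)

  K <- counts_to_matrix(sub_counts)
  expressed <- rowSums(K >= min_count) >= min_samples
  low <- tibble(gene_id = rownames(K)[!expressed], status = "low_counts")
  excluded <- bind_rows(excluded, low)
  tested <- sub_counts[expressed, , drop = FALSE]
  if (nrow(tested) == 0) abort("No gene passes the expression filter.")

  disp <- estimate_dispersions(
    tested, size_factors, sub_meta,
    groups = c("species", "vertebra"),
    offsets = offsets, shrink = shrink
  )
  res <- fit_contrast(tested, sub_meta, size_factors, disp, contrast,
                      offsets = offsets)
  res$padj <- adjust_bh(res$p)
  res$significant <- !is.na(res$padj) & res$padj < alpha

  out <- bind_rows(
    res,
    excluded |>
      mutate(base_mean = NA_real_, lfc = NA_real_, se = NA_real_,
             wald_z = NA_real_, p = NA_real_, padj = NA_real_,
             significant = FALSE, contrast = spec$label)
  ) |>
    arrange(match(.data$gene_id, counts$gene_id)) |>
    select("gene_id", "base_mean", "lfc", "se", "wald_z", "p", "padj",
           "significant", "status", "contrast")
  if (!is.null(path)) readr::write_tsv(out, path)
  out
}

#' Principal-component sanity check of normalized counts
#'
#' Projects samples onto the top principal components of gene-wise centered
#' `log2(count / size_factor + 1)`. In a well-behaved cross-species
#' experiment the first component separates the species.
#'
#' @param counts Data frame: `gene_id` plus one column per sample.
#' @param metadata Sample table joined onto the scores.
#' @param size_factors Optional; computed with [compute_size_factors()] when
#'   missing.
#' @param n_components Number of components to return.
#' @return A list with `scores` (tibble: sample metadata plus `PC1..PCk`) and
#'   `variance` (tibble: `component`, `variance_fraction`).
#' @export
pca_check <- function(counts, metadata, size_factors = NULL,
                      n_components = 2) {
  K <- counts_to_matrix(counts)
  if (ncol(K) < 3) abort("PCA needs at least 3 samples.")
  if (n_components > ncol(K)) {
    abort("Cannot request more components than samples.")
  }
  if (is.null(size_factors)) {
    size_factors <- compute_size_factors(counts, pseudo_reference = TRUE)
  }
  sf <- size_factors$size_factor[match(colnames(K), size_factors$sample_id)]
  X <- log2(sweep(K, 2, sf, "/") + 1)
  X <- X - rowMeans(X)
  pc <- prcomp(t(X), center = FALSE)
  k <- seq_len(n_components)
  scores <- as_tibble(pc$x[, k, drop = FALSE]) |>
    mutate(sample_id = colnames(K), .before = 1)
  if (!is.null(metadata)) {
    scores <- left_join(scores, as_tibble(metadata), by = "sample_id")
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = scores,
    variance = tibble(component = paste0("PC", seq_along(varfrac)),
                      variance_fraction = varfrac)
  )
}
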