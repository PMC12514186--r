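counts_to_matrix <- function(counts) {
  if (!is.data.frame(counts) || !"gene_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `gene_id` column.")
  }
  if (anyDuplicated(counts$gene_id)) abort("Gene identifiers must be unique.")
  K <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  if (any(K < 0) || any(K != floor(K))) {
    abort("Counts must be non-negative integers.")
  }
  rownames(K) <- counts$gene_id
  storage.mode(K) <- "double"
  K
}

#' Median-of-ratios size factors
#'
#' Computes the reference normalization of bulk RNA-seq counts: each sample's
#' size factor is the median, over usable genes, of the ratio of the sample's
#' count to the gene's geometric mean across samples. Usable genes are those
#' with no zero count in any sample, so the geometric-mean reference is
#' well defined; with `pseudo_reference = TRUE` the geometric mean is taken
#' over positive counts only, which rescues sparse toy matrices. Factors are
#' returned unnormalized (no rescaling to unit geometric mean).
#'
#' @param counts Data frame: `gene_id` plus one integer column per sample.
#' @param pseudo_reference Use a positive-count pseudo-reference when no gene
#'   is free of zeros.
#' @return A tibble with `sample_id` and `size_factor`.
#' @export
#' @examples
#' toy <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10L, 20L),
#'                       s2 = c(20L, 40L))
#' compute_size_factors(toy)
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  K <- counts_to_matrix(counts)
  if (ncol(K) < 1) abort("`counts` must contain at least one sample column.")
  if (pseudo_reference) {
    logg <- log(K)
    logg[!is.finite(logg)] <- NA
    geo <- exp(rowMeans(logg, na.rm = TRUE))
    usable <- is.finite(geo) & geo > 0
  } else {
    usable <- rowSums(K == 0) == 0
    if (!any(usable)) {
      abort(paste(
        "No gene has all-positive counts, so the median-of-ratios reference",
        "is undefined. Rerun with `pseudo_reference = TRUE` to use a",
        "positive-count pseudo-reference."
      ))
    }
    geo <- exp(rowMeans(log(pmax(K, 1e-300))))
  }
  ratios <- K[usable, , drop = FALSE] / geo[usable]
  sf <- apply(ratios, 2, function(r) median(r[r > 0 | !pseudo_reference]))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    abort("Size factors could not be computed (non-positive medians).")
  }
  tibble(sample_id = colnames(K), size_factor = unname(sf))
}

#' Cross-species gene-length offsets for the NB GLM
#'
#' When the same gene is measured against two genomes, its transcript length
#' differs between species and so does the expected read count at equal
#' expression. The offset places each sample's expected count on the scale of
#' the gene's species-specific length: for gene g in a sample of species s,
#' `o_gs = ln(L_gs / sqrt(L_g,mouse * L_g,jerboa))`. Offsets are centered by
#' the geometric mean of the two lengths so they sum to zero across species
#' on the log scale, leaving intra-species contrasts untouched.
#'
#' @param ortholog_table Table with `gene_id`, `length_mouse`,
#'   `length_jerboa` (see [simulate_ortholog_table()]).
#' @param metadata Sample table with `sample_id` and `species`
#'   (`"mouse"`/`"jerboa"`).
#' @return A tibble with `gene_id`, `sample_id`, `offset` (natural-log
#'   scale), one row per gene and sample.
#' @export
length_offsets <- function(ortholog_table, metadata) {
  stopifnot(all(c("gene_id", "length_mouse", "length_jerboa") %in%
                  names(ortholog_table)),
            all(c("sample_id", "species") %in% names(metadata)))
  if (!all(metadata$species %in% c("mouse", "jerboa"))) {
    abort("`metadata$species` must be 'mouse' or 'jerboa'.")
  }
  need_j <- any(metadata$species == "jerboa")
  need_m <- any(metadata$species == "mouse")
  if ((need_j && anyNA(ortholog_table$length_jerboa)) ||
      (need_m && anyNA(ortholog_table$length_mouse))) {
    abort(paste(
      "Every gene needs a length for each species present in the contrast;",
      "exclude one-to-zero genes from interspecies contrasts first."
    ))
  }
  if (any(ortholog_table$length_mouse <= 0, na.rm = TRUE) ||
      any(ortholog_table$length_jerboa <= 0, na.rm = TRUE)) {
    abort("Gene lengths must be positive.")
  }
  lbar <- sqrt(ortholog_table$length_mouse * ortholog_table$length_jerboa)
  per_species <- tibble(
    gene_id = rep(ortholog_table$gene_id, 2),
    species = rep(c("mouse", "jerboa"), each = nrow(ortholog_table)),
    offset = c(log(ortholog_table$length_mouse / lbar),
               log(ortholog_table$length_jerboa / lbar))
  )
  metadata |>
    select("sample_id", "species") |>
    inner_join(per_species, by = "species", relationship = "many-to-many") |>
    select("gene_id", "sample_id", "offset") |>
    arrange(.data$gene_id, .data$sample_id)
}

offsets_to_matrix <- function(offsets, gene_ids, sample_ids) {
  O <- matrix(0, length(gene_ids), length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  if (is.null(offsets)) return(O)
  keep <- offsets$gene_id %in% gene_ids & offsets$sample_id %in% sample_ids
  if (nrow(offsets) > 0 && !any(keep)) {
    abort("None of the supplied offsets match the counts' genes and samples.")
  }
  off <- offsets[keep, , drop = FALSE]
  O[cbind(match(off$gene_id, gene_ids), match(off$sample_id, sample_ids))] <-
    off$offset
  O
}
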