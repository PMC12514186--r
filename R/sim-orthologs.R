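#' Simulate a cross-species ortholog table with per-species gene lengths
#'
#' Emulates an orthology annotation between mouse and jerboa: mouse transcript
#' lengths are log-normal around 2 kb, jerboa lengths differ from the mouse
#' length by a log-normal factor with standard deviation `length_log_sd`, and
#' a small fraction of genes carry the one-to-zero classification (predicted
#' lost or unannotated in jerboa, so no jerboa length is available). Genes in
#' the one-to-zero class are retained for intra-species contrasts but cannot
#' enter interspecies contrasts, which require both lengths.
#'
#' @param n_genes Number of genes to generate.
#' @param length_log_sd Standard deviation of the natural-log jerboa/mouse
#'   length ratio.
#' @param frac_one_to_zero Fraction of genes flagged one-to-zero.
#' @param seed Integer seed; the table is a pure function of the arguments.
#' @return A tibble with columns `gene_id`, `orthology_class`
#'   (`"one_to_one"` or `"one_to_zero"`), `length_mouse`, `length_jerboa`
#'   (`NA` for one-to-zero genes).
#' @export
#' @examples
#' simulate_ortholog_table(5, seed = 1)
simulate_ortholog_table <- function(n_genes,
                                    length_log_sd = tailprop_defaults()$length_log_sd,
                                    frac_one_to_zero = tailprop_defaults()$frac_one_to_zero,
                                    seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    abort("`n_genes` must be a positive integer.")
  }
  n_genes <- as.integer(n_genes)
  stopifnot(length_log_sd >= 0, frac_one_to_zero >= 0, frac_one_to_zero < 1)
  with_seed(fan_out_seed(seed, "orthologs"), {
    length_mouse <- pmax(200, round(exp(log(2000) + rnorm(n_genes, 0, 0.6))))
    ratio <- exp(rnorm(n_genes, 0, length_log_sd))
    length_jerboa <- pmax(200, round(length_mouse * ratio))
    n_zero <- round(frac_one_to_zero * n_genes)
    zero_idx <- if (n_zero > 0) sample.int(n_genes, n_zero) else integer(0)
    cls <- rep("one_to_one", n_genes)
    cls[zero_idx] <- "one_to_zero"
    length_jerboa[zero_idx] <- NA_real_
    tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      orthology_class = cls,
      length_mouse = as.numeric(length_mouse),
      length_jerboa = as.numeric(length_jerboa)
    )
  })
}
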