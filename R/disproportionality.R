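#' Assemble the per-gene contrast-pair table
#'
#' Joins the three DE results on gene identifiers: the interspecies TV1
#' contrast (x-axis), the interspecies TV6 contrast (y-axis), and the
#' intra-jerboa TV6-versus-TV1 contrast. Positive log2 fold changes mean
#' higher in jerboa (interspecies) or higher in TV6 (intra-jerboa). Missing
#' adjusted p-values count as not significant downstream.
#'
#' @param de_tv1,de_tv6,de_intra DE result tibbles from [run_de()].
#' @return A tibble with one row per gene: `gene_id`, `lfc_x`, `padj_x`,
#'   `lfc_y`, `padj_y`, `lfc_intra`, `padj_intra`.
#' @export
contrast_pairs <- function(de_tv1, de_tv6, de_intra) {
  sel <- function(d, suffix) {
    d |>
      select("gene_id", "lfc", "padj") |>
      setNames(c("gene_id", paste0(c("lfc_", "padj_"), suffix)))
  }
  sel(de_tv1, "x") |>
    dplyr::full_join(sel(de_tv6, "y"), by = "gene_id") |>
    dplyr::full_join(sel(de_intra, "intra"), by = "gene_id")
}

sig <- function(padj, alpha) !is.na(padj) & padj < alpha

#' Genes differentially expressed between species in TV6 only
#'
#' @param pairs Contrast-pair table from [contrast_pairs()].
#' @param alpha Adjusted-p significance threshold.
#' @return The subset of `pairs` significant in TV6 but not TV1 (set A).
#' @export
classify_tv6_only <- function(pairs, alpha = tailprop_defaults()$alpha) {
  pairs |> filter(sig(.data$padj_y, alpha) & !sig(.data$padj_x, alpha))
}

#' Ordinary least squares of TV6 on TV1 log2 fold changes
#'
#' Fits `lfc_y ~ lfc_x` over exactly the genes significant in both
#' interspecies contrasts, the population the prediction interval is defined
#' on. Returns the fit statistics needed to evaluate the interval at any
#' point: intercept, slope, n, mean and centered sum of squares of x,
#' residual standard error on n - 2 degrees of freedom, and the two-sided
#' Student critical value at the requested level.
#'
#' @param pairs Contrast-pair table from [contrast_pairs()].
#' @param alpha Adjusted-p significance threshold selecting the fitted set.
#' @param level Prediction-interval level (default 0.95).
#' @return An object of class `"pi_fit"`.
#' @export
fit_lfc_regression <- function(pairs, alpha = tailprop_defaults()$alpha,
                               level = tailprop_defaults()$pi_level) {
  stopifnot(level > 0, level < 1)
  both <- pairs |> filter(sig(.data$padj_x, alpha) & sig(.data$padj_y, alpha))
  n <- nrow(both)
  if (n < 3) {
    abort("At least 3 genes significant in both contrasts are required.")
  }
  x <- both$lfc_x
  y <- both$lfc_y
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) abort("Degenerate regression: no variation in `lfc_x`.")
  fit <- lm(y ~ x)
  res <- stats::residuals(fit)
  s_e <- sqrt(sum(res^2) / (n - 2))
  r2 <- if (var(y) > 0) 1 - sum(res^2) / sum((y - mean(y))^2) else NA_real_
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      n = n, x_bar = mean(x), s_xx = sxx, s_e = s_e, r2 = r2,
      level = level, t_crit = qt(1 - (1 - level) / 2, df = n - 2),
      alpha = alpha
    ),
    class = "pi_fit"
  )
}

#' Prediction interval for a new observation
#'
#' The standard OLS prediction interval for a fresh response at `x0`:
#' `yhat +/- t * s_e * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)`.
#'
#' @param fit A `"pi_fit"` from [fit_lfc_regression()].
#' @param x0 Numeric vector of x positions.
#' @return A tibble with `x`, `fit`, `lo`, `hi`.
#' @export
prediction_interval <- function(fit, x0) {
  stopifnot(inherits(fit, "pi_fit"), is.numeric(x0))
  yhat <- fit$intercept + fit$slope * x0
  hw <- fit$t_crit * fit$s_e *
    sqrt(1 + 1 / fit$n + (x0 - fit$x_bar)^2 / fit$s_xx)
  tibble(x = x0, fit = yhat, lo = yhat - hw, hi = yhat + hw)
}

#' Both-significant genes outside the prediction interval
#'
#' Among genes significant in both interspecies contrasts, flags those whose
#' TV6 log2 fold change falls strictly outside the prediction interval
#' evaluated at their TV1 log2 fold change (set B, "disproportionately
#' differentially expressed"). Boundary-exact values count as inside.
#'
#' @param pairs Contrast-pair table from [contrast_pairs()].
#' @param fit A `"pi_fit"` fitted on the same table and alpha.
#' @param alpha Adjusted-p significance threshold.
#' @return The subset of `pairs` outside the interval, with columns `lo`,
#'   `hi` appended.
#' @export
classify_outside_pi <- function(pairs, fit,
                                alpha = tailprop_defaults()$alpha) {
  stopifnot(inherits(fit, "pi_fit"))
  both <- pairs |> filter(sig(.data$padj_x, alpha) & sig(.data$padj_y, alpha))
  pi <- prediction_interval(fit, both$lfc_x)
  both |>
    mutate(lo = pi$lo, hi = pi$hi) |>
    filter(.data$lfc_y < .data$lo | .data$lfc_y > .data$hi)
}

#' Sign-consistent intersection with the intra-jerboa contrast
#'
#' Final candidate filter: a gene in the disproportionate set D must also be
#' significant in the intra-jerboa TV6-versus-TV1 contrast with the same
#' fold-change sign as its interspecies TV6 response. Direction is up when
#' both are positive (higher in jerboa TV6) and down when both are negative.
#'
#' @param pairs Contrast-pair table from [contrast_pairs()].
#' @param set_d Character vector of gene ids (A union B).
#' @param alpha Adjusted-p significance threshold.
#' @return The candidate subset of `pairs` with a `direction` column.
#' @export
sign_consistent_intersection <- function(pairs, set_d,
                                         alpha = tailprop_defaults()$alpha) {
  d <- pairs |>
    filter(.data$gene_id %in% set_d, sig(.data$padj_intra, alpha))
  zero_sig <- d$lfc_y == 0 | d$lfc_intra == 0
  if (any(zero_sig, na.rm = TRUE)) {
    warn("Genes with zero log2FC but significant padj were excluded.")
  }
  d |>
    filter(!is.na(.data$lfc_y), !is.na(.data$lfc_intra),
           sign(.data$lfc_y) == sign(.data$lfc_intra),
           .data$lfc_y != 0, .data$lfc_intra != 0) |>
    mutate(direction = ifelse(.data$lfc_y > 0, "up_in_jerboa_TV6",
                              "down_in_jerboa_TV6"))
}

#' Full disproportionality classification
#'
#' Runs the whole intersection: set A (TV6-only), the OLS fit over the
#' both-significant set, set B (outside the prediction interval),
#' D = A union B, and the sign-consistent intra-jerboa candidates.
#'
#' @param pairs Contrast-pair table from [contrast_pairs()].
#' @param alpha Adjusted-p significance threshold used by every stage.
#' @param level Prediction-interval level.
#' @return An object of class `"disprop_result"`: a list with `categories`
#'   (per-gene tibble: `gene_id`, `category` in A/B/equivalent/none,
#'   `candidate`, `direction`), `fit` (the `"pi_fit"`), `sets` (character
#'   vectors `A`, `pairs`, `B`, `D`, `candidates`), and `counts`.
#' @export
#' @examples
#' pr <- simulate_lfc_pairs(500, seed = 2)
#' tbl <- tibble::tibble(gene_id = pr$gene_id, lfc_x = pr$lfc_tv1,
#'                       padj_x = 0.01, lfc_y = pr$lfc_tv6, padj_y = 0.01,
#'                       lfc_intra = pr$lfc_tv6, padj_intra = 0.01)
#' res <- disproportionality(tbl)
#' res$counts
disproportionality <- function(pairs, alpha = tailprop_defaults()$alpha,
                               level = tailprop_defaults()$pi_level) {
  set_a <- classify_tv6_only(pairs, alpha)$gene_id
  fit <- fit_lfc_regression(pairs, alpha, level)
  both <- pairs |>
    filter(sig(.data$padj_x, alpha) & sig(.data$padj_y, alpha))
  set_b <- classify_outside_pi(pairs, fit, alpha)$gene_id
  set_d <- union(set_a, set_b)
  cand <- sign_consistent_intersection(pairs, set_d, alpha)
  categories <- pairs |>
    mutate(
      category = dplyr::case_when(
        .data$gene_id %in% set_a ~ "A",
        .data$gene_id %in% set_b ~ "B",
        .data$gene_id %in% both$gene_id ~ "equivalent",
        TRUE ~ "none"
      ),
      candidate = .data$gene_id %in% cand$gene_id,
      direction = cand$direction[match(.data$gene_id, cand$gene_id)]
    ) |>
    select("gene_id", "lfc_x", "lfc_y", "category", "candidate", "direction")
  structure(
    list(
      categories = categories, fit = fit,
      sets = list(A = set_a, pairs = both$gene_id, B = set_b, D = set_d,
                  candidates = cand$gene_id),
      counts = c(A = length(set_a), pairs = nrow(both), B = length(set_b),
                 D = length(set_d), candidates = nrow(cand)),
      alpha = alpha, level = level
    ),
    class = "disprop_result"
  )
}

#' Collate candidates against external gene lists
#'
#' Cross-references candidate genes with external limb-proportion datasets
#' and mutant-phenotype annotations. Matching is case-insensitive exact
#' string match; no alias resolution is attempted. A candidate is
#' highlighted when it has a reported tail phenotype or appears in at least
#' `highlight_min` external datasets.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param external_sets Named list of character vectors (external datasets).
#' @param phenotype_genes Character vector of genes with a reported tail
#'   mutant phenotype.
#' @param highlight_min Dataset-count threshold for highlighting.
#' @return A tibble with one row per candidate: membership flags per dataset,
#'   `phenotype`, `n_datasets`, `highlight`; the attribute `common_to_all`
#'   holds the genes present in every external dataset.
#' @export
collate_candidates <- function(candidates, external_sets,
                               phenotype_genes = character(0),
                               highlight_min = 3) {
  if (length(external_sets) == 0) {
    abort("`external_sets` must contain at least one gene list.")
  }
  if (is.null(names(external_sets)) || any(names(external_sets) == "")) {
    abort("`external_sets` must be a named list.")
  }
  lc <- function(x) tolower(trimws(x))
  sets_lc <- lapply(external_sets, lc)
  pheno_lc <- lc(phenotype_genes)
  member <- vapply(sets_lc, function(s) lc(candidates) %in% s,
                   logical(length(candidates)))
  member <- matrix(member, nrow = length(candidates),
                   dimnames = list(NULL, names(external_sets)))
  out <- bind_cols(
    tibble(gene = candidates),
    as_tibble(member)
  ) |>
    mutate(
      phenotype = lc(candidates) %in% pheno_lc,
      n_datasets = rowSums(member),
      highlight = .data$phenotype | .data$n_datasets >= highlight_min
    )
  common <- Reduce(intersect, sets_lc)
  attr(out, "common_to_all") <-
    candidates[lc(candidates) %in% common]
  out
}

#' Collated candidate genes for vertebral and limb proportion
#'
#' The twenty candidate genes associated with both vertebral and limb
#' proportion, with their membership in four external limb-proportion
#' datasets and their reported tail mutant phenotype status. Dataset tags:
#' `shr` - human GWAS of leg-to-body proportion; `jh` - jerboa hindlimb
#' candidates; `my` - young-versus-mature tibia expression; `tp` - proximal
#' tibia versus distal phalanx expression.
#'
#' @return A tibble with columns `gene`, `shr`, `jh`, `my`, `tp`,
#'   `tail_phenotype`.
#' @export
#' @examples
#' head(table1_candidates())
table1_candidates <- function() {
  readr::read_tsv(
    system.file("extdata", "table1_candidates.tsv", package = "tailprop"),
    col_types = readr::cols(
      gene = readr::col_character(), .default = readr::col_logical()
    )
  )
}

#' @export
print.pi_fit <- function(x, ...) {
  cat(sprintf(
    "OLS log2FC regression: y = %.4f + %.4f x (n = %d, R^2 = %.3f)\n",
    x$intercept, x$slope, x$n, x$r2
  ))
  cat(sprintf("Residual SE %.4f; %.0f%% prediction interval (t = %.3f)\n",
              x$s_e, 100 * x$level, x$t_crit))
  invisible(x)
}

#' @export
print.disprop_result <- function(x, ...) {
  cat("Disproportionality classification\n")
  cat(sprintf(
    "  TV6-only (A): %d | both-significant pairs: %d | outside PI (B): %d\n",
    x$counts[["A"]], x$counts[["pairs"]], x$counts[["B"]]
  ))
  cat(sprintf("  D = A union B: %d | sign-consistent candidates: %d\n",
              x$counts[["D"]], x$counts[["candidates"]]))
  invisible(x)
}

#' Tidy the prediction-interval regression fit
#'
#' @param x A `"pi_fit"` object.
#' @param ... Unused.
#' @return One row per coefficient with `term` and `estimate`.
#' @method tidy pi_fit
#' @export
tidy.pi_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "lfc_x"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of the prediction-interval regression fit
#'
#' @param x A `"pi_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics.
#' @method glance pi_fit
#' @export
glance.pi_fit <- function(x, ...) {
  tibble(r.squared = x$r2, sigma = x$s_e, nobs = x$n, level = x$level,
         t_crit = x$t_crit, x_bar = x$x_bar, s_xx = x$s_xx)
}
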