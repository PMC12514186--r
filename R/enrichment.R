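#' Read a GMT gene-set file
#'
#' GMT dialect: one tab-separated line per term -- term id, description, then
#' the member genes. Duplicate members within a term are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A tibble in long form: `term`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("Malformed GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")))
  }
  purrr::map_dfr(parts, function(p) {
    tibble(term = p[1], description = p[2], gene = unique(p[-c(1, 2)]))
  })
}

#' Write a GMT gene-set file
#'
#' @param gene_sets Long tibble (`term`, `description`, `gene`) as returned
#'   by [read_gmt()], or a named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  gs <- normalize_gene_sets(gene_sets)
  lines <- vapply(names(gs$sets), function(tm) {
    paste(c(tm, gs$descriptions[[tm]], gs$sets[[tm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

normalize_gene_sets <- function(gene_sets) {
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("term", "gene") %in% names(gene_sets)))
    sets <- split(gene_sets$gene, gene_sets$term)
    sets <- lapply(sets, unique)
    desc <- if ("description" %in% names(gene_sets)) {
      d <- gene_sets[!duplicated(gene_sets$term), c("term", "description")]
      setNames(as.character(d$description), d$term)
    } else setNames(rep("", length(sets)), names(sets))
    # keep first-appearance order
    ord <- unique(gene_sets$term)
    list(sets = sets[ord], descriptions = desc[ord])
  } else if (is.list(gene_sets)) {
    if (is.null(names(gene_sets))) abort("Gene-set lists must be named.")
    list(sets = lapply(gene_sets, unique),
         descriptions = setNames(rep("", length(gene_sets)),
                                 names(gene_sets)))
  } else {
    abort("`gene_sets` must be a long tibble or a named list.")
  }
}

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation of the query in the term given
#' the universe: with N universe genes, K of them in the term, and a query of
#' n genes of which k hit the term, the upper-tail p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Query and terms are first
#' intersected with the universe; terms smaller than `min_size` or larger
#' than `max_size` (half the universe by default, mirroring common
#' enrichment practice) are skipped. Benjamini-Hochberg adjustment is
#' applied across all tested terms.
#'
#' @param query Character vector of query genes.
#' @param gene_sets Long tibble (`term`, `description`, `gene`) or named
#'   list of character vectors.
#' @param universe Character vector: the background gene universe.
#' @param p_cutoff Significance cutoff applied to the adjusted p-value.
#' @param min_size,max_size Term-size filter after universe intersection;
#'   `max_size = NULL` means half the universe.
#' @return A tibble sorted by p: `term`, `k`, `n`, `K`, `N`, `p`, `padj`,
#'   `fold_enrichment`, `significant`.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe, p_cutoff = 0.05,
                             min_size = 3, max_size = NULL) {
  universe <- unique(universe)
  N <- length(universe)
  if (N < 1) abort("The universe must contain at least one gene.")
  if (is.null(max_size)) max_size <- floor(N / 2)
  q <- intersect(unique(query), universe)
  n <- length(q)
  gs <- normalize_gene_sets(gene_sets)$sets
  rows <- purrr::imap(gs, function(members, tm) {
    term_u <- intersect(members, universe)
    K <- length(term_u)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(q, term_u))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term = tm, k = k, n = n, K = K, N = N, p = p,
           fold_enrichment = if (n > 0 && K > 0) (k / n) / (K / N)
                             else NA_real_)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(
    tibble(term = character(0), k = integer(0), n = integer(0),
           K = integer(0), N = integer(0), p = numeric(0), padj = numeric(0),
           fold_enrichment = numeric(0), significant = logical(0))
  )
  out |>
    mutate(padj = adjust_bh(.data$p),
           significant = .data$padj < p_cutoff) |>
    select("term", "k", "n", "K", "N", "p", "padj", "fold_enrichment",
           "significant") |>
    arrange(.data$p)
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 table `[[o, |a|-o], [|b|-o, N-|a|-|b|+o]]` for sets of
#' sizes |a| and |b| overlapping in o genes within a universe of size N. The
#' one-sided ("greater") p-value is the hypergeometric upper tail, the
#' convention of gene-set overlap testing; `alternative = "two.sided"`
#' doubles-or-sums via the exact distribution. The reported odds ratio is
#' the sample odds ratio with a 0.5 continuity correction when any cell is
#' zero.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe_n Universe size (an integer, at least the size of each
#'   set).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble: `n_a`, `n_b`, `overlap`, `odds_ratio`, `p`.
#' @export
fisher_overlap <- function(set_a, set_b, universe_n,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- unique(set_a)
  b <- unique(set_b)
  o <- length(intersect(a, b))
  na <- length(a)
  nb <- length(b)
  if (na > universe_n || nb > universe_n || universe_n - na - nb + o < 0) {
    abort("Set sizes are inconsistent with `universe_n` (negative cell).")
  }
  cells <- c(o, na - o, nb - o, universe_n - na - nb + o)
  cc <- if (any(cells == 0)) 0.5 else 0
  or <- ((cells[1] + cc) * (cells[4] + cc)) /
    ((cells[2] + cc) * (cells[3] + cc))
  if (alternative == "greater") {
    p <- phyper(o - 1, na, universe_n - na, nb, lower.tail = FALSE)
  } else {
    dens <- stats::dhyper(0:min(na, nb), na, universe_n - na, nb)
    p <- sum(dens[dens <= stats::dhyper(o, na, universe_n - na, nb) *
                    (1 + 1e-7)])
  }
  tibble(n_a = na, n_b = nb, overlap = o, odds_ratio = or,
         p = min(p, 1))
}

#' Overlap of a candidate set with several external datasets
#'
#' Runs [fisher_overlap()] of the candidate set against each external set,
#' with Benjamini-Hochberg adjustment across sets.
#'
#' @param candidates Character vector of candidate genes.
#' @param external_sets Named list of character vectors.
#' @param universe_n Universe size.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param alternative Passed to [fisher_overlap()].
#' @return A tibble with one row per external set: `dataset`, `n_a`, `n_b`,
#'   `overlap`, `odds_ratio`, `p`, `padj`, `significant`.
#' @export
overlap_matrix <- function(candidates, external_sets, universe_n,
                           alpha = tailprop_defaults()$alpha,
                           alternative = "greater") {
  if (length(external_sets) == 0) {
    abort("`external_sets` must contain at least one gene list.")
  }
  rows <- purrr::imap(external_sets, function(s, nm) {
    fisher_overlap(candidates, s, universe_n, alternative) |>
      mutate(dataset = nm, .before = 1)
  })
  bind_rows(rows) |>
    mutate(padj = adjust_bh(.data$p), significant = .data$padj < alpha)
}
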