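# Vectorized NB fitting machinery shared by dispersion estimation and the
# Wald contrast fit. All functions work on G x m matrices per sample group:
# K = counts, Cc = known multiplier s_j * exp(o_gj), so mu = Cc * exp(eta_g).

nb_fit_group_eta <- function(K, Cc, alpha, eta0 = NULL, iters = 12L) {
  rs <- rowSums(K)
  cs <- rowSums(Cc)
  eta <- if (is.null(eta0)) log(pmax(rs, 0.5) / cs) else eta0
  for (i in seq_len(iters)) {
    mu <- Cc * exp(eta)
    denom <- 1 + alpha * mu
    g <- rowSums((K - mu) / denom)
    gp <- -rowSums(mu * (1 + alpha * K) / denom^2)
    step <- g / gp
    step[!is.finite(step)] <- 0
    eta <- eta - pmax(pmin(step, 2), -2)
  }
  eta
}

nb_loglik_rows <- function(K, mu, alpha) {
  a <- alpha
  rowSums(lgamma(K + 1 / a) - lgamma(1 / a) - lgamma(K + 1) +
            K * log(a * mu / (1 + a * mu)) - (1 / a) * log(1 + a * mu))
}

# Cox-Reid adjusted profile log-likelihood of alpha, profiling out the group
# means; group_list is a list of (K, Cc) pairs.
nb_profile_ll <- function(group_list, alpha, cox_reid = TRUE) {
  ll <- 0
  for (g in group_list) {
    eta <- nb_fit_group_eta(g$K, g$Cc, alpha)
    mu <- g$Cc * exp(eta)
    ll <- ll + nb_loglik_rows(g$K, mu, alpha)
    if (cox_reid) {
      info <- rowSums(mu / (1 + alpha * mu))
      ll <- ll - 0.5 * log(pmax(info, 1e-300))
    }
  }
  ll
}

grid_argmax_refine <- function(LL, la) {
  idx <- max.col(LL, ties.method = "first")
  out <- la[idx]
  n_grid <- length(la)
  ok <- idx > 1 & idx < n_grid
  if (any(ok)) {
    wk <- which(ok)
    i0 <- idx[ok]
    y1 <- LL[cbind(wk, i0 - 1L)]
    y2 <- LL[cbind(wk, i0)]
    y3 <- LL[cbind(wk, i0 + 1L)]
    h <- la[2] - la[1]
    d <- 0.5 * h * (y1 - y3) / (y1 - 2 * y2 + y3)
    d[!is.finite(d)] <- 0
    out[ok] <- la[i0] + pmax(pmin(d, h), -h)
  }
  out
}

disp_grid <- function(n_grid = 60L, lo = 1e-8, hi = 30) {
  seq(log(lo), log(hi), length.out = n_grid)
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Gene-wise dispersions are estimated by maximizing the Cox-Reid adjusted
#' profile likelihood (group means profiled out) over a log-spaced grid with
#' parabolic refinement, floored at 1e-8. With `shrink = TRUE` a parametric
#' mean-dispersion trend `a1 + a0 / mean` is fitted across genes by a
#' gamma-family regression and each gene's dispersion is re-estimated as the
#' maximum a-posteriori value under a log-normal prior centered on the trend;
#' genes far above the trend keep their gene-wise estimate. Shrinkage is what
#' makes the downstream normal-reference Wald test calibrated at small
#' replicate numbers; the bare gene-wise estimate is returned by default.
#'
#' @param counts Data frame: `gene_id` plus one column per sample.
#' @param size_factors Tibble from [compute_size_factors()] (or any table
#'   with `sample_id`, `size_factor`).
#' @param design Sample metadata with `sample_id` and the grouping columns
#'   named in `groups`; every group needs at least 2 replicates.
#' @param groups Character vector of metadata columns whose interaction
#'   defines the fitted group means.
#' @param offsets Optional long offset table from [length_offsets()].
#' @param shrink Apply trend shrinkage (see Details).
#' @param prior_floor Lower bound on the log-scale prior variance used by the
#'   shrinkage step.
#' @return A tibble with `gene_id`, `base_mean`, `dispersion`,
#'   `dispersion_genewise`, `dispersion_trend`.
#' @export
estimate_dispersions <- function(counts, size_factors, design,
                                 groups = intersect(c("species", "vertebra"),
                                                    names(design)),
                                 offsets = NULL, shrink = FALSE,
                                 prior_floor = 0.05) {
  K <- counts_to_matrix(counts)
  if (length(groups) == 0) abort("`groups` must name at least one column.")
  design <- as_tibble(design)
  sf <- size_factors$size_factor[match(colnames(K), size_factors$sample_id)]
  if (anyNA(sf)) abort("`size_factors` must cover every sample.")
  grp <- interaction(design[match(colnames(K), design$sample_id), groups,
                            drop = FALSE], drop = TRUE)
  if (anyNA(grp)) abort("`design` must cover every sample.")
  if (any(table(grp) < 2)) {
    abort("Every group needs at least 2 replicates to estimate dispersion.")
  }
  O <- offsets_to_matrix(offsets, rownames(K), colnames(K))
  Cc_full <- sweep(exp(O), 2, sf, "*")
  group_list <- lapply(levels(grp), function(lv) {
    j <- which(grp == lv)
    list(K = K[, j, drop = FALSE], Cc = Cc_full[, j, drop = FALSE])
  })
  base_mean <- rowMeans(K / Cc_full)

  la <- disp_grid()
  G <- nrow(K)
  LL <- matrix(NA_real_, G, length(la))
  for (i in seq_along(la)) {
    LL[, i] <- nb_profile_ll(group_list, rep(exp(la[i]), G))
  }
  la_hat <- grid_argmax_refine(LL, la)
  disp_gene <- pmax(exp(la_hat), 1e-8)

  disp_trend <- rep(NA_real_, G)
  disp_final <- disp_gene
  if (shrink) {
    m <- ncol(K)
    p <- length(group_list)
    trend <- fit_dispersion_trend(disp_gene, base_mean)
    lr <- log(pmax(disp_gene, 1e-8)) - log(trend)
    samp_var <- trigamma(pmax(m - p, 1) / 2)
    prior_var <- max(mad(lr)^2 - samp_var, prior_floor)
    pen <- -(matrix(la, G, length(la), byrow = TRUE) - log(trend))^2 /
      (2 * prior_var)
    la_map <- grid_argmax_refine(LL + pen, la)
    disp_final <- pmax(exp(la_map), 1e-8)
    keep <- lr > 2 * sqrt(samp_var + prior_var)
    disp_final[keep] <- disp_gene[keep]
    disp_trend <- trend
  }
  tibble(
    gene_id = rownames(K), base_mean = base_mean,
    dispersion = disp_final, dispersion_genewise = disp_gene,
    dispersion_trend = disp_trend
  )
}

fit_dispersion_trend <- function(disp_gene, base_mean) {
  use <- disp_gene > 1e-7 & base_mean > 0
  if (sum(use) < 10) {
    return(rep(exp(mean(log(pmax(disp_gene, 1e-8)))), length(disp_gene)))
  }
  tryCatch({
    fit <- suppressWarnings(glm(
      disp_gene[use] ~ I(1 / base_mean[use]),
      family = Gamma(link = "identity"),
      start = c(median(disp_gene[use]), 1)
    ))
    co <- coef(fit)
    pmax(co[1] + co[2] / base_mean, 1e-8)
  }, error = function(e) {
    rep(exp(mean(log(pmax(disp_gene, 1e-8)))), length(disp_gene))
  })
}
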