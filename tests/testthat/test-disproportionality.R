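pairs_from_lfc <- function(lfc, padj_intra = 0.01, lfc_intra = NULL) {
  tibble::tibble(
    gene_id = lfc$gene_id, lfc_x = lfc$lfc_tv1, padj_x = 0.01,
    lfc_y = lfc$lfc_tv6, padj_y = 0.01,
    lfc_intra = lfc_intra %||% lfc$lfc_tv6, padj_intra = padj_intra
  )
}

test_that("the TV6-only rule handles significance and missingness", {
  tbl <- tibble::tibble(
    gene_id = c("in_a", "both", "na_y", "na_x"),
    lfc_x = c(0.1, 1, 0.2, 0.5), padj_x = c(0.2, 0.01, 0.3, NA),
    lfc_y = c(1, 1, 1, 1), padj_y = c(0.01, 0.01, NA, 0.01),
    lfc_intra = 1, padj_intra = 0.01
  )
  a <- classify_tv6_only(tbl)
  expect_setequal(a$gene_id, c("in_a", "na_x"))
})

test_that("the OLS fit matches the closed-form normal equations", {
  x <- c(-1.2, 0.3, 0.8, 1.9, -0.5)
  y <- c(-0.9, 0.4, 0.6, 1.8, -0.2)
  tbl <- tibble::tibble(gene_id = paste0("g", 1:5), lfc_x = x, padj_x = 0.01,
                        lfc_y = y, padj_y = 0.01, lfc_intra = y,
                        padj_intra = 0.01)
  fit <- fit_lfc_regression(tbl)
  expect_equal(fit$intercept, 0.122663387210119, tolerance = 1e-12)
  expect_equal(fit$slope, 0.835910049191848, tolerance = 1e-12)
  expect_equal(fit$n, 5)
  expect_equal(fit$x_bar, mean(x))
  expect_equal(fit$s_xx, sum((x - mean(x))^2))

  # collinear points: slope exact, residual zero
  tblc <- tbl |> dplyr::mutate(lfc_y = 0.9 * lfc_x)
  fitc <- fit_lfc_regression(tblc)
  expect_equal(fitc$slope, 0.9, tolerance = 1e-12)
  expect_equal(fitc$r2, 1, tolerance = 1e-12)
  expect_equal(fitc$s_e, 0, tolerance = 1e-12)

  # default fixture: slope near the calibrated value
  big <- pairs_from_lfc(simulate_lfc_pairs(6786, seed = 1))
  expect_lt(abs(fit_lfc_regression(big)$slope - 0.883), 0.02)

  expect_error(fit_lfc_regression(tbl[1:2, ]), "At least 3")
  expect_error(
    fit_lfc_regression(tbl |> dplyr::mutate(lfc_x = 1)), "Degenerate"
  )
})

test_that("the prediction interval matches the textbook computation exactly", {
  set.seed(8)
  x <- c(-2.1, -0.7, 0.2, 0.9, 1.7, 2.4)
  y <- 0.3 + 0.85 * x + rnorm(6, 0, 0.2)
  tbl <- tibble::tibble(gene_id = paste0("g", 1:6), lfc_x = x, padj_x = 0.01,
                        lfc_y = y, padj_y = 0.01, lfc_intra = y,
                        padj_intra = 0.01)
  fit <- fit_lfc_regression(tbl, level = 0.95)
  x0 <- seq(-3, 3, length.out = 11)
  ours <- prediction_interval(fit, x0)
  ref <- predict(lm(y ~ x), newdata = data.frame(x = x0),
                 interval = "prediction", level = 0.95)
  expect_equal(ours$fit, unname(ref[, "fit"]), tolerance = 1e-10)
  expect_equal(ours$lo, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(ours$hi, unname(ref[, "upr"]), tolerance = 1e-10)

  # width is minimized at the mean of x and grows with |x0 - xbar|
  w <- ours$hi - ours$lo
  d <- abs(x0 - fit$x_bar)
  expect_true(all(diff(w[order(d)]) >= -1e-12))

  # zero residual: the interval collapses onto the line
  tbl0 <- tbl |> dplyr::mutate(lfc_y = 0.3 + 0.85 * lfc_x)
  fit0 <- fit_lfc_regression(tbl0)
  pi0 <- prediction_interval(fit0, c(-1, 0, 2))
  expect_equal(pi0$lo, pi0$fit, tolerance = 1e-12)
  expect_equal(pi0$hi, pi0$fit, tolerance = 1e-12)
})

test_that("interval coverage is nominal at every level", {
  lfc <- simulate_lfc_pairs(4000, frac_outlier = 0, seed = 17)
  tbl <- pairs_from_lfc(lfc)
  train <- tbl[1:2000, ]
  test <- tbl[2001:4000, ]
  for (lv in c(0.8, 0.9, 0.95, 0.99)) {
    fit <- fit_lfc_regression(train, level = lv)
    pi <- prediction_interval(fit, test$lfc_x)
    cover <- mean(test$lfc_y >= pi$lo & test$lfc_y <= pi$hi)
    mc <- 3 * sqrt(lv * (1 - lv) / nrow(test))
    expect_lt(abs(cover - lv), mc + 0.005)
  }
})

test_that("outlier classification recovers planted disproportionate pairs", {
  lfc <- simulate_lfc_pairs(6786, seed = 5)
  tbl <- pairs_from_lfc(lfc)
  fit <- fit_lfc_regression(tbl)
  b <- classify_outside_pi(tbl, fit)
  planted <- lfc$gene_id[lfc$is_outlier]
  recall <- length(intersect(b$gene_id, planted)) / length(planted)
  false_incl <- length(setdiff(b$gene_id, planted)) /
    (nrow(lfc) - length(planted))
  expect_gte(recall, 0.9)
  expect_lte(false_incl, 0.07)

  # a point exactly on the line stays inside when residual spread exists
  on_line <- tbl[1, ] |>
    dplyr::mutate(gene_id = "online",
                  lfc_y = fit$intercept + fit$slope * lfc_x)
  expect_equal(nrow(classify_outside_pi(on_line, fit)), 0)

  # no planted outliers: about the nominal 5% of pairs fall outside
  lfc0 <- simulate_lfc_pairs(6000, frac_outlier = 0, seed = 6)
  tbl0 <- pairs_from_lfc(lfc0)
  fit0 <- fit_lfc_regression(tbl0)
  frac_out <- nrow(classify_outside_pi(tbl0, fit0)) / nrow(tbl0)
  expect_lt(abs(frac_out - 0.05), 0.015)
})

test_that("sign consistency gates the candidate set", {
  tbl <- tibble::tibble(
    gene_id = c("up_up", "up_down", "not_sig", "zero"),
    lfc_x = 0.5, padj_x = 0.01,
    lfc_y = c(1.2, 1.2, 1.2, 1.2), padj_y = 0.01,
    lfc_intra = c(0.8, -0.8, 0.8, 0), padj_intra = c(0.01, 0.01, 0.2, 0.01)
  )
  cand <- suppressWarnings(
    sign_consistent_intersection(tbl, tbl$gene_id)
  )
  expect_equal(cand$gene_id, "up_up")
  expect_equal(cand$direction, "up_in_jerboa_TV6")
  expect_warning(sign_consistent_intersection(tbl, "zero"), "zero")

  down <- tbl[1, ] |>
    dplyr::mutate(lfc_y = -1.2, lfc_intra = -0.4)
  expect_equal(sign_consistent_intersection(down, down$gene_id)$direction,
               "down_in_jerboa_TV6")
})

test_that("the classification partitions the significant genes", {
  lfc <- simulate_lfc_pairs(3000, seed = 23)
  # make a mix: some rows TV6-only, some both-significant
  tbl <- pairs_from_lfc(lfc)
  tbl$padj_x[1:500] <- 0.5
  res <- disproportionality(tbl)
  expect_equal(length(intersect(res$sets$A, res$sets$pairs)), 0)
  expect_true(all(res$sets$B %in% res$sets$pairs))
  expect_setequal(res$sets$D, union(res$sets$A, res$sets$B))
  expect_equal(res$counts[["D"]], res$counts[["A"]] + res$counts[["B"]])
  expect_true(all(res$sets$candidates %in% res$sets$D))

  # monotonicity: a larger alpha never shrinks the both-significant set;
  # a higher level never grows B on the same fit population
  res_loose <- disproportionality(tbl, alpha = 0.2)
  expect_gte(res_loose$counts[["pairs"]], res$counts[["pairs"]])
  res_hi <- disproportionality(tbl, level = 0.99)
  expect_lte(res_hi$counts[["B"]], res$counts[["B"]])

  # broom-style accessors
  td <- tidy(res$fit)
  expect_equal(td$estimate[2], res$fit$slope)
  gl <- glance(res$fit)
  expect_equal(gl$nobs, res$fit$n)
})

test_that("candidate collation flags datasets, phenotypes and Npr3", {
  t1 <- table1_candidates()
  sets <- list(
    SHR = t1$gene[t1$shr], JH = t1$gene[t1$jh],
    MY = t1$gene[t1$my], TP = t1$gene[t1$tp]
  )
  coll <- collate_candidates(t1$gene, sets,
                             phenotype_genes = t1$gene[t1$tail_phenotype])
  all_four <- coll$gene[coll$n_datasets == 4]
  expect_equal(all_four, "Npr3")
  expect_equal(attr(coll, "common_to_all"), "Npr3")
  expect_true(all(coll$highlight))

  # two datasets and no phenotype: not highlighted
  c2 <- collate_candidates("geneA",
                           list(d1 = "geneA", d2 = "geneA", d3 = "other"))
  expect_false(c2$highlight)
  # phenotype alone highlights
  c3 <- collate_candidates("geneB", list(d1 = "other"),
                           phenotype_genes = "GENEB")
  expect_true(c3$highlight)
  expect_true(c3$phenotype) # case-insensitive match
  expect_error(collate_candidates("g", list()), "at least one")
})
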