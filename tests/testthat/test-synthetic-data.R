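test_that("ortholog tables are deterministic and follow the length law", {
  t1 <- simulate_ortholog_table(500, seed = 11)
  t2 <- simulate_ortholog_table(500, seed = 11)
  expect_identical(t1, t2)
  expect_false(identical(t1, simulate_ortholog_table(500, seed = 12)))

  # zero-variance ratio law: jerboa length equals mouse length
  t0 <- simulate_ortholog_table(300, length_log_sd = 0, seed = 3)
  one2one <- t0$orthology_class == "one_to_one"
  expect_equal(t0$length_jerboa[one2one], t0$length_mouse[one2one])
  expect_true(all(is.na(t0$length_jerboa[!one2one])))

  # moment check: sd of the log length ratio matches the generative law
  tb <- simulate_ortholog_table(10000, length_log_sd = 0.3, seed = 5)
  lr <- log(tb$length_jerboa / tb$length_mouse)
  expect_lt(abs(sd(lr, na.rm = TRUE) - 0.3) / 0.3, 0.05)

  # ~2% one-to-zero
  expect_equal(sum(tb$orthology_class == "one_to_zero"), 0.02 * 10000)
  expect_error(simulate_ortholog_table(0), "positive")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(frac_equivalent = 0.6, frac_A = 0.3, frac_B = 0.2),
               "at most 1")
  expect_error(sim_config(n_reps = 1), "at least 2")
  expect_error(sim_config(resid_sd = -1), "non-negative")
})

test_that("ground-truth classes have exact counts and consistent effects", {
  sim <- simulate_counts(sim_config(n_genes = 2000, frac_A = 0.1,
                                    frac_equivalent = 0.2, frac_B = 0.05,
                                    seed = 4))
  counts_by_class <- table(sim$truth$class)
  expect_equal(unname(counts_by_class[["A_type"]]), 200)
  expect_equal(unname(counts_by_class[["equivalent"]]), 400)
  expect_equal(unname(counts_by_class[["B_type"]]), 100)

  # invariants of the class definitions
  null_genes <- sim$truth[sim$truth$class == "null", ]
  expect_true(all(null_genes$lfc_TV1 == 0 & null_genes$lfc_TV6 == 0))
  a_genes <- sim$truth[sim$truth$class == "A_type", ]
  expect_true(all(a_genes$lfc_TV1 == 0 & a_genes$lfc_TV6 != 0))
  expect_equal(sim$truth$lfc_intra,
               sim$truth$delta_vert + sim$truth$lfc_TV6 - sim$truth$lfc_TV1)

  # all fractions zero: every gene null
  sim0 <- simulate_counts(sim_config(n_genes = 100, frac_equivalent = 0,
                                     frac_A = 0, frac_B = 0, seed = 1))
  expect_true(all(sim0$truth$class == "null"))

  # determinism of the full bundle
  cfg <- sim_config(n_genes = 150, seed = 99)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
})

test_that("simulated counts match the negative-binomial moments", {
  # one shared mean: flat baselines, equal lengths, all-null truth; then a
  # single sample column is an iid NB draw across genes
  cfg <- sim_config(n_genes = 20000, baseline_log_sd = 0, length_log_sd = 0,
                    frac_equivalent = 0, frac_A = 0, frac_B = 0,
                    delta_vert_sd = 0, dispersion = 0.1, seed = 8)
  sim <- simulate_counts(cfg)
  K <- as.matrix(sim$counts[, -1])
  # recover the per-sample mean from the data; check var = mu + alpha mu^2
  for (j in c(1, 9)) {
    x <- K[, j]
    mu_hat <- mean(x)
    v_expect <- mu_hat + 0.1 * mu_hat^2
    se_var <- sd((x - mu_hat)^2) / sqrt(length(x))
    expect_lt(abs(var(x) - v_expect), 3 * se_var)
  }

  # Poisson limit: dispersion ~ 0 gives variance ~ mean
  cfgp <- sim_config(n_genes = 20000, baseline_log_sd = 0, length_log_sd = 0,
                     frac_equivalent = 0, frac_A = 0, frac_B = 0,
                     delta_vert_sd = 0, dispersion = 1e-10, seed = 9)
  Kp <- as.matrix(simulate_counts(cfgp)$counts[, -1])
  x <- Kp[, 3]
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("lfc pair simulation plants the linear relation and outliers", {
  exact <- simulate_lfc_pairs(100, a = 0.2, b = 0.9, resid_sd = 0,
                              frac_outlier = 0, seed = 2)
  expect_equal(exact$lfc_tv6, 0.2 + 0.9 * exact$lfc_tv1)
  expect_false(any(exact$is_outlier))

  p1 <- simulate_lfc_pairs(500, seed = 6)
  expect_identical(p1, simulate_lfc_pairs(500, seed = 6))
  expect_equal(sum(p1$is_outlier), round(0.062 * 500))

  # default calibration: OLS slope near the planted 0.883
  big <- simulate_lfc_pairs(6786, seed = 1)
  b_hat <- coef(lm(lfc_tv6 ~ lfc_tv1, data = big))[["lfc_tv1"]]
  expect_lt(abs(b_hat - 0.883), 0.02)

  expect_error(simulate_lfc_pairs(5), "at least 10")
})

test_that("tail phantoms render elements with exact half-height geometry", {
  # one element of 2700 um at 27 um/px: a 100-pixel plateau
  cfg <- phantom_config("mouse", n_vertebrae = 1, true_lengths = 2700,
                        gap = 270, intensity_noise_sd = 0)
  ph <- simulate_tail_phantom(cfg)
  v <- ph$profile$intensity
  thr <- (min(v) + max(v)) / 2
  run <- rle(v > thr)
  expect_equal(sum(run$values), 1)
  expect_equal(run$lengths[run$values], 100)

  # masking k elements removes k supra-threshold runs
  mask <- rep(TRUE, 10); mask[c(3, 7)] <- FALSE
  phm <- simulate_tail_phantom(
    phantom_config("mouse", n_vertebrae = 10,
                   true_lengths = rep(1000, 10), ossified_mask = mask)
  )
  runs <- rle(phm$profile$intensity >
                (min(phm$profile$intensity) + max(phm$profile$intensity)) / 2)
  expect_equal(sum(runs$values), 8)

  expect_error(
    simulate_tail_phantom(phantom_config("mouse", n_vertebrae = 1,
                                         true_lengths = 30)),
    "2 effective pixels"
  )
})

test_that("growth series hit the planted proportions and grow monotonically", {
  for (sp in c("mouse", "jerboa")) {
    gs <- simulate_growth_series(sp, noise_sd = 0)
    tb <- tail_body_ratio(gs)
    expect_equal(mean(tb$ratio[tb$timepoint_days == 0]), 0.5,
                 tolerance = 0.01)
    adult <- tailprop_defaults()$adult_ratio[[sp]]
    expect_equal(mean(tb$ratio[tb$timepoint_days == 42]), adult,
                 tolerance = 0.01)
    expect_true(all(gs$length_um >= 0))
    mono <- gs |>
      dplyr::summarise(l = mean(length_um),
                       .by = c("vertebra", "timepoint_days")) |>
      dplyr::arrange(timepoint_days) |>
      dplyr::summarise(ok = all(diff(l) >= -1e-9), .by = "vertebra")
    expect_true(all(mono$ok))
  }
  gs1 <- simulate_growth_series("mouse", seed = 7)
  expect_identical(gs1, simulate_growth_series("mouse", seed = 7))
})

test_that("growth-plate tables honour their planted parameters", {
  gp <- simulate_growth_plate(growth_plate_config(
    n_specimens = 10, cells_per_section = 1000, edu_p = 0.3,
    daily_rate_um = 42, rate_noise_sd = 0, seed = 13
  ))
  frac <- sum(gp$sections$edu_pos) / sum(gp$sections$edu_total)
  n_cells <- sum(gp$sections$edu_total)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n_cells))
  expect_true(all(gp$sections$calcein_distance_um == 2 * 42))
  cfg <- growth_plate_config(seed = 21)
  expect_identical(simulate_growth_plate(cfg), simulate_growth_plate(cfg))
  expect_error(growth_plate_config(zone_means = c(total = -5, resting = 1,
                                                  proliferative = 1,
                                                  hypertrophic = 1)),
               "non-negative")
})
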