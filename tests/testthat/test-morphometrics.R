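test_that("phantom profiles segment into the planted element counts", {
  jer <- simulate_tail_phantom(phantom_config("jerboa"))
  expect_equal(nrow(segment_elements(jer$profile)), 28)
  mou <- simulate_tail_phantom(phantom_config("mouse"))
  expect_equal(nrow(segment_elements(mou$profile)), 31)
  expect_error(segment_elements(rep(5, 100)), "supra-threshold")
})

test_that("half-height measurement recovers exact and analytic lengths", {
  # noiseless rectangular plateau of 100 px at 27 um/px
  cfg <- phantom_config("mouse", n_vertebrae = 1, true_lengths = 2700,
                        gap = 270)
  ph <- simulate_tail_phantom(cfg)
  m <- measure_profile(ph$profile)
  expect_equal(m$length_um, 2700, tolerance = 1e-9)

  # symmetric trapezoid with 4-px ramps: length = plateau + one ramp width
  v <- c(rep(0, 10), 20, 40, 60, 80, rep(100, 10), 80, 60, 40, 20,
         rep(0, 12))
  segs <- segment_elements(v)
  len_px <- measure_diaphysis_length(v, segs$start_px[1], segs$end_px[1],
                                     voxel = 1, resize = 1, window_px = 8)
  expect_equal(len_px, 14, tolerance = 1e-12) # 10 px plateau + 4 px ramp

  # unit coherence: microns scale with voxel and resize
  l1 <- measure_diaphysis_length(v, segs$start_px[1], segs$end_px[1],
                                 voxel = 9, resize = 3, window_px = 8)
  l2 <- measure_diaphysis_length(v, segs$start_px[1], segs$end_px[1],
                                 voxel = 9, resize = 6, window_px = 8)
  expect_equal(l1, 14 * 27)
  expect_equal(l2 / l1, 2)

  expect_error(measure_diaphysis_length(rep(1, 30), 5, 10), "contrast")
})

test_that("all planted lengths are recovered within one effective pixel", {
  for (sp in c("mouse", "jerboa")) {
    ph <- simulate_tail_phantom(phantom_config(sp))
    m <- measure_profile(ph$profile)
    expect_equal(nrow(m), nrow(ph$truth))
    err <- abs(m$length_um - ph$truth$true_length_um)
    expect_true(all(err <= 27))
  }
  # noise at 5% of the dynamic range, with smoothing
  phn <- simulate_tail_phantom(phantom_config("mouse",
                                              intensity_noise_sd = 4.5,
                                              seed = 3))
  mn <- measure_profile(phn$profile, smooth = TRUE)
  err <- abs(mn$length_um - phn$truth$true_length_um[seq_len(nrow(mn))])
  expect_lte(median(err), 27)
})

test_that("normalization and weekly change follow the hand-computed fixture", {
  expect_error(
    normalize_to_body(tibble::tibble(length_um = 1, naso_anal_um = 0)),
    "positive"
  )
  one <- normalize_to_body(tibble::tibble(length_um = 50,
                                          naso_anal_um = 50))
  expect_equal(one$rel_length, 1)

  # 2 vertebrae x 3 timepoints, one animal, naso-anal 100 everywhere:
  # rel lengths v1: 0.10, 0.20, 0.25 / v2: 0.30, 0.30, 0.60
  toy <- tibble::tibble(
    animal_id = "a1",
    timepoint_days = rep(c(0, 7, 14), each = 2),
    vertebra = rep(1:2, 3),
    length_um = c(10, 30, 20, 30, 25, 60),
    naso_anal_um = 100
  )
  ch <- weekly_relative_change(toy)
  expect_equal(ch$delta[ch$vertebra == 1], c(0.10, 0.05))
  expect_equal(ch$delta[ch$vertebra == 2], c(0.00, 0.30))

  # static series: all zero; linear growth: constant delta
  static <- toy |> dplyr::mutate(length_um = rep(c(10, 30), 3))
  expect_true(all(weekly_relative_change(static)$delta == 0))

  expect_error(weekly_relative_change(toy[toy$timepoint_days == 0, ]),
               "2 timepoints")

  pk <- peak_vertebra(ch)
  expect_equal(pk$peak_vertebra, 2)
  expect_false(pk$tie)

  # single vertebra: that vertebra; exact tie: smaller index with flag
  pk1 <- peak_vertebra(ch[ch$vertebra == 1, ])
  expect_equal(pk1$peak_vertebra, 1)
  tie_tbl <- tibble::tibble(vertebra = c(5, 5, 6, 6),
                            from_day = c(0, 7, 0, 7), to_day = c(7, 14, 7, 14),
                            delta = c(0.1, 0.2, 0.2, 0.1))
  pk_tie <- peak_vertebra(tie_tbl)
  expect_equal(pk_tie$peak_vertebra, 5)
  expect_true(pk_tie$tie)
})

test_that("the default growth series peaks at TV6 with the planted ratios", {
  gs <- simulate_growth_series("mouse", noise_sd = 0)
  pk <- peak_vertebra(weekly_relative_change(gs))
  expect_equal(pk$peak_vertebra, 6)
  gsj <- simulate_growth_series("jerboa", noise_sd = 0)
  tb <- tail_body_ratio(gsj)
  expect_equal(mean(tb$ratio[tb$timepoint_days == 42]), 1.5,
               tolerance = 0.01)
})

test_that("growth-plate summaries use the fixed averaging order", {
  expect_equal(calcein_growth_rate(100), 50)
  expect_equal(calcein_growth_rate(0), 0)
  expect_equal(calcein_growth_rate(90, elapsed_hours = 24), 90)
  expect_error(calcein_growth_rate(-1), "non-negative")
  gp <- simulate_growth_plate(growth_plate_config(daily_rate_um = 33,
                                                  rate_noise_sd = 0))
  expect_true(all(calcein_growth_rate(gp$sections$calcein_distance_um) == 33))

  pi_tbl <- tibble::tibble(specimen = "a", edu_pos = c(10, 20, 30),
                           edu_total = 100)
  expect_equal(proliferative_index(pi_tbl)$proliferative_index, 0.2)
  all_pos <- tibble::tibble(specimen = "b", edu_pos = 50, edu_total = 50)
  expect_equal(proliferative_index(all_pos)$proliferative_index, 1)
  expect_error(proliferative_index(tibble::tibble(specimen = "c",
                                                  edu_pos = 0,
                                                  edu_total = 0)),
               "at least one")

  # binomial recovery
  gp2 <- simulate_growth_plate(growth_plate_config(
    n_specimens = 20, cells_per_section = 500, edu_p = 0.3, seed = 4
  ))
  est <- mean(proliferative_index(gp2$sections)$proliferative_index)
  expect_lt(abs(est - 0.3), 3 * sqrt(0.3 * 0.7 / (20 * 3 * 500)))

  # top-3 rule, then sections -> specimen
  sec <- tibble::tibble(specimen = "a", section = 1,
                        height_um = c(5, 7, 9, 30, 31, 32))
  expect_equal(max_hypertrophic_height(sec)$max_height_um, 31)
  eqh <- tibble::tibble(specimen = "a", section = rep(1:2, each = 4),
                        height_um = 12)
  expect_equal(max_hypertrophic_height(eqh)$max_height_um, 12)
  # hand-computed 3-section fixture: (mean top3) 20, 26, 35 -> 27
  three <- tibble::tibble(
    specimen = "a", section = rep(1:3, each = 4),
    height_um = c(10, 18, 20, 22, 20, 24, 26, 28, 30, 33, 35, 37)
  )
  expect_equal(max_hypertrophic_height(three)$max_height_um, 27)
  expect_error(
    max_hypertrophic_height(tibble::tibble(specimen = "a", section = 1,
                                           height_um = c(1, 2))),
    "at least 3"
  )
})

test_that("Welch's test matches the frozen oracle and its limits", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1)
  r <- welch_t(a, b)
  expect_equal(r$t, -2.0895801943520889, tolerance = 1e-12)
  expect_equal(r$df, 18.9378426026050697, tolerance = 1e-10)
  expect_equal(r$p, 0.0503877165661317, tolerance = 1e-12)

  # identical groups with spread: t = 0, p = 1
  g <- c(1, 2, 3, 4)
  r0 <- welch_t(g, g)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # equal sample variances and sizes: df collapses to n1 + n2 - 2
  r2 <- welch_t(g, g + 5)
  expect_equal(r2$df, length(g) * 2 - 2)

  # degenerate: both variances zero
  expect_warning(rz <- welch_t(c(2, 2), c(2, 2)), "undefined")
  expect_true(rz$undefined)

  # null calibration of the p-value
  set.seed(31)
  ps <- replicate(500, welch_t(rnorm(8), rnorm(8))$p)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
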