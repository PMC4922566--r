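series_of <- function(pixel_series, times = NULL) {
  # single-pixel CBF series
  g <- image_grid(c(1, 1, 1), c(1, 1, 1))
  times <- times %||% seq(10, by = 10, length.out = length(pixel_series))
  lapply(seq_along(pixel_series), function(i) {
    scalar_map(pixel_series[i], g, "CBF", time_min = times[i])
  })
}

test_that("the per-pixel median uses standard odd/even conventions", {
  expect_equal(median_cbf_map(series_of(c(30, 10, 20)))$map$values[1, 1, 1], 20)
  expect_equal(median_cbf_map(series_of(c(10, 20, 30, 40)))$map$values[1, 1, 1], 25)
  # order invariance
  s <- c(17, 3, 42, 8, 25)
  perm <- c(4, 1, 5, 3, 2)
  expect_equal(median_cbf_map(series_of(s))$map$values,
               median_cbf_map(series_of(s[perm]))$map$values)
  expect_error(median_cbf_map(list()), "at least one")
})

test_that("non-finite values are dropped per pixel with a reported count", {
  g <- flat_grid(2)
  m1 <- scalar_map(c(10, 10, 10, 10), g, "CBF", time_min = 10)
  v2 <- c(20, NaN, 20, 20)
  m2 <- scalar_map(v2, g, "CBF", time_min = 20)
  m3 <- scalar_map(c(30, 30, 30, 30), g, "CBF", time_min = 30)
  expect_message(med <- median_cbf_map(list(m1, m2, m3)), "1 non-finite")
  expect_equal(med$n_dropped, 1L)
  expect_equal(med$map$values[2, 1, 1], 20)   # median of {10, 30}
  expect_equal(med$map$values[1, 1, 1], 20)
})

test_that("the median map is bounded by the series and robust to upward spikes", {
  ph <- generate_study(small_phantom_config(seed = 29))
  med <- median_cbf_map(ph$study)
  arr <- vapply(ph$study$cbf_series[study_times(ph$study) > 0],
                function(m) as.numeric(m$values),
                numeric(prod(ph$study$grid$shape)))
  expect_true(all(med$map$values >= apply(arr, 1, min) - 1e-12))
  expect_true(all(med$map$values <= apply(arr, 1, max) + 1e-12))

  # reperfusion robustness: perturbing the floor((n-1)/2) largest values of a
  # pixel's series upward leaves its median unchanged
  set.seed(1)
  n <- 7
  for (i in 1:20) {
    s <- rnorm(n, 30, 10)
    k <- (n - 1) %/% 2
    spiked <- s
    top <- order(s, decreasing = TRUE)[seq_len(k)]
    spiked[top] <- spiked[top] + runif(k, 0, 100)
    expect_equal(median_cbf_map(series_of(spiked))$map$values,
                 median_cbf_map(series_of(s))$map$values)
  }
})

test_that("the baseline scan is excluded from the median unless requested", {
  # baseline at time 0 carries normal flow; including it biases the median up
  s <- series_of(c(50, 20, 30), times = c(0, 10, 30))
  med_excl <- median_cbf_map(s)
  med_incl <- median_cbf_map(s, include_baseline = TRUE)
  expect_equal(med_excl$n_timepoints, 2L)
  expect_equal(med_incl$n_timepoints, 3L)
  expect_equal(med_excl$map$values[1, 1, 1], 25)
  expect_gt(med_incl$map$values[1, 1, 1], med_excl$map$values[1, 1, 1])
})

test_that("relative CBF normalizes to contralateral grey matter", {
  g <- flat_grid(2)
  cbf <- scalar_map(c(20, 50, 50, 50), g, "CBF")
  contra <- roi_mask(c(FALSE, TRUE, TRUE, TRUE), g)
  r <- relative_cbf(cbf, contra)
  expect_equal(r$values[1, 1, 1], 40)    # 20 / 50 -> 40%
  expect_equal(r$values[2, 1, 1], 100)   # pixel equal to the mean
  # global scale invariance
  r2 <- relative_cbf(scalar_map(c(40, 100, 100, 100), g, "CBF"), contra)
  expect_equal(r2$values, r$values)
  expect_error(relative_cbf(scalar_map(rep(0, 4), g, "CBF"), contra), "positive")
})

test_that("the infarct rCBF time course reproduces the phantom trajectory", {
  ph <- generate_study(small_phantom_config(seed = 37))
  med <- median_cbf_map(ph$study)
  seg <- final_analysis_masks(ph$study, med)
  contra_gm <- mask_diff(ph$study$roi_contra, seg$wm)
  tc <- infarct_rcbf_timecourse(ph$study, ph$truth$infarct_mask, contra_gm)
  expect_equal(nrow(tc$timecourse), 7L)
  # early time points near 56%, plateau near 40%
  expect_lt(abs(tc$timecourse$mean_rcbf_pct[1] - 56), 5)
  expect_lt(abs(tc$timecourse$mean_rcbf_pct[5] - 40), 5)
  # pooled grand mean tracks the mixture (2 x 0.56 + 5 x 0.40) / 7 = 44.6%
  expect_lt(abs(tc$grand_mean_pct - 44.6), 4)
  expect_identical(tidy(tc), tc$timecourse)

  # single time point series
  one <- ph$study
  one$cbf_series <- one$cbf_series[2]
  tc1 <- infarct_rcbf_timecourse(one, ph$truth$infarct_mask, contra_gm)
  expect_equal(nrow(tc1$timecourse), 1L)
  expect_equal(tc1$grand_mean_pct, tc1$timecourse$mean_rcbf_pct)
})

test_that("a null-effect phantom stays near 100% at every time point", {
  cfg <- small_phantom_config(
    seed = 43, infarct_present = FALSE, penumbra_rcbf = 1,
    rcbf_timecourse = tibble::tibble(
      time_min = c(10, 60, 120, 180), rcbf_fraction = rep(1, 4)
    )
  )
  ph <- generate_study(cfg)
  # probe the region where an infarct would have been
  geo_probe <- generate_study(small_phantom_config(seed = 43))$truth$infarct_mask
  contra_gm <- ph$study$roi_contra
  tc <- infarct_rcbf_timecourse(ph$study, geo_probe, contra_gm)
  expect_true(all(abs(tc$timecourse$mean_rcbf_pct - 100) < 5))
})
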