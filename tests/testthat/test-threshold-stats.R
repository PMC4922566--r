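test_that("class tables are built from the final masks with unit weights", {
  ph <- generate_study(small_phantom_config(seed = 2))
  med <- median_cbf_map(ph$study)
  seg <- final_analysis_masks(ph$study, med)
  tab <- build_class_table(med, seg$infarct_gm, seg$noninfarct_gm)
  expect_equal(nrow(tab),
               mask_count(seg$infarct_gm) + mask_count(seg$noninfarct_gm))
  expect_true(all(tab$weight == 1))
  expect_equal(sum(tab$label), mask_count(seg$infarct_gm))
  # a pixel in neither mask contributes no row
  neither <- mask_diff(ph$study$roi_affected,
                       mask_union(seg$infarct_gm, seg$noninfarct_gm))
  expect_equal(nrow(tab) + mask_count(neither), mask_count(ph$study$roi_affected))
  empty <- roi_mask(array(FALSE, ph$study$grid$shape), ph$study$grid)
  expect_error(build_class_table(med, empty, seg$noninfarct_gm), "non-analyzable")
})

test_that("balancing equalizes class mass without touching relative frequencies", {
  tab <- tibble::tibble(
    cbf = c(rnorm(100, 15, 5), rnorm(1000, 30, 8)),
    label = rep(c(1L, 0L), c(100, 1000)),
    weight = 1
  )
  bal <- balance_classes(tab)
  expect_true(all(bal$weight[bal$label == 1L] == 10))
  expect_true(all(bal$weight[bal$label == 0L] == 1))
  expect_equal(sum(bal$weight[bal$label == 1L]),
               sum(bal$weight[bal$label == 0L]), tolerance = 1e-9)
  # already balanced input is untouched
  eq <- tibble::tibble(cbf = rnorm(40), label = rep(c(1L, 0L), 20), weight = 1)
  expect_equal(balance_classes(eq), eq)
})

test_that("the ROC curve is bitwise invariant under class balancing", {
  set.seed(314)
  for (i in 1:5) {
    tab <- random_class_table(n1 = sample(20:60, 1), n0 = sample(100:300, 1))
    r1 <- roc_curve(tab)
    r2 <- roc_curve(balance_classes(tab))
    expect_identical(r1$curve, r2$curve)
    expect_identical(r1$auc, r2$auc)
  }
})

test_that("the logistic fit matches glm and is weight-scale invariant", {
  set.seed(11)
  tab <- tibble::tibble(
    cbf = c(rnorm(300, 12, 5), rnorm(300, 28, 6)),
    label = rep(c(1L, 0L), each = 300),
    weight = 1
  )
  fit <- fit_logistic(tab)
  expect_true(fit$converged)
  ref <- stats::glm(label ~ cbf, family = stats::binomial(), data = tab)
  expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_lt(fit$beta1, 0)

  scaled <- tab
  scaled$weight <- 7.3
  fit2 <- fit_logistic(scaled)
  expect_equal(fit2$beta0, fit$beta0, tolerance = 1e-8)
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-8)

  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "cbf"))
  expect_equal(td$std.error,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$p50_cbf, probability_crossing(fit, 0.5))
})

test_that("complete separation is flagged and the midpoint stays at p = 0.5", {
  tab <- tibble::tibble(
    cbf = rep(c(1, 3), each = 5),
    label = rep(c(1L, 0L), each = 5),
    weight = 1
  )
  fit <- fit_logistic(tab)
  expect_false(fit$converged)
  expect_equal(unname(predict(fit, 2)), 0.5, tolerance = 1e-8)
  expect_error(
    fit_logistic(tibble::tibble(cbf = rep(5, 4), label = c(1L, 1L, 0L, 0L),
                                weight = 1)),
    "identical"
  )
  expect_error(
    fit_logistic(tibble::tibble(cbf = 1:4, label = rep(1L, 4), weight = 1)),
    "classes"
  )
})

test_that("balanced equal-variance Gaussian classes recover the analytic logit", {
  # posterior log-odds for N(10, 5^2) vs N(30, 5^2) with equal mass is exactly
  # linear with slope (10 - 30) / 25 = -0.8 and 50% point at 20
  set.seed(123)
  n <- 20000
  tab <- tibble::tibble(
    cbf = c(rnorm(n, 10, 5), rnorm(n, 30, 5)),
    label = rep(c(1L, 0L), each = n),
    weight = 1
  )
  fit <- fit_logistic(tab)
  se1 <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$beta1 - (-0.8)), 3 * se1)
  expect_lt(abs(probability_crossing(fit, 0.5) - 20), 0.3)
  expect_lt(abs(probability_crossing(fit, 0.75) - (20 - log(3) / 0.8)), 0.3)
  # Youden optimum sits at the density crossing
  opt <- roc_curve(tab)$optimal
  expect_lt(abs(opt$threshold - 20), 0.5)
})

test_that("probability_crossing inverts the logistic closed form", {
  fit <- structure(
    list(beta0 = 5, beta1 = -1, converged = TRUE, n_iter = 1, log_lik = 0,
         nobs = 0, vcov = diag(2), cbf_range = c(0, 10)),
    class = "cbf_logit"
  )
  expect_equal(probability_crossing(fit, 0.5), 5)
  expect_equal(probability_crossing(fit, 0.75), 5 - log(3))
  fit$beta1 <- 0
  expect_error(probability_crossing(fit, 0.5), "zero")
})

test_that("ROC endpoints, AUC and the Mann-Whitney oracle agree", {
  # perfectly separated classes
  sep <- tibble::tibble(cbf = c(1, 2, 3, 10, 11, 12),
                        label = rep(c(1L, 0L), each = 3), weight = 1)
  r <- roc_curve(sep)
  expect_equal(r$auc, 1.0)
  # tie-break: the lowest threshold achieving J = 1 is the infarct maximum
  expect_equal(r$optimal$threshold, 3)
  expect_equal(r$optimal$youden, 1)

  # labels independent of CBF -> AUC near 1/2
  set.seed(5)
  null_tab <- tibble::tibble(cbf = rnorm(2000), label = rep(c(1L, 0L), 1000),
                             weight = 1)
  expect_lt(abs(roc_curve(null_tab)$auc - 0.5), 0.05)

  # trapezoid equals exhaustive pairwise concordance, with and without weights
  set.seed(6)
  for (i in 1:5) {
    tab <- random_class_table(n1 = 15, n0 = 35)
    expect_equal(roc_curve(tab)$auc, mw_concordance(tab), tolerance = 1e-12)
    wtab <- tab
    wtab$weight <- runif(nrow(tab), 0.5, 3)
    expect_equal(roc_curve(wtab)$auc, mw_concordance(wtab), tolerance = 1e-12)
  }
})

test_that("the ROC is a rank statistic and matches pROC on unweighted data", {
  set.seed(8)
  tab <- random_class_table(n1 = 30, n0 = 80)
  r1 <- roc_curve(tab)
  mono <- tab
  mono$cbf <- exp(tab$cbf / 10)
  r2 <- roc_curve(mono)
  expect_identical(r1$curve$sensitivity, r2$curve$sensitivity)
  expect_identical(r1$curve$specificity, r2$curve$specificity)
  expect_identical(r1$auc, r2$auc)

  pr <- pROC::roc(response = tab$label, predictor = tab$cbf,
                  direction = ">", levels = c(0, 1), quiet = TRUE)
  expect_equal(r1$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("the closest-to-corner criterion is available and reported", {
  set.seed(9)
  tab <- random_class_table(n1 = 40, n0 = 100)
  r <- roc_curve(tab, criterion = "closest")
  expect_equal(r$optimal$criterion, "closest")
  oy <- optimal_operating_point(r, "youden")
  oc <- optimal_operating_point(r, "closest")
  expect_equal(oc, r$optimal)
  # both optima must beat chance
  expect_gt(oy$youden, 0)
  # accuracy is the weight-averaged correct fraction
  cv <- r$curve[is.finite(r$curve$threshold), ]
  i <- which(cv$threshold == oy$threshold)
  expect_equal(oy$accuracy,
               (cv$sensitivity[i] * r$w1 + cv$specificity[i] * r$w0) /
                 (r$w1 + r$w0))
})
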