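# helper: one-slice study pieces on a shared grid
seg_fixture <- function(pet_vals, contra_idx, affected_idx, n = 4) {
  g <- flat_grid(n)
  contra <- affected <- rep(FALSE, n * n)
  contra[contra_idx] <- TRUE
  affected[affected_idx] <- TRUE
  list(
    g = g,
    pet = scalar_map(pet_vals, g, "PET"),
    contra = roi_mask(contra, g, "contralateral"),
    affected = roi_mask(affected, g, "affected")
  )
}

test_that("the PET defect rule thresholds at contralateral mean minus k SD", {
  pet_vals <- c(98, 100, 102, 100, 100, 96, 98, rep(0, 9))
  fx <- seg_fixture(pet_vals, contra_idx = 1:5, affected_idx = 6:7)
  res <- pet_infarct_mask(fx$pet, fx$affected, fx$contra)
  expect_equal(res$threshold, 100 - 2 * sqrt(2), tolerance = 1e-12)  # ~97.17
  expect_true(res$infarct$members[6])       # PET 96 < 97.17
  expect_false(res$infarct$members[7])      # PET 98 >= 97.17
  expect_true(res$noninfarct$members[7])
  # the two outputs partition the affected ROI
  expect_identical(res$infarct$members | res$noninfarct$members,
                   fx$affected$members)
  expect_equal(mask_count(mask_intersect(res$infarct, res$noninfarct)), 0L)
})

test_that("a constant contralateral ROI gives a zero-SD threshold at the mean", {
  pet_vals <- c(rep(100, 5), 99.9, 100, rep(0, 9))
  fx <- seg_fixture(pet_vals, contra_idx = 1:5, affected_idx = 6:7)
  res <- pet_infarct_mask(fx$pet, fx$affected, fx$contra)
  expect_equal(res$threshold, 100)
  expect_true(res$infarct$members[6])    # 99.9 < 100
  expect_false(res$infarct$members[7])   # equality stays non-infarct
  expect_error(
    pet_infarct_mask(fx$pet, fx$affected, roi_mask(rep(FALSE, 16), fx$g)),
    "empty"
  )
})

test_that("the white-matter rule is strictly below the HU cutoff", {
  g <- flat_grid(2)
  hu <- scalar_map(c(39.9, 40.0, 50, 35), g, "HU")
  wm <- white_matter_mask(hu)
  expect_identical(as.logical(wm$members), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(mask_count(white_matter_mask(scalar_map(rep(50, 4), g, "HU"))), 0L)
  expect_error(white_matter_mask(scalar_map(rep(50, 4), g, "PET")), "HU")
})

test_that("white matter is recovered from a noisy phantom almost exactly", {
  ph <- generate_study(small_phantom_config(seed = 13, gm_hu_sd = 1, wm_hu_sd = 1))
  wm <- white_matter_mask(ph$study$avg_image)
  gt <- ph$truth$wm_mask
  agree <- sum(wm$members == gt$members) / length(gt$members)
  expect_gte(agree, 0.99)
})

test_that("the vessel rules use strict BV and median-CBF cutoffs", {
  g <- flat_grid(3)
  # affected ROI holds BV {3,4,5}: mean 4, SD 1, threshold 6
  bv <- scalar_map(c(3, 4, 5, 6.1, 6.0, rep(0, 4)), g, "BV")
  med <- scalar_map(c(rep(50, 5), 100.1, 100.0, rep(50, 2)), g, "CBF")
  roi <- roi_mask(c(rep(TRUE, 3), rep(FALSE, 6)), g, "affected")
  ves <- vessel_mask(bv, med, roi)
  expect_equal(attr(ves, "bv_threshold"), 6)
  expect_true(ves$members[4])    # BV 6.1 > 6
  expect_false(ves$members[5])   # BV 6.0 is not strictly above
  expect_true(ves$members[6])    # median CBF 100.1 > 100
  expect_false(ves$members[7])   # 100.0 is not
  expect_error(vessel_mask(bv, med, roi_mask(rep(FALSE, 9), g)), "empty")
})

test_that("final masks are disjoint, inside the affected ROI, and order-independent", {
  ph <- generate_study(small_phantom_config(seed = 17))
  med <- median_cbf_map(ph$study)
  seg <- final_analysis_masks(ph$study, med)
  expect_equal(mask_count(mask_intersect(seg$infarct_gm, seg$noninfarct_gm)), 0L)
  both <- mask_union(seg$infarct_gm, seg$noninfarct_gm)
  expect_equal(mask_count(mask_diff(both, ph$study$roi_affected)), 0L)

  # exclusions commute: wm-then-vessels equals vessels-then-wm equals union
  pet <- pet_infarct_mask(ph$study$pet_image, ph$study$roi_affected,
                          ph$study$roi_contra)
  wm <- white_matter_mask(ph$study$avg_image)
  ves <- vessel_mask(ph$study$bv_map, med, ph$study$roi_affected)
  a <- mask_diff(mask_diff(pet$infarct, wm), ves)
  b <- mask_diff(mask_diff(pet$infarct, ves), wm)
  expect_identical(a$members, b$members)
  expect_identical(a$members, seg$infarct_gm$members)
})

test_that("tightening pet_k or hu_min shrinks the corresponding masks", {
  ph <- generate_study(small_phantom_config(seed = 19))
  med <- median_cbf_map(ph$study)
  prev <- NULL
  for (k in c(1, 2, 3)) {
    m <- pet_infarct_mask(ph$study$pet_image, ph$study$roi_affected,
                          ph$study$roi_contra, seg_params(pet_k = k))$infarct
    if (!is.null(prev)) {
      expect_equal(mask_count(mask_diff(m, prev)), 0L)  # m subset of prev
    }
    prev <- m
  }
  prev <- NULL
  for (h in c(45, 40, 35)) {
    m <- white_matter_mask(ph$study$avg_image, seg_params(hu_min = h))
    if (!is.null(prev)) {
      expect_equal(mask_count(mask_diff(m, prev)), 0L)
    }
    prev <- m
  }
})

test_that("a subject whose affected ROI is all vessels is flagged non-analyzable", {
  ph <- generate_study(small_phantom_config(seed = 23))
  med <- median_cbf_map(ph$study)
  # an absurdly low vessel CBF cap turns every pixel into vessel
  expect_warning(
    seg <- final_analysis_masks(ph$study, med, seg_params(cbf_vessel_cap = 0.01)),
    "non-analyzable"
  )
  expect_false(seg$analyzable)
})
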