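# constructed scenes: a 20^3 volume with one lacune, one WMH blob, one CMB
make_scene <- function() {
  d <- c(20, 20, 20)
  lac <- array(FALSE, d); lac[9:11, 9:11, 9:11] <- TRUE
  wmh <- array(FALSE, d); wmh[2:8, 2:8, 2:8] <- TRUE
  cmb <- array(FALSE, d); cmb[16, 16, 16] <- TRUE
  lesions <- lesion_set(lacunes = list(which(lac)), cmbs = list(which(cmb)),
                        wmh = wmh, dim3 = d)
  list(d = d, lac = lac, wmh = wmh, cmb = cmb, lesions = lesions)
}

hotspot_tbl <- function(voxels) {
  tibble::tibble(hotspot_id = seq_along(voxels), voxels = voxels)
}

test_that("hotspots in a lesion's contact band are flagged at its edge", {
  sc <- make_scene()
  # shell at Chebyshev distance 2 from the lacune: inside the contact band
  shell <- which(outer_band(sc$lac, radius = 2) & !outer_band(sc$lac, radius = 1))
  cls <- classify_hotspots(hotspot_tbl(list(shell[1:6])), sc$lesions)
  expect_true(cls$at_lacune_edge)
  expect_false(cls$at_cmb_edge)
  expect_equal(cls$lacune_ids[[1]], 1L)
})

test_that("WMH containment and edge categories are mutually exclusive", {
  sc <- make_scene()
  interior <- which(erode_one_voxel(sc$wmh))          # strictly inside
  straddle <- c(which(sc$wmh)[1:3],
                which(outer_band(sc$wmh, 1))[1:3])    # inside and outside
  cls <- classify_hotspots(hotspot_tbl(list(interior[1:8], straddle)),
                           sc$lesions)
  expect_equal(cls$within_wmh, c(TRUE, FALSE))
  expect_equal(cls$at_wmh_edge, c(FALSE, TRUE))
  expect_false(any(cls$within_wmh & cls$at_wmh_edge))
})

test_that("flags are independent across lesion classes", {
  # a hotspot fully inside WMH that also touches a lacune band
  d <- c(20, 20, 20)
  lac <- array(FALSE, d); lac[10:12, 10:12, 10:12] <- TRUE
  wmh <- array(FALSE, d); wmh[4:9, 4:14, 4:14] <- TRUE  # WMH next to lacune
  lesions <- lesion_set(lacunes = list(which(lac)), cmbs = list(),
                        wmh = wmh, dim3 = d)
  hs_vox <- which(wmh & outer_band(lac, radius = 2))
  expect_gt(length(hs_vox), 0)
  cls <- classify_hotspots(hotspot_tbl(list(hs_vox)), lesions)
  expect_true(cls$within_wmh)
  expect_true(cls$at_lacune_edge)
})

test_that("classification is invariant under scene translation and axis permutation", {
  sc <- make_scene()
  hs <- list(which(outer_band(sc$lac, radius = 2))[1:5])
  base <- classify_hotspots(hotspot_tbl(hs), sc$lesions)

  shift_mask <- function(m, by) {
    out <- array(FALSE, dim(m))
    idx <- which(m)
    cc <- arrayInd(idx, dim(m))
    cc <- cc + matrix(by, nrow(cc), 3, byrow = TRUE)
    out[cc] <- TRUE
    out
  }
  by <- c(2, 1, 3)
  lac2 <- shift_mask(sc$lac, by); wmh2 <- shift_mask(sc$wmh, by)
  cmb2 <- shift_mask(sc$cmb, by)
  hsm <- array(FALSE, sc$d); hsm[hs[[1]]] <- TRUE
  les2 <- lesion_set(lacunes = list(which(lac2)), cmbs = list(which(cmb2)),
                     wmh = wmh2, dim3 = sc$d)
  cls2 <- classify_hotspots(hotspot_tbl(list(which(shift_mask(hsm, by)))), les2)
  expect_equal(cls2$at_lacune_edge, base$at_lacune_edge)
  expect_equal(cls2$within_wmh, base$within_wmh)

  perm <- c(3, 1, 2)
  les3 <- lesion_set(lacunes = list(which(aperm(sc$lac, perm))),
                     cmbs = list(which(aperm(sc$cmb, perm))),
                     wmh = aperm(sc$wmh, perm), dim3 = sc$d)
  cls3 <- classify_hotspots(hotspot_tbl(list(which(aperm(hsm, perm)))), les3)
  expect_equal(cls3$at_lacune_edge, base$at_lacune_edge)
})

test_that("subgroup eligibility applies the Fazekas and minimal-NAWM rules", {
  b <- small_bundle()
  masks <- build_analysis_masks(b$phantom$labels)
  lesions <- lesion_set(b$phantom)
  # minimal WMH load: dwmh = 0 and pvh = 1 fails the entry rule
  e1 <- subgroup_eligibility(masks, lesions, fazekas_dwmh = 0, fazekas_pvh = 1)
  expect_false(e1$wmh_subgroup)
  e2 <- subgroup_eligibility(masks, lesions, fazekas_dwmh = 3, fazekas_pvh = 1)
  expect_true(e2$wmh_subgroup)
  # minimal NAWM left: raise the threshold above the phantom's NAWM fraction
  e3 <- subgroup_eligibility(masks, lesions, fazekas_dwmh = 3, fazekas_pvh = 3,
                             nawm_fraction_threshold = e2$nawm_fraction + 0.01)
  expect_false(e3$wmh_subgroup)
  # this phantom has deep-WM lacunes and a CMB
  expect_true(e1$lacune_subgroup)
  expect_true(e1$cmb_subgroup)
  expect_error(subgroup_eligibility(masks, lesions, 4, 0), "0-3")
  # without lesions the focal subgroups are empty
  ph0 <- generate_phantom(shape = c(36, 36, 36),
                          lesion_spec = lesion_spec(0, n_wmh_blobs = 0,
                                                    n_cmb = 0))
  m0 <- build_analysis_masks(ph0$labels)
  l0 <- lesion_set(ph0)
  e0 <- subgroup_eligibility(m0, l0, 1, 1)
  expect_false(e0$lacune_subgroup)
  expect_false(e0$cmb_subgroup)
})

test_that("cohort colocalization fractions equal a hand tally", {
  set.seed(5)
  patients <- tibble::tibble(
    id = sprintf("P%02d", 1:10),
    lacune_subgroup = c(rep(TRUE, 6), rep(FALSE, 4)),
    wmh_subgroup = rep(c(TRUE, FALSE), 5),
    cmb_subgroup = rep(FALSE, 10),
    lacune_edge_presence = c(1, 0, 1, 1, 0, 0, NA, NA, NA, NA),
    within_wmh_presence = rep(c(1, NA), 5),
    wmh_edge_presence = rep(c(0, NA), 5),
    cmb_edge_presence = rep(NA, 10),
    n_lacunes_total = c(3, 2, 1, 4, 2, 1, 0, 0, 0, 0),
    n_lacunes_with_hotspot = c(2, 0, 1, 1, 0, 0, 0, 0, 0, 0),
    n_cmbs_total = rep(0, 10),
    n_cmbs_with_hotspot = rep(0, 10)
  )
  s <- summarize_colocalization(patients)
  ps <- s$patient_summary
  expect_equal(ps$n_eligible[ps$category == "lacune_edge"], 6L)
  expect_equal(ps$n_with_hotspot[ps$category == "lacune_edge"], 3L)
  expect_equal(ps$fraction[ps$category == "lacune_edge"], 0.5)
  expect_equal(ps$fraction[ps$category == "within_wmh"], 1)
  expect_equal(ps$fraction[ps$category == "wmh_edge"], 0)
  # lesion-level: 4/13 lacunes in the eligible subgroup have hotspots
  ls <- s$lesion_summary
  expect_equal(ls$n_lesions[ls$lesion_class == "lacune"], 13)
  expect_equal(ls$fraction[ls$lesion_class == "lacune"], 4 / 13)
  # empty category is marked, not silently dropped
  expect_true("cmb_edge" %in% s$no_eligible)
})

test_that("per-lesion flags are monotone in hotspot count", {
  sc <- make_scene()
  band_vox <- which(outer_band(sc$lac, radius = 2))
  one <- classify_hotspots(hotspot_tbl(list(band_vox[1:5])), sc$lesions)
  two <- classify_hotspots(hotspot_tbl(list(band_vox[1:5], band_vox[6:10])),
                           sc$lesions)
  s1 <- colocalization_summary(one, sc$lesions)
  s2 <- colocalization_summary(two, sc$lesions)
  expect_gte(s2$n_lacunes_with_hotspot, s1$n_lacunes_with_hotspot)
  expect_gte(s2$n_lacune_edge, s1$n_lacune_edge)
})
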