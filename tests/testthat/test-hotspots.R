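test_that("the nearest-rank decile threshold follows rank arithmetic", {
  m <- array(TRUE, c(10, 10, 1))
  ps <- array(as.numeric(1:100), c(10, 10, 1))
  thr <- decile_threshold(ps, m)
  expect_equal(thr$threshold_value, 91)
  expect_equal(sort(ps[thr$selected]), as.numeric(91:100))
  expect_equal(thr$n_selected_voxels, 10L)
})

test_that("ties at the threshold are all included; constant maps select everything", {
  m <- array(TRUE, c(5, 5, 4))
  ps <- array(7, c(5, 5, 4))
  thr <- decile_threshold(ps, m)
  expect_equal(thr$n_selected_voxels, 100L)
  expect_gt(thr$ties_at_threshold, 0L)
  expect_error(decile_threshold(ps, array(FALSE, c(5, 5, 4))), "empty mask")
})

test_that("on large continuous maps the selected fraction is 10% within rounding", {
  set.seed(101)
  n <- c(50, 50, 40)  # 1e5 voxels
  ps <- array(rnorm(prod(n)), n)
  m <- array(TRUE, n)
  thr <- decile_threshold(ps, m)
  frac <- thr$n_selected_voxels / thr$n_mask_voxels
  expect_gte(frac, 0.0999)
  expect_lte(frac, 0.1001)
  # sort-based oracle: selected values are exactly the top-k order statistics
  k <- round(0.1 * prod(n))
  expect_equal(sort(ps[thr$selected]), sort(ps, decreasing = TRUE)[k:1])
})

test_that("the minimum-size filter keeps clusters of 5 or more voxels", {
  # constructed sizes 4, 5, 6 in one volume, mutually distant
  m <- array(FALSE, c(20, 20, 3))
  m[1:4, 1, 1] <- TRUE        # size 4
  m[1:5, 10, 1] <- TRUE       # size 5
  m[1:6, 18, 1] <- TRUE       # size 6
  comp <- label_components(m, 26)
  hs <- filter_min_size(comp, min_size = 5)
  expect_equal(nrow(hs), 2L)
  expect_setequal(hs$size, c(5L, 6L))
  # retained voxel total equals the recomputed sum of retained sizes
  expect_equal(sum(hs$size), length(unlist(hs$voxels)))
  # nothing survives when all clusters are small
  m2 <- array(FALSE, c(10, 10, 1)); m2[1:3, 1, 1] <- TRUE
  hs2 <- filter_min_size(label_components(m2, 26), 5)
  expect_equal(nrow(hs2), 0L)
})

test_that("hotspot extraction respects the mask and is rank-invariant", {
  b <- small_bundle()
  masks <- build_analysis_masks(b$phantom$labels)
  maps <- map_patlak(b$dce, b$vif, masks$wm_eroded)
  hs <- detect_hotspots(maps$ps, masks$wm_eroded, atlas = b$phantom$atlas,
                        voxel_mm = b$phantom$voxel_mm)
  expect_gt(hs$n_hotspots, 0L)
  expect_true(all(hs$hotspots$size >= 5L))
  expect_true(all(unlist(hs$hotspots$voxels) %in% which(masks$wm_eroded)))
  # hotspot voxel sets are pairwise disjoint and within the selected set
  vox <- unlist(hs$hotspots$voxels)
  expect_equal(length(vox), length(unique(vox)))
  expect_true(all(vox %in% which(hs$selected)))
  # a strictly monotone transform of the map leaves the hotspots unchanged
  hs2 <- detect_hotspots(exp(1e4 * maps$ps), masks$wm_eroded,
                         atlas = b$phantom$atlas,
                         voxel_mm = b$phantom$voxel_mm)
  expect_equal(hs2$n_hotspots, hs$n_hotspots)
  expect_identical(hs2$hotspots$voxels, hs$hotspots$voxels)
})

test_that("region assignment takes the majority vote with a deterministic tie-break", {
  atlas <- array(0L, c(10, 10, 1))
  atlas[1:6, 1, 1] <- 61L  # centrum semiovale, left
  expect_equal(assign_region(which(atlas == 61L), atlas)$region,
               "centrum_semiovale")
  # 3 voxels of code 21 vs 2 of code 51 -> majority 21
  a2 <- array(0L, c(10, 1, 1)); a2[1:3] <- 21L; a2[4:5] <- 51L
  r <- assign_region(1:5, a2)
  expect_equal(r$code, 21L)
  expect_equal(r$region, "internal_capsule")
  # exact 3-3 tie between codes 21 and 51 -> lowest code wins
  a3 <- array(0L, c(10, 1, 1)); a3[1:3] <- 21L; a3[4:6] <- 51L
  expect_equal(assign_region(1:6, a3)$code, 21L)
  # all-unlabeled hotspot
  expect_equal(assign_region(1:3, array(0L, c(5, 1, 1)))$region, "unassigned")
})

test_that("regional load maps counts to the 0-6 summed ordinal scale", {
  mk <- function(counts_left, counts_right, region = "temporal") {
    tibble::tibble(
      region = region,
      side = rep(c("left", "right"), c(counts_left, counts_right)))
  }
  hs <- dplyr::bind_rows(mk(2, 4))  # left 2 -> 1, right 4 -> 2
  load <- regional_load(hs)
  row <- load[load$region == "temporal", ]
  expect_equal(row$load_left, 1L)
  expect_equal(row$load_right, 2L)
  expect_equal(row$load_total, 3L)
  # absent regions score 0; maximum attainable is 6
  expect_true(all(load$load_total[load$region != "temporal"] == 0L))
  big <- regional_load(mk(10, 40, "cerebellum"))
  expect_equal(max(big$load_total), 6L)
  expect_true(all(regional_load(tibble::tibble(region = character(),
                                               side = character()))$load_total == 0L))
})
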