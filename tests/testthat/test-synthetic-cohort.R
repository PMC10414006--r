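codes <- label_codes()

test_that("an empty lesion spec yields white matter and no lesions", {
  ph <- generate_phantom(shape = c(36, 36, 36),
                         lesion_spec = lesion_spec(n_lacunes = 0,
                                                   n_wmh_blobs = 0, n_cmb = 0),
                         seed = 5)
  expect_gt(sum(ph$labels == codes[["wm"]]), 0)
  expect_equal(sum(ph$labels %in% codes[c("wmh", "lacune", "cmb")]), 0)
  expect_equal(nrow(ph$lesion_index), 0L)
})

test_that("three requested lacunes form exactly three connected cavities", {
  ph <- generate_phantom(shape = c(48, 48, 48),
                         lesion_spec = lesion_spec(n_lacunes = 3,
                                                   lacune_radius = c(2, 2),
                                                   n_wmh_blobs = 0, n_cmb = 0),
                         seed = 9)
  lac <- ph$labels == codes[["lacune"]]
  comp <- oracle_flood_fill(lac, 26)
  expect_equal(max(comp), 3L)
  expect_equal(sum(ph$lesion_index$class == "lacune"), 3L)
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generate_phantom(seed = 21)
  b <- generate_phantom(seed = 21)
  expect_identical(a$labels, b$labels)
  expect_identical(a$atlas, b$atlas)
  expect_identical(a$lesion_index$voxels, b$lesion_index$voxels)
})

test_that("phantom invariants hold: atlas coverage, lesion labels, sizing errors", {
  ph <- small_bundle()$phantom
  wm_class <- ph$labels %in% codes[c("wm", "wmh")]
  expect_true(all(ph$atlas[wm_class] > 0L))           # atlas covers WM-class
  # lesion-index voxels carry the matching label
  for (i in seq_len(nrow(ph$lesion_index))) {
    cls <- ph$lesion_index$class[i]
    vox <- ph$lesion_index$voxels[[i]]
    if (cls == "lacune") expect_true(all(ph$labels[vox] == codes[["lacune"]]))
    if (cls == "cmb") expect_true(all(ph$labels[vox] == codes[["cmb"]]))
    if (cls == "wmh") expect_true(all(ph$labels[vox] == codes[["wmh"]]))
  }
  # lacune interiors are never WM/WMH, by construction of the label volume
  expect_error(
    generate_phantom(shape = c(32, 32, 32),
                     lesion_spec = lesion_spec(n_lacunes = 40,
                                               lacune_radius = c(3, 3))),
    "too small")
})

test_that("truth maps are piecewise-constant off foci and carry the requested bases", {
  ph <- generate_phantom(shape = c(36, 36, 36),
                         lesion_spec = lesion_spec(n_lacunes = 1,
                                                   n_wmh_blobs = 2, n_cmb = 0),
                         seed = 3)
  tr <- generate_truth_maps(ph,
                            base_ps = c(nawm = 2e-4, wmh = 4e-4),
                            base_vp = c(nawm = 0.01, wmh = 0.015),
                            focus_spec = focus_spec(), seed = 1)
  expect_equal(unique(tr$ps_true[ph$labels == codes[["wm"]]]), 2e-4)
  expect_equal(unique(tr$ps_true[ph$labels == codes[["wmh"]]]), 4e-4)
  expect_equal(sort(unique(tr$vp_true[ph$labels %in% codes[c("wm", "wmh")]])),
               c(0.01, 0.015))
  expect_true(all(tr$vp_true >= 0 & tr$vp_true <= 1))
  expect_true(all(is.finite(tr$ps_true)))
})

test_that("a lacune-rim focus raises mean PS over the rim band above baseline", {
  ph <- generate_phantom(shape = c(40, 40, 40),
                         lesion_spec = lesion_spec(n_lacunes = 1,
                                                   n_wmh_blobs = 0, n_cmb = 0),
                         seed = 7)
  amp <- 5e-4
  tr <- generate_truth_maps(ph, focus_spec = focus_spec(at_lacune_rim = 1,
                                                        amplitude = amp),
                            seed = 8)
  lac_mask <- array(FALSE, dim = ph$shape)
  lac_mask[ph$lesion_index$voxels[[1]]] <- TRUE
  band <- outer_band(lac_mask, radius = 2) &
    (ph$labels %in% codes[c("wm", "wmh")])
  nawm_base <- 0.43e-4
  # recompute the band mean directly from the constructed map
  expect_gt(mean(tr$ps_true[band]), nawm_base)
  # focus voxels sit exactly amplitude above baseline
  fv <- tr$focus_index$voxels[[1]]
  expect_true(all(abs(tr$ps_true[fv] - (nawm_base + amp)) < 1e-12 |
                    abs(tr$ps_true[fv] - (0.91e-4 + amp)) < 1e-12))
  # all focus voxels are WM-class
  expect_true(all(ph$labels[fv] %in% codes[c("wm", "wmh")]))
})

test_that("focus attachments to absent lesion classes are rejected", {
  ph <- generate_phantom(shape = c(36, 36, 36),
                         lesion_spec = lesion_spec(n_lacunes = 0,
                                                   n_wmh_blobs = 0, n_cmb = 0),
                         seed = 2)
  expect_error(generate_truth_maps(ph, focus_spec = focus_spec(at_lacune_rim = 1)),
               "no lacunes")
  expect_error(generate_truth_maps(ph, focus_spec = focus_spec(inside_wmh = 1)),
               "no WMH")
})

test_that("the DCE forward model reduces to vp * cp when PS is zero and is seeded", {
  ph <- generate_phantom(shape = c(32, 32, 32),
                         lesion_spec = lesion_spec(0, n_wmh_blobs = 0, n_cmb = 0))
  tr <- generate_truth_maps(ph, base_ps = c(nawm = 0, wmh = 0),
                            base_vp = c(nawm = 0.4, wmh = 0.4),
                            focus_spec = focus_spec())
  vif <- generate_vif(times = seq(0, 300, 30))
  dce <- synthesize_dce(tr, vif, noise_sd = 0)
  wm_vox <- which(ph$labels == label_codes()[["wm"]])[1]
  cc <- arrayInd(wm_vox, ph$shape)
  expect_equal(dce$conc[cc[1], cc[2], cc[3], ], 0.4 * vif$cp)
  # pre-arrival frames are exactly zero without noise
  expect_true(all(dce$conc[, , , vif$times < vif$arrival_time] == 0))
  # seeded noise is reproducible
  d1 <- synthesize_dce(tr, vif, noise_sd = 0.01, seed = 5)
  d2 <- synthesize_dce(tr, vif, noise_sd = 0.01, seed = 5)
  expect_identical(d1$conc, d2$conc)
  expect_error(synthesize_dce(tr, vif, times = seq(0, 290, 29)), "time axis")
})

test_that("the mean over seeded noisy replicates approaches the noise-free curve", {
  # Monte-Carlo oracle at a single voxel: 200 replicates, tolerance
  # 3 * noise_sd / sqrt(200) per time point
  vif <- generate_vif(times = seq(0, 300, 30))
  cumint <- cumulative_vif_integral(vif)
  ps <- 2e-4; vp <- 0.01; sd <- 0.01
  clean <- vp * vif$cp + ps * cumint
  set.seed(99)
  reps <- replicate(200, clean + rnorm(length(clean), sd = sd))
  expect_true(all(abs(rowMeans(reps) - clean) < 3 * sd / sqrt(200)))
})

test_that("cohort sampling respects the design and is reproducible", {
  expect_equal(nrow(sample_cohort(cohort_design(n_patients = 0))$covariates), 0L)
  des <- cohort_design(n_patients = 200, prop_cadasil = 0.4, seed = 31)
  coh <- sample_cohort(des)
  p_hat <- mean(coh$covariates$svd_type == "cadasil")
  # binomial 99% bounds for n = 200, p = 0.4
  bounds <- qbinom(c(0.005, 0.995), 200, 0.4) / 200
  expect_gte(p_hat, bounds[1])
  expect_lte(p_hat, bounds[2])
  coh2 <- sample_cohort(des)
  expect_identical(coh$covariates, coh2$covariates)
  # grades in range, counts non-negative, missing CVR marked not imputed
  cv <- coh$covariates
  expect_true(all(cv$fazekas_dwmh %in% 0:3 & cv$fazekas_pvh %in% 0:3))
  expect_true(all(cv$n_lacunes >= 0 & cv$n_cmb >= 0))
  expect_true(any(is.na(cv$cvr_wmh)))
  expect_true(all(cv$svd_score %in% 0:4))
})

test_that("planted effects push outcome prevalence in the configured direction", {
  des <- cohort_design(n_patients = 400, seed = 17)
  cv <- sample_cohort(des)$covariates
  elig <- cv[cv$lacune_subgroup & !is.na(cv$cvr_wmh), ]
  lo <- elig$cvr_wmh < median(elig$cvr_wmh)
  # planted log-odds -0.8 per SD of WMH CVR: low-CVR patients show
  # lacune-edge hotspots more often
  expect_gt(mean(elig$lacune_edge_presence[lo]),
            mean(elig$lacune_edge_presence[!lo]))
})
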