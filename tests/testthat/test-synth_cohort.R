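test_that("generation is reproducible and satisfies the record invariants", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_controls = 5, n_positive = 2, n_negative = 2,
                       n_lesions = 3, seed = 11)
  co <- generate_cohort(cfg, m)
  co2 <- generate_cohort(cfg, m)
  expect_identical(co$subjects, co2$subjects)   # bit-identical for same seed

  expect_equal(co$measure_names, sbm_measure_names())
  expect_length(sbm_measure_names(), 19)
  groups <- vapply(co$subjects, `[[`, "", "group")
  for (s in co$subjects) {
    expect_true(all(is.finite(s$base_measures)))
    expect_equal(nrow(s$base_measures), m$nv)
    if (s$group == "mri_positive") expect_gte(length(s$lesion_labels), 1)
    if (s$group == "control") {
      expect_length(s$lesion_labels, 0)
      expect_null(s$hypothesis_label)
    }
    if (s$group == "mri_negative") {
      phi <- s$hypothesis_label$phi
      expect_gte(phi, cfg$hypothesis_phi_range[1])
      expect_lte(phi, cfg$hypothesis_phi_range[2])
    }
  }
  expect_equal(sum(vapply(co$subjects, function(s)
    length(s$lesion_labels), 0L)), 3)
})

test_that("intensity depth maps are complete, ordered and depth-correlated", {
  co <- fixture_cohort()
  expect_true(all(c(paste0("t1_", c("75", "50", "25", "interface",
                                    "m1mm", "m2mm")),
                    paste0("flair_", c("75", "50", "25", "interface",
                                       "m1mm", "m2mm"))) %in%
                  co$measure_names))
  t1 <- c("t1_75", "t1_50", "t1_25", "t1_interface", "t1_m1mm", "t1_m2mm")
  ctrl <- co$subjects[vapply(co$subjects, `[[`, "", "group") == "control"]
  # monotone depth gradient: subcortical T1 above the cortical baseline
  depth_means <- colMeans(do.call(rbind, lapply(ctrl, function(s)
    colMeans(s$base_measures[, t1]))))
  expect_true(all(diff(depth_means) > 0))
  # adjacent-depth correlation of each subject's T1 maps
  cors <- vapply(ctrl, function(s) {
    b <- s$base_measures[, t1]
    min(vapply(1:5, function(d) cor(b[, d], b[, d + 1]), 0))
  }, 0)
  expect_true(all(cors >= 0.5))
})

test_that("zero-noise generation is a deterministic transform of the means", {
  m <- fixture_mesh(2)
  cfg <- cohort_config(n_controls = 3, n_positive = 0, n_negative = 0,
                       noise_sd = 0, subject_sd = 0,
                       covariate_effect_sizes = c(age = 0, sex = 0,
                                                  site = 0, icv = 0),
                       seed = 4)
  co <- generate_cohort(cfg, m)
  expect_equal(co$subjects[[1]]$base_measures, co$subjects[[2]]$base_measures)
  expect_equal(co$subjects[[2]]$base_measures, co$subjects[[3]]$base_measures)
})

test_that("intensity normalization is the two-point affine map", {
  expect_equal(normalize_intensity(rep(1000, 5), 1400, 1000), rep(0, 5))
  expect_equal(normalize_intensity(rep(1400, 5), 1400, 1000), rep(1, 5))
  expect_equal(normalize_intensity(1200, 1400, 1000), 0.5)
  expect_error(normalize_intensity(1:5, 1000, 1000), "differ")
  # generated cohorts carry the per-subject reference convention
  co <- fixture_cohort()
  s <- co$subjects[[1]]
  expect_equal(median(s$base_measures[, "t1_50"]), 0, tolerance = 1e-9)
  expect_equal(median(s$base_measures[, "t1_m1mm"]), 1, tolerance = 1e-9)
})

test_that("white/grey contrast is a deterministic function of the T1 maps", {
  co <- fixture_cohort()
  for (s in co$subjects[c(1, 9)]) {
    t1m1 <- s$base_measures[, "t1_m1mm"]
    t150 <- s$base_measures[, "t1_50"]
    expect_equal(s$base_measures[, "wg_contrast"],
                 100 * (t1m1 - t150) / pmax(0.5 * (t1m1 + t150), 0.05))
  }
  expect_error(cohort_config(lesion_effects = c(wg_contrast = -2)),
               "derived")
})

test_that("implanted lesion effects are recovered in control-SD units", {
  m <- fixture_mesh(4)
  cfg <- cohort_config(n_controls = 40, n_positive = 16, n_negative = 0,
                       lesion_radius_mm = c(10, 10),
                       lesion_effects = c(thickness = 4),
                       covariate_effect_sizes = c(age = 0, sex = 0,
                                                  site = 0, icv = 0),
                       measures = "thickness", seed = 33)
  co <- generate_cohort(cfg, m)
  ctrl <- sapply(co$subjects[1:40], function(s) s$base_measures[, "thickness"])
  mu <- rowMeans(ctrl)
  sdv <- apply(ctrl, 1, sd)
  ratios <- vapply(41:56, function(i) {
    s <- co$subjects[[i]]
    les <- s$lesion_labels[[1]]$vertex_ids
    mean(s$base_measures[les, "thickness"] - mu[les]) / mean(sdv[les])
  }, 0)
  expect_lt(abs(mean(ratios) - 4) / 4, 0.10)
  # the FCD profile: white/grey contrast decreases inside lesions
  cfg2 <- cohort_config(n_controls = 10, n_positive = 8, n_negative = 0,
                        lesion_radius_mm = c(15, 15), seed = 9)
  co2 <- generate_cohort(cfg2, fixture_mesh(3))
  ctrl_wg <- rowMeans(sapply(co2$subjects[1:10], function(s)
    s$base_measures[, "wg_contrast"]))
  drops <- vapply(11:18, function(i) {
    s <- co2$subjects[[i]]
    les <- s$lesion_labels[[1]]$vertex_ids
    mean(s$base_measures[les, "wg_contrast"] - ctrl_wg[les])
  }, 0)
  expect_lt(mean(drops), 0)
})

test_that("zero-effect patients are exchangeable with controls", {
  m <- fixture_mesh(2)
  rejections <- 0L; tests <- 0L
  for (seed in 1:4) {
    cfg <- cohort_config(n_controls = 20, n_positive = 10, n_negative = 0,
                         lesion_effects = c(thickness = 0),
                         negative_effect_scale = 0,
                         measures = c("sulc", "thickness"), seed = seed)
    co <- generate_cohort(cfg, m)
    set.seed(seed + 100)
    verts <- sample.int(m$nv, 5)
    for (meas in c("sulc", "thickness")) {
      ctrl <- sapply(co$subjects[1:20], function(s) s$base_measures[, meas])
      pat <- sapply(co$subjects[21:30], function(s) s$base_measures[, meas])
      for (v in verts) {
        p <- suppressWarnings(ks.test(ctrl[v, ], pat[v, ])$p.value)
        tests <- tests + 1L
        rejections <- rejections + (p < 0.05)
      }
    }
  }
  expect_lte(rejections / tests, 0.2)  # nominal 5%, generous binomial slack
})

test_that("configuration errors are refused up front", {
  m <- fixture_mesh(2)
  expect_error(cohort_config(n_controls = 2), ">= 3")
  expect_error(cohort_config(n_positive = 4, n_lesions = 2), "n_lesions")
  expect_error(
    generate_cohort(cohort_config(lesion_radius_mm = c(200, 400)), m),
    "hemisphere")
  expect_error(cohort_config(measures = c("wg_contrast", "thickness")),
               "t1_50")
})
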