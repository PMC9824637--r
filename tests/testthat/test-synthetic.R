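test_that("scene generation is deterministic in the seed", {
  sp <- scene_spec(seed = 201)
  s1 <- generate_scene(sp)
  s2 <- generate_scene(sp)
  expect_identical(s1$stems, s2$stems)
  expect_identical(s1$occupied, s2$occupied)
  s3 <- generate_scene(scene_spec(seed = 202))
  expect_false(identical(s1$occupied, s3$occupied))
})

test_that("zero understory intensity leaves the strata empty end to end", {
  sp <- scene_spec(stem_density = 0, understory_intensity_LU = 0,
                   understory_intensity_UU = 0, seed = 203)
  sc <- generate_scene(sp)
  truth <- scene_truth_pdi(sc)
  expect_equal(truth$true_pdi[truth$stratum %in% c("LU", "UU")], c(0, 0))
  geom <- plot_geometry(13.5, 13.5)
  tls <- sample_tls(sc, geom, seed = 204)
  expect_lt(max(tls$z), 0.2)  # ground returns only
  prof <- strata_profile(clip_to_plot(tls, geom), geom)
  expect_equal(prof$strata$pdi, rep(0, 5))
  expect_error(scene_spec(understory_intensity_LU = 1.2), "feasible")
})

test_that("realized stratum occupancy tracks the requested intensity", {
  # 20 seeds at LU intensity 0.3: mean realized occupancy within 0.03
  real <- vapply(1:20, function(s) {
    sc <- generate_scene(scene_spec(stem_density = 0,
                                    understory_intensity_LU = 0.3,
                                    understory_intensity_UU = 0.1,
                                    seed = 300 + s))
    truth <- scene_truth_pdi(sc)
    truth$true_pdi[truth$stratum == "LU"]
  }, numeric(1))
  expect_lt(abs(mean(real) - 0.3), 0.03)
  expect_lt(abs(mean(vapply(1:20, function(s) {
    sc <- generate_scene(scene_spec(stem_density = 0,
                                    understory_intensity_LU = 0.3,
                                    understory_intensity_UU = 0.1,
                                    seed = 300 + s))
    scene_truth_pdi(sc)$true_pdi[4]
  }, numeric(1))) - 0.1), 0.03)
})

test_that("TLS sampling recovers the scene truth per stratum", {
  sc <- generate_scene(scene_spec(understory_intensity_LU = 0.35,
                                  understory_intensity_UU = 0.2,
                                  stem_density = 250, seed = 210))
  geom <- plot_geometry(13.5, 13.5)
  tls <- sample_tls(sc, geom, noise_sd = 0, seed = 211)
  expect_identical(tls, sample_tls(sc, geom, noise_sd = 0, seed = 211))
  prof <- strata_profile(clip_to_plot(tls, geom), geom)
  truth <- scene_truth_pdi(sc)
  merged <- merge(prof$strata, truth, by = "stratum")
  expect_true(all(abs(merged$pdi - merged$true_pdi) <= 0.05),
              info = paste(round(merged$pdi - merged$true_pdi, 3),
                           collapse = ", "))
})

test_that("ALS sampling respects canopy occlusion physics", {
  # transmission 1 with no understory: every first return is ground
  sp <- scene_spec(understory_intensity_LU = 0, understory_intensity_UU = 0,
                   stem_density = 300, seed = 220)
  sc <- generate_scene(sp)
  sc$occupied <- sc$occupied[0, ]  # strip trunk/crown voxels too
  als <- sample_als(sc, canopy_transmission = 1, seed = 221)
  expect_true(all(als$classification == 2L))
  expect_lt(max(als$z), 0.2)
  expect_identical(als, sample_als(sc, canopy_transmission = 1, seed = 221))

  # denser canopies never let more pulses reach below (in expectation)
  sub_canopy_rate <- function(tr) {
    sc2 <- generate_scene(scene_spec(stem_density = 400,
                                     understory_intensity_LU = 0.3,
                                     understory_intensity_UU = 0.2,
                                     seed = 222))
    a <- sample_als(sc2, canopy_transmission = tr, seed = 223)
    mean(a$z < 10)
  }
  rates <- vapply(c(0.2, 0.5, 0.9), sub_canopy_rate, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("understory-only scenes put HM_1_3 near the layer's weighted height", {
  study <- simulate_linear_link_study(n_plots = 6, seed = 230)
  d <- linear_link_metrics(study, seed = 231)
  # measured HM_1_3 close to the geometric expectation, plot by plot
  expect_true(all(abs(d$HM_1_3 - study$plots$hm13_true) < 0.35))
  expect_gt(cor(d$HM_1_3, study$plots$hm13_true), 0.9)
})

test_that("the linear-link construction realizes its stated response", {
  study <- simulate_linear_link_study(seed = 240)
  p <- study$plots
  eps <- p$uu_true_pdi - (study$true_slope * p$hm13_true +
                            study$true_intercept)
  # clipping aside, the residuals behave like the stated Gaussian noise
  expect_lt(abs(mean(eps)), 0.04)
  expect_lt(sd(eps), 0.08)
  expect_true(all(p$uu_true_pdi >= 0 & p$uu_true_pdi <= 0.5))
  expect_true(all(p$lu_true_pdi > 0))
})
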