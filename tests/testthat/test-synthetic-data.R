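test_that("empty scenario renders a uniform pink field with empty masks", {
  sc <- image_scenario(width = 64, height = 48, n_nests = 0,
                       nuclei_density_in_nest = 0, stromal_round_density = 0,
                       stromal_nonround_density = 0, stain_noise_sd = 0,
                       illumination_gradient = 0, seed = 1)
  out <- generate_he_image(sc)
  expect_equal(sum(out$truth$nest_mask), 0)
  expect_equal(sum(out$truth$nuclei_mask), 0)
  # uniform: one color everywhere; pink: red channel dominates green
  px <- matrix(out$image, ncol = 3)
  expect_equal(nrow(unique(px)), 1)
  expect_gt(px[1, 1], px[1, 2])
})

test_that("generation is bit-identical under a fixed seed", {
  sc <- image_scenario(width = 96, height = 96, n_nests = 3,
                       nest_area_mean = 1200, seed = 7)
  a <- generate_he_image(sc)
  b <- generate_he_image(sc)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$nuclei_mask, b$truth$nuclei_mask)
})

test_that("requested stromal nuclei are all placed and counted", {
  # 50 round nuclei on pure stroma: density chosen so count = 50
  area <- 200 * 150
  sc <- image_scenario(width = 150, height = 200, n_nests = 0,
                       nuclei_density_in_nest = 0,
                       stromal_round_density = 50 / area,
                       stromal_nonround_density = 0, seed = 3)
  out <- generate_he_image(sc)
  expect_equal(unname(out$truth$true_counts["stromal_round"]), 50L)
})

test_that("every epithelial centroid lies inside the nest mask", {
  out <- small_scene()
  epi <- dplyr::filter(out$truth$centroids, class == "epithelial")
  inside <- out$truth$nest_mask[cbind(round(epi$row), round(epi$col))] > 0
  expect_true(all(inside))
  # and every labeled nucleus has a class
  ids <- setdiff(unique(as.vector(out$truth$nuclei_mask)), 0)
  expect_true(all(!is.na(out$truth$nucleus_classes[ids])))
  expect_equal(sum(out$truth$true_counts), length(out$truth$nucleus_classes))
})

test_that("infeasible densities are rejected", {
  sc <- image_scenario(width = 64, height = 64, n_nests = 1,
                       nest_area_mean = 2000,
                       nuclei_density_in_nest = 0.02,  # 4x the feasible packing
                       seed = 2)
  expect_error(generate_he_image(sc), "infeasible density")
})

test_that("labeled pixel samples are balanced, in-mask and reproducible", {
  out <- small_scene()
  px <- generate_labeled_pixels(out$truth, 10, seed = 5)
  expect_equal(nrow(px), 20L)
  expect_equal(sum(px$label == "nest"), 10L)
  nest_px <- dplyr::filter(px, label == "nest")
  expect_true(all(out$truth$nest_mask[cbind(nest_px$row, nest_px$col)] > 0))
  stroma_px <- dplyr::filter(px, label == "stroma")
  expect_true(all(out$truth$nest_mask[cbind(stroma_px$row, stroma_px$col)] == 0))
  expect_identical(px, generate_labeled_pixels(out$truth, 10, seed = 5))
  expect_error(generate_labeled_pixels(out$truth, 1e6), "fewer than")
})

test_that("cohort has the right shape and no censoring means all events", {
  sc <- cohort_scenario(n_patients = 230, images_per_patient = 5, seed = 11)
  coh <- generate_cohort(sc)
  expect_equal(nrow(coh$images), 1150L)
  expect_equal(nrow(coh$patients), 230L)
  sc0 <- cohort_scenario(n_patients = 100, betas = c(), censor_rate = 0,
                         follow_up_max = Inf, seed = 4)
  coh0 <- generate_cohort(sc0)
  expect_equal(mean(coh0$patients$event), 1.0)
  expect_identical(generate_cohort(sc0)$patients, coh0$patients)
  expect_error(cohort_scenario(baseline_hazard = -1))
})

test_that("a unit log-hazard on a binary feature yields an empirical hazard ratio near e", {
  sc <- cohort_scenario(n_patients = 5000, betas = c(x = 1),
                        feature_types = c(x = "binary"),
                        censor_rate = 0, follow_up_max = Inf, seed = 21)
  coh <- generate_cohort(sc)
  # Monte-Carlo oracle: with exponential times and no censoring, the group
  # mean time ratio estimates the hazard ratio
  hr_emp <- mean(coh$patients$time[coh$patients$x == 0]) /
    mean(coh$patients$time[coh$patients$x == 1])
  expect_equal(hr_emp, exp(1), tolerance = 0.1)
})

test_that("null-model survival follows the exponential baseline", {
  sc <- cohort_scenario(n_patients = 2000, betas = c(), censor_rate = 0,
                        follow_up_max = Inf, seed = 8)
  coh <- generate_cohort(sc)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = coh$patients)
  grid <- c(12, 24, 48, 72)
  s_hat <- summary(fit, times = grid)$surv
  s_true <- exp(-sc$baseline_hazard * grid)
  se <- sqrt(s_true * (1 - s_true) / 2000)
  expect_true(all(abs(s_hat - s_true) < 3.5 * se))
})
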