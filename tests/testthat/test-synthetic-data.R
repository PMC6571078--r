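test_that("generation is deterministic under a fixed seed", {
  a <- generate_dataset(quick_config(seed = 99))
  b <- generate_dataset(quick_config(seed = 99))
  expect_identical(a$observations, b$observations)
  expect_identical(a$truth$per_study, b$truth$per_study)
  c <- generate_dataset(quick_config(seed = 100))
  expect_false(identical(a$observations$size_value,
                         c$observations$size_value))
})

test_that("zero noise reproduces the true clines, ratio and SDI exactly", {
  cfg <- quick_config(seed = 17, noise_sd_range = c(0, 0))
  ds <- generate_dataset(cfg)
  obs <- apply_conversions(ds$observations)
  fits <- suppressWarnings(fit_all_clines(obs))
  pairs <- suppressWarnings(build_cline_pairs(fits))
  truth <- ds$truth$per_study
  truth <- truth[match(pairs$study_id, truth$study_id), ]
  expect_equal(pairs$female_slope, truth$female_slope, tolerance = 1e-8)
  expect_equal(pairs$male_slope, truth$male_slope, tolerance = 1e-8)
  expect_equal(pairs$size_cline_ratio, truth$true_ratio, tolerance = 1e-6)
  expect_equal(pairs$sdi, truth$true_sdi, tolerance = 1e-6)
  expect_true(all(abs(fits$r_squared - 1) < 1e-10))
})

test_that("the empty and counting contracts hold", {
  empty <- generate_dataset(generator_config(n_studies = 0))
  expect_null(empty$observations)

  ds <- generate_dataset(generator_config(n_studies = 50, seed = 2))
  obs <- apply_conversions(ds$observations)
  pairs <- build_cline_pairs(fit_all_clines(obs))
  expect_equal(nrow(pairs), 50)
  expect_length(validate_dataset(ds$observations)$errors, 0)
})

test_that("seasonal configurations are all multivoltine and other gradients scale", {
  ds <- generate_dataset(quick_config(gradient_type = "seasonal_temperature",
                                      seed = 4))
  expect_true(all(ds$observations$voltinism == "multivoltine"))
  alt <- generate_dataset(quick_config(gradient_type = "altitude", seed = 4))
  expect_true(all(alt$observations$gradient_value <= 2000))
  ## per-150m percent change is on the same scale as per-degree latitude
  expect_equal(median(abs(percent_change(
    generate_dataset(quick_config(seed = 4))$truth$per_study$female_slope))),
    median(abs(percent_change(alt$truth$per_study$female_slope, 150))),
    tolerance = 0.5)
})

test_that("realized true ratios follow the configured distribution", {
  cfg <- generator_config(n_studies = 400, seed = 13,
                          taxonomy_shape = c(classes = 2, orders = 8,
                                             families = 40, species = 400))
  ds <- generate_dataset(cfg)
  r <- ds$truth$per_study$true_ratio
  total_sd <- sqrt(cfg$ratio_sd_species^2 + cfg$ratio_sd_study^2)
  ks <- stats::ks.test(r, "pnorm", cfg$true_overall_ratio, total_sd)
  expect_gt(ks$p.value, 0.01)
  ## the true ratio is recomputable from the two true slopes via the
  ## signed larger/smaller rule
  ps <- ds$truth$per_study
  expect_equal(size_cline_ratio(percent_change(ps$male_slope),
                                percent_change(ps$female_slope)),
               ps$true_ratio, tolerance = 1e-8)
})

test_that("a small recovery experiment reports the recovery summaries", {
  cfg <- generator_config(seed = 23, n_studies = 20, stations_per_study = 5,
                          taxonomy_shape = c(classes = 2, orders = 3,
                                             families = 5, species = 10))
  rec <- suppressWarnings(recovery_experiment(cfg, 4))
  expect_s3_class(rec, "recovery_report")
  expect_true(is.finite(rec$bias))
  expect_true(is.finite(rec$coverage))
  expect_equal(nrow(rec$per_replicate), 4)
  ## replicate seeds are derived from the master seed: reproducible
  rec2 <- suppressWarnings(recovery_experiment(cfg, 4))
  expect_equal(rec$per_replicate$estimate, rec2$per_replicate$estimate)
})

test_that("an injected covariate effect moves the recovered coefficient", {
  cfg <- generator_config(seed = 37, n_studies = 80,
                          covariate_effects = list(environment = 2))
  ds <- generate_dataset(cfg)
  obs <- apply_conversions(ds$observations)
  pairs <- build_cline_pairs(fit_all_clines(obs))
  sel <- suppressWarnings(model_selection_table(
    pairs, c("environment", "sdi")))
  avg <- model_average(sel)
  est <- avg$estimate[avg$term == "environmentterrestrial"]
  expect_gt(est, 0.5)  # true terrestrial offset is +2
  expect_lt(avg$p[avg$term == "environmentterrestrial"], 0.05)
})
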