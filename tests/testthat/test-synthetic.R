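test_that("generated cohorts have the requested shape and are seed-reproducible", {
  spec <- synthetic_spec(n_samples = 100, n_features = 50, seed = 21)
  co <- generate_cohort(spec)
  expect_equal(dim(co$profile), c(50, 100))
  expect_equal(nrow(co$metadata), 100)
  expect_identical(co$profile$stage, "raw")
  expect_true(all(co$profile$values > 0))

  co2 <- generate_cohort(spec)
  expect_identical(co$profile$values, co2$profile$values)
  expect_identical(co$metadata, co2$metadata)

  co3 <- generate_cohort(synthetic_spec(n_samples = 100, n_features = 50,
                                        seed = 22))
  expect_false(identical(co$profile$values, co3$profile$values))
})

test_that("in the noise- and background-free limit a planted age slope is exact", {
  spec <- synthetic_spec(n_samples = 40, n_features = 5, n_age_linear = 1,
                         beta_age = 0.01, noise_sd = 1e-9,
                         background_mean = 0, background_sd = 0,
                         array_scale_sdlog = 0, baseline_sd = 0,
                         baseline_mean = 3, seed = 8)
  co <- generate_cohort(spec)
  lv <- log10(co$profile$values[1, ])
  expect_equal(unname(lv), 3 + 0.01 * co$metadata$age, tolerance = 1e-6)
  # untouched features stay flat at the baseline
  expect_equal(unname(log10(co$profile$values[3, ])),
               rep(3, 40), tolerance = 1e-6)
})

test_that("ground truth bookkeeping matches the spec and infeasible specs fail", {
  spec <- synthetic_spec(n_samples = 60, n_features = 30, n_age_linear = 4,
                         beta_age = c(0.01, -0.01), n_sex = 3,
                         waves = list(list(center_age = 50, n_features = 5,
                                           step_size = 0.3)),
                         diagnosis_design = list(
                           AD = list(n_samples = 20, n_features = 6,
                                     effect = 0.4)),
                         seed = 4)
  co <- generate_cohort(spec)
  expect_equal(sum(co$truth$age_beta != 0), 4)
  expect_equal(co$truth$age_beta[1:2], c(0.01, -0.01))
  expect_equal(sum(!is.na(co$truth$wave_center)), 5)
  expect_equal(sum(co$truth$diagnosis == "AD", na.rm = TRUE), 6)
  expect_equal(sum(co$truth$sex_beta != 0), 3)
  expect_equal(sum(co$metadata$diagnosis == "AD"), 20)

  expect_error(synthetic_spec(n_features = 10, n_age_linear = 8,
                              waves = list(list(center_age = 50,
                                                n_features = 5,
                                                step_size = 0.3))),
               "infeasible")
  expect_error(synthetic_spec(age_range = c(80, 20)), "min < max")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
})

test_that("planted age slopes are recovered without bias by the association model", {
  set.seed(20)
  betas <- replicate(10, {
    seed <- sample.int(1e6, 1)
    spec <- synthetic_spec(n_samples = 155, n_features = 50,
                           n_age_linear = 5, beta_age = 0.005,
                           noise_sd = 0.1, background_mean = 0,
                           background_sd = 0, array_scale_sdlog = 0,
                           seed = seed)
    co <- generate_cohort(spec)
    pm <- profile_matrix(log10(co$profile$values), stage = "log10")
    tab <- fit_feature_models(pm, co$metadata)
    mean(tab$estimate[tab$term == "age"][1:5])
  })
  expect_lt(abs(mean(betas) - 0.005) / 0.005, 0.1)
})

test_that("with no planted effects the per-term p-values are uniform", {
  spec <- synthetic_spec(n_samples = 155, n_features = 2000, noise_sd = 0.1,
                         background_mean = 0, background_sd = 0,
                         array_scale_sdlog = 0, seed = 314)
  co <- generate_cohort(spec)
  pm <- profile_matrix(log10(co$profile$values), stage = "log10")
  tab <- fit_feature_models(pm, co$metadata)
  for (tm in c("age", "sex")) {
    ks <- suppressWarnings(stats::ks.test(tab$p_value[tab$term == tm],
                                          "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("the template library provides six distinct bounded shapes", {
  lib <- trajectory_template_library(amplitude = 0.4)
  expect_length(lib, 6)
  ages <- seq(19, 79, length.out = 100)
  curves <- vapply(lib, function(f) f(ages), numeric(100))
  expect_true(all(abs(curves) <= 0.4 + 1e-12))
  expect_gt(min(dist(t(curves))), 0.5)  # mutually distinct
})
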