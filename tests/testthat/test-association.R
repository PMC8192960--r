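test_that("a noiseless linear feature is fit exactly", {
  meta <- make_meta(seq(20, 78, length.out = 30))
  y <- 1.0 + 0.02 * meta$age
  pm <- make_log10_profile(rbind(y, y), meta)
  tab <- fit_feature_models(pm, meta)
  age_row <- tab[tab$term == "age" & tab$feature_id == "F0001", ]
  expect_equal(age_row$estimate, 0.02, tolerance = 1e-10)
  expect_equal(age_row$rss, 0, tolerance = 1e-16)
  expect_equal(age_row$eta_squared, 1)
  expect_equal(age_row$p_value, 0)
})

test_that("type-II SS, F and eta^2 match per-feature lm/Anova oracles", {
  set.seed(61)
  meta <- make_meta(runif(40, 20, 80), diagnosis = rep(c("control", "ESPD"),
                                                       each = 20))
  Y <- matrix(rnorm(40 * 6, 3, 0.3), 6, 40)
  Y[1, ] <- Y[1, ] + 0.01 * meta$age
  Y[2, ] <- Y[2, ] + 0.4 * (meta$diagnosis == "ESPD")
  pm <- make_log10_profile(Y, meta)
  tab <- fit_feature_models(pm, meta, terms = c("diagnosis", "age", "sex"))

  male <- as.numeric(meta$sex == "male")
  case <- as.numeric(meta$diagnosis == "ESPD")
  for (f in seq_len(6)) {
    y <- Y[f, ]
    full <- lm(y ~ case + meta$age + male)
    rss_full <- sum(resid(full)^2)
    drops <- list(diagnosis = lm(y ~ meta$age + male),
                  age = lm(y ~ case + male),
                  sex = lm(y ~ case + meta$age))
    for (tm in names(drops)) {
      row <- tab[tab$feature_id == sprintf("F%04d", f) & tab$term == tm, ]
      ss_oracle <- sum(resid(drops[[tm]])^2) - rss_full
      expect_equal(row$ss, ss_oracle, tolerance = 1e-8)
      expect_equal(row$statistic,
                   (ss_oracle / 1) / (rss_full / full$df.residual),
                   tolerance = 1e-8)
      expect_equal(row$eta_squared, ss_oracle / (ss_oracle + rss_full),
                   tolerance = 1e-8)
    }
    # independent route: car's type-II ANOVA on the same fit
    a2 <- car::Anova(lm(y ~ case + age + male,
                        data = data.frame(y = y, case = case,
                                          age = meta$age, male = male)),
                     type = 2)
    got_F <- tab$statistic[tab$feature_id == sprintf("F%04d", f)]
    expect_equal(sort(got_F), sort(a2$`F value`[1:3]), tolerance = 1e-8)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(17)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_equal(q, bh_bruteforce(p), tolerance = 1e-12)
  expect_true(all(q >= p))
  expect_identical(order(q[order(p)]), seq_len(100))  # monotone in p
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("partial eta squared implements its formula", {
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(3, 1), 0.75)
  expect_equal(partial_eta_squared(2, 2), 0.5)
  expect_error(partial_eta_squared(0, 0), "undefined")
  expect_error(partial_eta_squared(-1, 2), "nonnegative")
})

test_that("direction classification splits significant features by slope sign", {
  tab <- data.frame(feature_id = c("a", "b", "c"), term = "age",
                    estimate = c(0.01, -0.01, -0.02),
                    q_value = c(0.01, 0.2, 0.001))
  d <- classify_directions(tab)
  expect_identical(d$increasing, "a")
  expect_identical(d$decreasing, "c")
  expect_error(classify_directions(tab, term = "sex"), "not present")
})

test_that("planted positive and negative age effects are partitioned correctly", {
  spec <- synthetic_spec(n_samples = 120, n_features = 300,
                         n_age_linear = 50,
                         beta_age = c(rep(0.02, 30), rep(-0.02, 20)),
                         noise_sd = 0.1, background_mean = 0,
                         background_sd = 0, array_scale_sdlog = 0,
                         seed = 77)
  co <- generate_cohort(spec)
  pm <- profile_matrix(log10(co$profile$values), stage = "log10")
  tab <- fit_feature_models(pm, co$metadata)
  d <- classify_directions(tab)
  planted_up <- co$truth$feature_id[co$truth$age_beta > 0]
  planted_down <- co$truth$feature_id[co$truth$age_beta < 0]
  expect_true(all(planted_up %in% d$increasing))
  expect_true(all(planted_down %in% d$decreasing))
  # BH controls the FDR at 5%, so a few null features may slip in
  n_extra <- length(d$increasing) + length(d$decreasing) - 50
  expect_lte(n_extra, 5)
})

test_that("rank-deficient designs are rejected with the collinear term named", {
  meta <- make_meta(30:49, sex = "female")
  pm <- make_log10_profile(matrix(rnorm(40), 2, 20), meta)
  expect_error(fit_feature_models(pm, meta), "sex")

  meta2 <- make_meta(30:49)
  expect_error(fit_feature_models(make_log10_profile(matrix(rnorm(40), 2, 20),
                                                     meta2),
                                  meta2, terms = c("diagnosis", "age", "sex")),
               "diagnosis")
})
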