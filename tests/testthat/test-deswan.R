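test_that("parcel assignment follows the half-open window convention", {
  expect_identical(as.character(assign_parcels(c(35, 45, 29), 40)),
                   c("low", "high", "excluded"))
  expect_identical(as.character(assign_parcels(40, 40)), "high")
  expect_identical(as.character(assign_parcels(50, 40)), "high")
  expect_identical(as.character(assign_parcels(50.01, 40)), "excluded")
  expect_true(all(assign_parcels(c(10, 15, 18), 40) == "excluded"))
})

test_that("scan centers span (min age + 10) to (max age - 10)", {
  set.seed(12)
  ages <- c(37, runif(120, 37, 79), 79)
  meta <- make_meta(ages)
  pm <- make_log10_profile(matrix(rnorm(20 * length(ages), 3, 0.1),
                                  20), meta)
  wp <- deswan_scan(pm, meta)
  expect_equal(min(wp$centers), 47)
  expect_equal(max(wp$centers), 69)
  expect_true(all(diff(wp$centers) == 1))
  expect_true(all(wp$n_significant <= 20))
})

test_that("a single window reproduces the two-group linear model exactly", {
  set.seed(71)
  ages <- runif(60, 29, 51)
  meta <- make_meta(ages)
  Y <- matrix(rnorm(60 * 8, 3, 0.2), 8, 60)
  Y[1, ] <- Y[1, ] + 0.5 * (ages >= 40)
  pm <- make_log10_profile(Y, meta)
  wp <- deswan_scan(pm, meta, min_per_parcel = 3)
  i <- which(wp$centers == 40)
  expect_length(i, 1)

  # oracle: the same comparison expressed as a case/control model on the
  # window's samples
  parcel <- assign_parcels(ages, 40)
  keep <- parcel != "excluded"
  meta2 <- meta[keep, , drop = FALSE]
  meta2$diagnosis <- ifelse(parcel[keep] == "high", "AD", "control")
  pm2 <- profile_matrix(pm$values[, keep], stage = "log10")
  tab <- fit_feature_models(pm2, meta2, terms = c("diagnosis", "sex"))
  p_oracle <- tab$p_value[tab$term == "diagnosis"]
  expect_equal(unname(wp$p[, i]), p_oracle, tolerance = 1e-8)
  expect_equal(unname(wp$q[, i]), bh_adjust(p_oracle), tolerance = 1e-8)
  expect_equal(unname(wp$sign[1, i]), 1)
})

test_that("significant counts are invariant to feature and sample order", {
  co <- generate_cohort(synthetic_spec(
    n_samples = 150, n_features = 100, noise_sd = 0.15,
    background_mean = 0, background_sd = 0, array_scale_sdlog = 0,
    waves = list(list(center_age = 50, n_features = 20, step_size = 0.15)),
    seed = 404))
  pm <- profile_matrix(log10(co$profile$values), stage = "log10")
  wp <- deswan_scan(pm, co$metadata)
  set.seed(2)
  fperm <- sample(nrow(pm$values))
  sperm <- sample(ncol(pm$values))
  pm2 <- profile_matrix(pm$values[fperm, sperm], stage = "log10")
  wp2 <- deswan_scan(pm2, co$metadata)
  expect_equal(wp2$n_significant, wp$n_significant)
})

test_that("wave detection picks plateau-aware local maxima and merges near peaks", {
  fake_profile <- function(centers, counts) {
    nf <- max(counts) + 2L
    q <- matrix(1, nf, length(centers))
    for (i in seq_along(centers))
      if (counts[i] > 0) q[seq_len(counts[i]), i] <- 0.001
    structure(list(centers = centers,
                   n_significant = setNames(counts, centers),
                   q = q, sign = matrix(1, nf, length(centers)),
                   q_threshold = 0.05,
                   feature_ids = sprintf("F%03d", seq_len(nf))),
              class = "wave_profile")
  }
  w1 <- detect_waves(fake_profile(30:34, c(0, 0, 5, 0, 0)), min_count = 1)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$peak_age, 32)
  expect_equal(w1[[1]]$n_significant, 5)
  expect_length(w1[[1]]$features, 5)

  w2 <- detect_waves(fake_profile(30:33, c(0, 5, 5, 0)), min_count = 1)
  expect_equal(w2[[1]]$peak_age, 31)  # earlier plateau age

  expect_length(detect_waves(fake_profile(30:34, rep(0, 5))), 0)

  # merging: two maxima 3 years apart keep the larger; tie keeps the earlier
  w3 <- detect_waves(fake_profile(30:42, c(0, 6, 0, 9, 0, 0, 0, 0, 0, 0, 0,
                                           7, 0)),
                     min_separation = 8, min_count = 1)
  expect_equal(vapply(w3, `[[`, numeric(1), "peak_age"), c(33, 41))
  w4 <- detect_waves(fake_profile(30:36, c(0, 6, 0, 0, 0, 6, 0)),
                     min_separation = 8, min_count = 1)
  expect_equal(vapply(w4, `[[`, numeric(1), "peak_age"), 31)

  # peaks below min_count are not waves
  expect_length(detect_waves(fake_profile(30:34, c(0, 0, 3, 0, 0)),
                             min_count = 5), 0)
})

test_that("a planted moderate step is localized by the scan", {
  set.seed(88)
  hits <- replicate(5, {
    co <- generate_cohort(synthetic_spec(
      n_samples = 300, n_features = 1000, noise_sd = 0.15,
      background_mean = 0, background_sd = 0, array_scale_sdlog = 0,
      waves = list(list(center_age = 50, n_features = 100,
                        step_size = 0.12)),
      seed = sample.int(1e6, 1)))
    pm <- profile_matrix(log10(co$profile$values), stage = "log10")
    wp <- deswan_scan(pm, co$metadata)
    waves <- detect_waves(wp)
    length(waves) >= 1 &&
      min(abs(vapply(waves, `[[`, numeric(1), "peak_age") - 50)) <= 2
  })
  expect_gte(sum(hits), 4)
})

test_that("wave overlaps enumerate the Venn regions exactly", {
  ws <- function(age, feats) structure(list(peak_age = age, features = feats,
                                            n_significant = length(feats),
                                            direction = NULL),
                                       class = "wave_set")
  disjoint <- wave_overlap(list(ws(30, c("a", "b")), ws(50, "c")))
  expect_equal(disjoint$total[disjoint$region == "30&50"], 0)
  expect_equal(disjoint$exclusive[disjoint$region == "30"], 2)

  same <- wave_overlap(list(ws(30, c("a", "b")), ws(50, c("a", "b"))))
  expect_equal(same$total[same$region == "30&50"], 2)
  expect_identical(sort(attr(same, "common")), c("a", "b"))

  # constructed three-way truth
  w30 <- c("p", "q", "r", "s")
  w50 <- c("r", "s", "t")
  w62 <- c("s", "t", "u", "v")
  ov <- wave_overlap(list(ws(30, w30), ws(50, w50), ws(62, w62)))
  get <- function(region, col) ov[[col]][ov$region == region]
  expect_equal(get("30", "exclusive"), 2)      # p, q
  expect_equal(get("30&50", "exclusive"), 1)   # r
  expect_equal(get("30&50&62", "exclusive"), 1)  # s
  expect_equal(get("50&62", "exclusive"), 1)   # t
  expect_equal(get("62", "exclusive"), 2)      # u, v
  expect_equal(get("50", "exclusive"), 0)
  expect_equal(get("30&62", "total"), 1)       # s
  expect_identical(attr(ov, "common"), "s")
  expect_error(wave_overlap(list(ws(30, "a"))), "at least 2")
})
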