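#' Specification of a synthetic autoantibody-array cohort
#'
#' Defines a generative model mirroring the structure of real protein-array
#' cohorts: on the log10 scale each feature has a baseline level plus
#' optional linear age effects, sex effects, disease shifts, step "waves"
#' (a level shift for subjects older than a center age), smooth trajectory
#' templates of age, and i.i.d. Gaussian residual noise. The linear signal
#' is exponentiated, multiplied by a per-array log-normal scale factor
#' (so between-array normalization has real work to do), and summed with a
#' zero-truncated normal optical background per spot, yielding raw
#' fluorescence on which the full preprocessing chain can be exercised.
#'
#' Feature blocks are assigned deterministically in id order: age-linear
#' features first, then wave members (one block per wave), then trajectory
#' template members, then disease-affected features; sex effects occupy the
#' last `n_sex` features and may overlap the other blocks.
#'
#' @param n_samples Number of samples (default 155, a typical healthy-cohort
#'   size for this assay).
#' @param age_range Ages are drawn uniformly from this interval (years);
#'   default 19-79.
#' @param sex_proportion Fraction female (default 0.5).
#' @param n_features Number of array features.
#' @param n_age_linear Number of features with a linear age effect.
#' @param beta_age Age slope(s), log10 units per year; recycled to
#'   `n_age_linear`.
#' @param n_sex Number of features with a sex effect.
#' @param beta_sex Sex effect(s) (male minus female, log10 units); recycled.
#' @param diagnosis_design Optional named list: for each non-control
#'   diagnosis, `list(n_samples=, n_features=, effect=)` giving the group
#'   size and the log10 shift applied to its affected features.
#' @param waves List of `list(center_age=, n_features=, step_size=)`: each
#'   wave shifts its features by `step_size` for subjects older than
#'   `center_age`.
#' @param trajectory_templates List of `list(fun=, n_features=, label=)`
#'   where `fun(age)` returns a smooth log10-scale contribution; see
#'   [trajectory_template_library()].
#' @param noise_sd Residual SD on the log10 scale (> 0).
#' @param baseline_mean,baseline_sd Per-feature baseline log10 level
#'   distribution (default around 10^3 fluorescence units).
#' @param background_mean,background_sd Per-spot additive normal background
#'   (truncated at 0), in fluorescence units.
#' @param array_scale_sdlog SD of the log-normal per-array scale factor.
#' @param seed Integer seed; identical spec + seed gives bit-identical data.
#' @return A validated spec list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 155, age_range = c(19, 79),
                           sex_proportion = 0.5, n_features = 1000,
                           n_age_linear = 0, beta_age = 0.005,
                           n_sex = 0, beta_sex = 0.2,
                           diagnosis_design = NULL,
                           waves = list(), trajectory_templates = list(),
                           noise_sd = 0.1,
                           baseline_mean = 3, baseline_sd = 0.3,
                           background_mean = 500, background_sd = 50,
                           array_scale_sdlog = 0.2, seed = 1L) {
  stopifnot(n_samples >= 1, n_features >= 1, length(age_range) == 2)
  if (age_range[1] >= age_range[2]) stop("age_range must satisfy min < max")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (sex_proportion < 0 || sex_proportion > 1)
    stop("sex_proportion must be in [0, 1]")
  for (w in waves)
    stopifnot(is.list(w), all(c("center_age", "n_features", "step_size") %in%
                                names(w)))
  for (tt in trajectory_templates)
    stopifnot(is.list(tt), is.function(tt$fun), tt$n_features >= 1)
  n_wave <- sum(vapply(waves, function(w) w$n_features, numeric(1)))
  n_tmpl <- sum(vapply(trajectory_templates, function(t) t$n_features,
                       numeric(1)))
  n_dis <- if (is.null(diagnosis_design)) 0 else
    sum(vapply(diagnosis_design, function(d) d$n_features, numeric(1)))
  if (n_age_linear + n_wave + n_tmpl + n_dis > n_features)
    stop("infeasible membership counts: age-linear + wave + template + ",
         "disease features exceed n_features")
  if (!is.null(diagnosis_design)) {
    if (is.null(names(diagnosis_design)) || any(names(diagnosis_design) == ""))
      stop("diagnosis_design must be a named list (diagnosis -> design)")
    n_cases <- sum(vapply(diagnosis_design, function(d) d$n_samples,
                          numeric(1)))
    if (n_cases > n_samples)
      stop("diagnosis_design case counts exceed n_samples")
  }
  structure(list(
    n_samples = as.integer(n_samples), age_range = as.numeric(age_range),
    sex_proportion = sex_proportion, n_features = as.integer(n_features),
    n_age_linear = as.integer(n_age_linear), beta_age = beta_age,
    n_sex = as.integer(n_sex), beta_sex = beta_sex,
    diagnosis_design = diagnosis_design, waves = waves,
    trajectory_templates = trajectory_templates, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    background_mean = background_mean, background_sd = background_sd,
    array_scale_sdlog = array_scale_sdlog, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Library of smooth trajectory template shapes
#'
#' Six canonical shapes over an age interval, scaled to a common amplitude
#' on the log10 scale: linear rise, linear fall, two undulating (sinusoidal)
#' shapes in opposite phase, and smooth (logistic) step up / step down at
#' mid-range. Useful as `trajectory_templates` for [synthetic_spec()] when
#' testing trajectory clustering.
#'
#' @param amplitude Peak-to-trough amplitude in log10 units.
#' @param age_range Interval over which shapes are parameterized.
#' @return Named list of functions of age.
#' @export
trajectory_template_library <- function(amplitude = 0.2,
                                        age_range = c(19, 79)) {
  a0 <- age_range[1]; a1 <- age_range[2]
  u <- function(age) (age - a0) / (a1 - a0)  # 0..1
  mid <- (a0 + a1) / 2
  list(
    rising = function(age) amplitude * u(age),
    falling = function(age) amplitude * (1 - u(age)),
    undulating_a = function(age) amplitude / 2 * sin(2 * pi * u(age)),
    undulating_b = function(age) amplitude / 2 * sin(2 * pi * u(age) + pi),
    step_up = function(age) amplitude / (1 + exp(-(age - mid))),
    step_down = function(age) amplitude - amplitude / (1 + exp(-(age - mid)))
  )
}

#' Generate a synthetic raw cohort with known ground truth
#'
#' Draws sample ages, sexes and diagnoses, builds the log10-scale linear
#' signal described by the spec, and returns raw fluorescence
#' `X = background + array_scale * 10^signal` together with the per-feature
#' ground truth needed to assert recovery by every downstream stage.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `profile` (raw [profile_matrix()]),
#'   `metadata` (sample data.frame), `truth` (per-feature effect table) and
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_samples
    nf <- spec$n_features
    sample_id <- sprintf("S%04d", seq_len(n))
    feature_id <- sprintf("F%05d", seq_len(nf))
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    sex <- ifelse(runif(n) < spec$sex_proportion, "female", "male")
    diagnosis <- rep("control", n)
    if (!is.null(spec$diagnosis_design)) {
      pool <- sample.int(n)
      k <- 0L
      for (d in names(spec$diagnosis_design)) {
        nd <- spec$diagnosis_design[[d]]$n_samples
        diagnosis[pool[(k + 1L):(k + nd)]] <- d
        k <- k + nd
      }
    }
    male <- as.numeric(sex == "male")

    truth <- data.frame(
      feature_id = feature_id, age_beta = 0, sex_beta = 0,
      wave_center = NA_real_, wave_step = 0,
      template = NA_character_, diagnosis = NA_character_,
      diagnosis_effect = 0, stringsAsFactors = FALSE
    )
    nxt <- 1L
    take <- function(k) {
      idx <- seq.int(nxt, length.out = k)
      nxt <<- nxt + k
      idx
    }

    intercept <- rnorm(nf, spec$baseline_mean, spec$baseline_sd)
    logS <- matrix(intercept, nf, n)

    if (spec$n_age_linear > 0) {
      idx <- take(spec$n_age_linear)
      b <- rep_len(spec$beta_age, spec$n_age_linear)
      truth$age_beta[idx] <- b
      logS[idx, ] <- logS[idx, , drop = FALSE] + outer(b, age)
    }
    for (w in spec$waves) {
      idx <- take(w$n_features)
      truth$wave_center[idx] <- w$center_age
      truth$wave_step[idx] <- w$step_size
      logS[idx, ] <- logS[idx, , drop = FALSE] +
        w$step_size * matrix(age > w$center_age, length(idx), n, byrow = TRUE)
    }
    for (tt in spec$trajectory_templates) {
      idx <- take(tt$n_features)
      lab <- if (!is.null(tt$label)) tt$label else paste0("template", nxt)
      truth$template[idx] <- lab
      logS[idx, ] <- logS[idx, , drop = FALSE] +
        matrix(tt$fun(age), length(idx), n, byrow = TRUE)
    }
    if (!is.null(spec$diagnosis_design)) {
      for (d in names(spec$diagnosis_design)) {
        dd <- spec$diagnosis_design[[d]]
        idx <- take(dd$n_features)
        truth$diagnosis[idx] <- d
        truth$diagnosis_effect[idx] <- dd$effect
        logS[idx, ] <- logS[idx, , drop = FALSE] +
          dd$effect * matrix(diagnosis == d, length(idx), n, byrow = TRUE)
      }
    }
    if (spec$n_sex > 0) {
      idx <- seq.int(nf - spec$n_sex + 1L, nf)
      b <- rep_len(spec$beta_sex, spec$n_sex)
      truth$sex_beta[idx] <- b
      logS[idx, ] <- logS[idx, , drop = FALSE] + outer(b, male)
    }

    logS <- logS + matrix(rnorm(nf * n, 0, spec$noise_sd), nf, n)
    scale <- exp(rnorm(n, 0, spec$array_scale_sdlog))
    signal <- 10^logS * matrix(scale, nf, n, byrow = TRUE)
    background <-
      if (spec$background_mean > 0 || spec$background_sd > 0)
        pmax(matrix(rnorm(nf * n, spec$background_mean, spec$background_sd),
                    nf, n), 0)
      else matrix(0, nf, n)
    values <- background + signal
    dimnames(values) <- list(feature_id, sample_id)

    list(
      profile = profile_matrix(values, stage = "raw"),
      metadata = data.frame(sample_id = sample_id, age = age, sex = sex,
                            diagnosis = diagnosis, stringsAsFactors = FALSE),
      truth = truth,
      spec = spec
    )
  })
}
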