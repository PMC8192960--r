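#' Assign samples to sliding-window parcels
#'
#' For a window of width `window` centered at age `center`, the low parcel
#' is the half-open interval `[center - window/2, center)` and the high
#' parcel the closed interval `[center, center + window/2]`; a subject
#' exactly at the center age falls in the high parcel. Ages outside the
#' window are excluded.
#'
#' @param ages Numeric vector of ages.
#' @param center Window center age.
#' @param window Window width in years (two parcels of `window/2`).
#' @return Factor with levels `low`, `high`, `excluded`.
#' @export
assign_parcels <- function(ages, center, window = 20) {
  half <- window / 2
  lab <- ifelse(ages >= center - half & ages < center, "low",
         ifelse(ages >= center & ages <= center + half, "high", "excluded"))
  factor(lab, levels = c("low", "high", "excluded"))
}

#' Sliding-window differential expression scan (DE-SWAN)
#'
#' Slides a 20-year window in 1-year steps across the age range. At each
#' center age, age is binarized into the two 10-year parcels and every
#' feature is tested with the covariate-adjusted linear model
#' `level ~ binarized_age + sex`; the binarized-age p-values are
#' Benjamini-Hochberg adjusted across features within the window (or across
#' all windows jointly with `adjust = "global"`, for sensitivity analysis),
#' and the number of features with q below the threshold is recorded per
#' center. Windows where either parcel has fewer than `min_per_parcel`
#' samples are skipped, not padded. A covariate that is constant within a
#' window (e.g. a single-sex window) is dropped for that window.
#'
#' @param pm A [profile_matrix()] at stage `"log10"`.
#' @param meta Sample metadata covering the matrix columns.
#' @param window Window width in years (default 20; parcels of width
#'   `window/2`).
#' @param step Slide increment in years (default 1).
#' @param q_threshold Per-window significance threshold (default 0.05).
#' @param min_per_parcel Minimum samples per parcel (default 5; must be
#'   >= 3).
#' @param adjust BH scope: `"within_window"` (default) or `"global"`.
#' @return An object of class `wave_profile`: list with `centers`,
#'   `n_significant`, matrices `p`, `q` and `sign` (features x centers; the
#'   sign of the binarized-age coefficient), `n_low`, `n_high`,
#'   `q_threshold` and `feature_ids`.
#' @export
deswan_scan <- function(pm, meta, window = 20, step = 1, q_threshold = 0.05,
                        min_per_parcel = 5,
                        adjust = c("within_window", "global")) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (pm$stage != "log10")
    stop("deswan_scan expects log10-stage values, got stage '", pm$stage, "'")
  adjust <- match.arg(adjust)
  if (min_per_parcel < 3) stop("min_per_parcel must be at least 3")
  meta <- .align_metadata(pm, meta)
  half <- window / 2
  if (diff(range(meta$age)) < window)
    stop("age span is narrower than the window")
  centers <- seq(ceiling(min(meta$age) + half), floor(max(meta$age) - half),
                 by = step)
  nf <- nrow(pm$values)
  p_mat <- sign_mat <- matrix(NA_real_, nf, length(centers),
                              dimnames = list(feature_ids(pm), centers))
  n_low <- n_high <- integer(length(centers))
  male_all <- as.numeric(meta$sex == "male")
  Yt <- t(pm$values)
  for (i in seq_along(centers)) {
    parcel <- assign_parcels(meta$age, centers[i], window)
    keep <- parcel != "excluded"
    n_low[i] <- sum(parcel == "low")
    n_high[i] <- sum(parcel == "high")
    if (n_low[i] < min_per_parcel || n_high[i] < min_per_parcel) next
    high <- as.numeric(parcel[keep] == "high")
    X <- cbind(`(Intercept)` = 1, agelowhigh = high, sex = male_all[keep])
    # drop covariates constant within this window (never the tested term)
    const <- apply(X, 2, function(v) length(unique(v)) == 1L)
    const["(Intercept)"] <- FALSE
    if (const["agelowhigh"]) next
    X <- X[, !const, drop = FALSE]
    Y <- Yt[keep, , drop = FALSE]
    qr_full <- qr(X)
    if (qr_full$rank < ncol(X)) next
    yty <- colSums(Y^2)
    rss_full <- pmax(yty - colSums(qr.qty(qr_full, Y)[seq_len(qr_full$rank), ,
                                                      drop = FALSE]^2), 0)
    qr_red <- qr(X[, colnames(X) != "agelowhigh", drop = FALSE])
    rss_red <- pmax(yty - colSums(qr.qty(qr_red, Y)[seq_len(qr_red$rank), ,
                                                    drop = FALSE]^2), 0)
    df_err <- nrow(Y) - qr_full$rank
    Fst <- pmax(rss_red - rss_full, 0) / (rss_full / df_err)
    pv <- pf(Fst, 1, df_err, lower.tail = FALSE)
    pv[!is.finite(Fst)] <- 0
    p_mat[, i] <- pv
    sign_mat[, i] <- sign(qr.coef(qr_full, Y)["agelowhigh", ])
  }
  valid <- colSums(!is.na(p_mat)) > 0
  if (!any(valid))
    stop("no window has ", min_per_parcel, " samples in both parcels")
  centers <- centers[valid]
  p_mat <- p_mat[, valid, drop = FALSE]
  sign_mat <- sign_mat[, valid, drop = FALSE]
  n_low <- n_low[valid]
  n_high <- n_high[valid]
  q_mat <- if (adjust == "within_window") {
    apply(p_mat, 2, bh_adjust)
  } else {
    matrix(bh_adjust(as.vector(p_mat)), nrow(p_mat), ncol(p_mat))
  }
  dimnames(q_mat) <- dimnames(p_mat)
  structure(list(
    centers = centers,
    n_significant = setNames(colSums(q_mat < q_threshold), centers),
    p = p_mat, q = q_mat, sign = sign_mat,
    n_low = n_low, n_high = n_high,
    q_threshold = q_threshold, feature_ids = feature_ids(pm),
    adjust = adjust
  ), class = "wave_profile")
}

#' @export
print.wave_profile <- function(x, ...) {
  cat(sprintf("<wave_profile> %d centers (%d..%d), %d features, q < %g (%s BH)\n",
              length(x$centers), min(x$centers), max(x$centers),
              length(x$feature_ids), x$q_threshold, x$adjust))
  print(x$n_significant)
  invisible(x)
}

#' Identify waves as peaks of the significant-feature count profile
#'
#' A wave is a local maximum of the number of significant features versus
#' window center age. A maximal run of equal counts that exceeds both of
#' its neighbors counts as a single peak, located at the floor of the run's
#' midpoint (so a two-center plateau reports the earlier age). Peaks with
#' fewer than `min_count` significant features are discarded (isolated
#' false discoveries in otherwise-null windows do not constitute a wave),
#' and peaks closer together than `min_separation` years are merged,
#' keeping the larger count (ties: the earlier age).
#'
#' @param profile A [deswan_scan()] result.
#' @param min_separation Minimum distance between peaks in years
#'   (default 8).
#' @param min_count Minimum significant-feature count for a peak
#'   (default 5).
#' @return A list of `wave_set` objects, ordered by peak age: each has
#'   `peak_age`, `n_significant`, `features` (ids significant at the peak
#'   center) and `direction` (named +1/-1 by sign of the binarized-age
#'   coefficient). Empty list if no center has a significant feature.
#' @export
detect_waves <- function(profile, min_separation = 8, min_count = 5) {
  stopifnot(inherits(profile, "wave_profile"))
  counts <- as.integer(profile$n_significant)
  centers <- profile$centers
  if (all(counts == 0)) return(list())
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_idx <- integer(0)
  for (i in seq_along(r$values)) {
    left <- if (i > 1L) r$values[i - 1L] else -Inf
    right <- if (i < length(r$values)) r$values[i + 1L] else -Inf
    if (r$values[i] > left && r$values[i] > right && r$values[i] > 0)
      cand_idx <- c(cand_idx, (starts[i] + ends[i]) %/% 2L)
  }
  cand_age <- centers[cand_idx]
  cand_cnt <- counts[cand_idx]
  ok <- cand_cnt >= min_count
  cand_idx <- cand_idx[ok]; cand_age <- cand_age[ok]; cand_cnt <- cand_cnt[ok]
  if (!length(cand_idx)) return(list())
  ord <- order(-cand_cnt, cand_age)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(cand_age[j] - cand_age[kept]) >= min_separation))
      kept <- c(kept, j)
  }
  kept <- kept[order(cand_age[kept])]
  lapply(kept, function(j) {
    i <- cand_idx[j]
    sig <- which(profile$q[, i] < profile$q_threshold)
    structure(list(
      peak_age = cand_age[j],
      n_significant = cand_cnt[j],
      features = profile$feature_ids[sig],
      direction = setNames(profile$sign[sig, i], profile$feature_ids[sig])
    ), class = "wave_set")
  })
}

#' @export
print.wave_set <- function(x, ...) {
  cat(sprintf("<wave_set> peak at age %g: %d significant features (%d up, %d down)\n",
              x$peak_age, x$n_significant, sum(x$direction > 0),
              sum(x$direction < 0)))
  invisible(x)
}

#' Overlaps among wave feature sets
#'
#' Computes every exclusive region of the intersection lattice (the Venn
#' counts) of the waves' significant-feature sets.
#'
#' @param waves A list of `wave_set` objects (at least 2), as returned by
#'   [detect_waves()].
#' @return A `data.frame` with one row per nontrivial wave combination:
#'   `region` (peak ages joined by `&`), `exclusive` (features in exactly
#'   that combination) and `total` (features shared by all waves of the
#'   combination, regardless of the others). Features common to all waves
#'   are in `attr(, "common")`.
#' @export
wave_overlap <- function(waves) {
  if (length(waves) < 2L) stop("need at least 2 waves")
  sets <- lapply(waves, function(w) w$features)
  labels <- vapply(waves, function(w) as.character(w$peak_age), character(1))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    inc <- as.logical(combos[i, ])
    excl <- sum(apply(member, 1, function(row) all(row == inc)))
    tot <- sum(apply(member[, inc, drop = FALSE], 1, all))
    data.frame(region = paste(labels[inc], collapse = "&"),
               exclusive = excl, total = tot, stringsAsFactors = FALSE)
  }))
  attr(out, "common") <- universe[apply(member, 1, all)]
  out
}
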