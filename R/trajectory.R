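#' Smooth per-feature trajectories of z-scored levels over age
#'
#' Each feature is z-scored across samples (mean 0, SD 1) and fitted with a
#' LOESS regression of z-score on age (local quadratic fits with tricube
#' weights), then evaluated on a uniform age grid spanning the observed age
#' range. A common grid gives every feature identical support, so Euclidean
#' distances between trajectories are well defined.
#'
#' @param pm A [profile_matrix()] at stage `"log10"`.
#' @param meta Sample metadata covering the matrix columns.
#' @param span LOESS smoothing fraction in (0, 1]; default 0.75.
#' @param grid_size Number of grid ages; default 50.
#' @return An object of class `trajectory_set`: list with `age_grid`,
#'   `fitted` (feature x grid matrix), `zscores` (feature x sample matrix),
#'   `ages`, `span`, and `excluded` (ids of constant features, dropped
#'   with a warning).
#' @export
fit_trajectories <- function(pm, meta, span = 0.75, grid_size = 50) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  meta <- .align_metadata(pm, meta)
  if (length(unique(meta$age)) < 10)
    stop("need at least 10 distinct ages to fit trajectories")
  m <- pm$values
  sds <- apply(m, 1, sd)
  excluded <- rownames(m)[sds == 0]
  if (length(excluded)) {
    warning("excluding ", length(excluded), " constant feature(s): ",
            paste(head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(m) == 0L) stop("no non-constant features to fit")
  z <- (m - rowMeans(m)) / sds
  age <- meta$age
  grid <- seq(min(age), max(age), length.out = grid_size)
  fitted <- t(apply(z, 1, function(zi) {
    fit <- loess(zi ~ age, span = span, degree = 2,
                 control = loess.control(surface = "direct"))
    predict(fit, newdata = data.frame(age = grid))
  }))
  dimnames(fitted) <- list(rownames(z), NULL)
  stopifnot(all(is.finite(fitted)))
  structure(list(age_grid = grid, fitted = fitted, zscores = z, ages = age,
                 span = span, excluded = excluded),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d features on a %d-point age grid [%.1f, %.1f], span %.2f\n",
              nrow(x$fitted), length(x$age_grid), min(x$age_grid),
              max(x$age_grid), x$span))
  invisible(x)
}

#' Cluster trajectories by complete-linkage hierarchical clustering
#'
#' Pairwise Euclidean distances between trajectories (by default the
#' LOESS-fitted grid curves; optionally the raw z-score vectors), an
#' agglomerative complete-linkage dendrogram, and a cut into `k` clusters.
#' Cluster labels are assigned in order of first appearance in the feature
#' list, so the labeling is deterministic; equal-height merges are resolved
#' by the agglomeration order (lower index first).
#'
#' @param ts A [fit_trajectories()] result.
#' @param k Number of clusters (>= 2); default 6.
#' @param on Cluster the `"fitted"` grid curves (default) or the raw
#'   `"zscores"`.
#' @return An object of class `trajectory_clusters`: list with
#'   `assignment` (named integer vector, labels 1..k), `k`, `means`
#'   (k x grid matrix of per-cluster mean trajectories), `hclust`, and the
#'   distance/linkage used.
#' @export
cluster_trajectories <- function(ts, k = 6, on = c("fitted", "zscores")) {
  stopifnot(inherits(ts, "trajectory_set"))
  on <- match.arg(on)
  m <- ts[[on]]
  if (k < 2) stop("k must be at least 2")
  if (nrow(m) < k) stop("need at least k = ", k, " features to cluster")
  h <- hclust(dist(m), method = "complete")
  assignment <- cutree(h, k = k)
  stopifnot(all(tabulate(assignment, k) > 0))
  means <- t(vapply(seq_len(k), function(cl)
    colMeans(ts$fitted[assignment == cl, , drop = FALSE]),
    numeric(ncol(ts$fitted))))
  structure(list(assignment = assignment, k = k, means = means, hclust = h,
                 distance = "euclidean", linkage = "complete", on = on),
            class = "trajectory_clusters")
}

#' @export
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf("<trajectory_clusters> k = %d (%s linkage, %s distance)\n",
              x$k, x$linkage, x$distance))
  print(table(cluster = x$assignment))
  invisible(x)
}
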