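#' Normexp background correction, one array at a time
#'
#' Fits the normal + exponential convolution model to each array: observed
#' intensity X = B + S with background B ~ Normal(mu, sigma^2) and signal
#' S ~ Exponential(mean alpha), estimated by saddle-point-approximated
#' maximum likelihood (via limma, the reference implementation for this
#' model). Each observation is replaced by the posterior mean
#' E\[S | X = x\] = mu.sx + sigma^2 * phi(mu.sx/sigma) / Phi(mu.sx/sigma)
#' with mu.sx = x - mu - sigma^2/alpha, which is strictly positive and
#' strictly increasing in x. If the likelihood fit fails for an array, a
#' method-of-moments estimator (matching mean, variance and third central
#' moment of the convolution) is used instead, with a warning.
#'
#' @param pm A raw-stage [profile_matrix()]; each column needs at least 50
#'   finite values for a stable fit.
#' @return The corrected [profile_matrix()] at stage `"bg_corrected"`, with
#'   a per-array parameter table (`mu`, `sigma`, `alpha`, `converged`) in
#'   `attr(, "normexp_params")`.
#' @export
normexp_background_correct <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (pm$stage != "raw")
    stop("normexp background correction expects stage 'raw', got '",
         pm$stage, "'")
  m <- pm$values
  if (nrow(m) < 50)
    stop("need at least 50 values per array to fit the background model")
  out <- m
  params <- data.frame(sample_id = colnames(m), mu = NA_real_,
                       sigma = NA_real_, alpha = NA_real_, converged = NA,
                       stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    if (sd(x) == 0)
      stop("degenerate (constant) array: ", colnames(m)[j])
    par <- tryCatch(
      list(p = limma::normexp.fit(x, method = "saddle")$par, ok = TRUE),
      error = function(e) NULL)
    if (is.null(par)) {
      warning("normexp likelihood fit failed for array '", colnames(m)[j],
              "'; falling back to moment estimation")
      par <- list(p = .normexp_moments(x), ok = FALSE)
    }
    out[, j] <- limma::normexp.signal(par$p, x)
    params$mu[j] <- par$p[1]
    params$sigma[j] <- exp(par$p[2])
    params$alpha[j] <- exp(par$p[3])
    params$converged[j] <- par$ok
  }
  res <- .advance_stage(profile_matrix(out, stage = "raw"), "bg_corrected")
  attr(res, "normexp_params") <- params
  res
}

# Moment estimator for the normal+exponential convolution:
# E X = mu + alpha, Var X = sigma^2 + alpha^2, E (X - EX)^3 = 2 alpha^3.
# Returns the (mu, log sigma, log alpha) parameterization used by the
# signal formula.
.normexp_moments <- function(x) {
  m1 <- mean(x)
  m2 <- var(x)
  m3 <- mean((x - m1)^3)
  alpha <- (max(m3, .Machine$double.eps) / 2)^(1 / 3)
  sigma2 <- m2 - alpha^2
  if (sigma2 <= 0) {
    alpha <- sqrt(m2 / 2)
    sigma2 <- m2 / 2
  }
  c(m1 - alpha, log(sqrt(sigma2)), log(alpha))
}

#' Posterior expected signal under the normexp model
#'
#' Evaluates E\[S | X = x\] for given background mean `mu`, background SD
#' `sigma` and exponential signal mean `alpha` — the value substituted for
#' each observation by [normexp_background_correct()].
#'
#' @param x Numeric vector of observed intensities.
#' @param mu,sigma,alpha Model parameters (`sigma > 0`, `alpha > 0`).
#' @return Numeric vector of strictly positive corrected intensities.
#' @export
normexp_signal <- function(x, mu, sigma, alpha) {
  stopifnot(sigma > 0, alpha > 0)
  limma::normexp.signal(c(mu, log(sigma), log(alpha)), x)
}

#' Quantile normalization across arrays
#'
#' Forces every column to share the same empirical distribution: for each
#' rank the reference value is the mean across columns of the columns'
#' order statistics, and each value is replaced by the reference value at
#' its within-column rank. Ties within a column receive the average of
#' their tied ranks' reference values (the limma dialect; dialects differ
#' on ties, so this choice is documented). Within-column rank order is
#' preserved exactly.
#'
#' @param pm A [profile_matrix()] at stage `"raw"` or `"bg_corrected"`.
#' @return The normalized [profile_matrix()] at stage
#'   `"quantile_normalized"`.
#' @export
quantile_normalize <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!pm$stage %in% c("raw", "bg_corrected"))
    stop("quantile normalization expects stage 'raw' or 'bg_corrected', got '",
         pm$stage, "'")
  m <- pm$values
  if (ncol(m) == 1L) {
    warning("single-column matrix: quantile normalization is a no-op")
    out <- m
  } else {
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
  }
  if (pm$stage == "raw")  # allow normalization without background correction
    pm <- .advance_stage(pm, "bg_corrected")
  pm$values <- out
  .advance_stage(pm, "quantile_normalized")
}

#' The full preprocessing chain: normexp, quantile, log10
#'
#' Reproduces the standard protein-array normalization sequence: per-array
#' normexp background correction, between-array quantile normalization, and
#' a log10 transform. Normexp output is strictly positive, so the log is
#' always defined; this is asserted.
#'
#' @param pm A raw-stage [profile_matrix()].
#' @return A [profile_matrix()] at stage `"log10"` with finite values; the
#'   per-array background parameters are carried in
#'   `attr(, "normexp_params")`.
#' @export
preprocess_pipeline <- function(pm) {
  bg <- normexp_background_correct(pm)
  qn <- quantile_normalize(bg)
  if (any(qn$values <= 0))
    stop("nonpositive value reached the log10 step; background correction ",
         "should have prevented this")
  out <- .advance_stage(qn, "log10")
  out$values <- log10(qn$values)
  stopifnot(all(is.finite(out$values)))
  attr(out, "normexp_params") <- attr(bg, "normexp_params")
  out
}
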