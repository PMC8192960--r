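# Shared fixtures and small oracles, all built in code at test time.

# Minimal metadata table.
make_meta <- function(ages, sex = NULL, diagnosis = "control",
                      prefix = "S") {
  n <- length(ages)
  if (is.null(sex)) sex <- rep(c("female", "male"), length.out = n)
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             age = ages, sex = rep_len(sex, n),
             diagnosis = rep_len(diagnosis, n), stringsAsFactors = FALSE)
}

# A log10-stage profile matrix from a plain numeric matrix.
make_log10_profile <- function(values, meta) {
  dimnames(values) <- list(sprintf("F%04d", seq_len(nrow(values))),
                           meta$sample_id)
  profile_matrix(values, stage = "log10")
}

# Adjusted Rand index between two labelings (independent implementation
# used as the clustering-recovery yardstick).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

# Quadrature oracle for the normexp posterior mean E[S | X = x]: direct
# numerical integration of s * f(s | x) over the positive axis. The
# integration range is split at the posterior peak so the adaptive rule
# cannot overlook a narrow mode far from the boundaries.
normexp_posterior_mean_quadrature <- function(x, mu, sigma, alpha) {
  dens <- function(s) stats::dnorm(x - s, mu, sigma) * stats::dexp(s, 1 / alpha)
  upper <- max(x - mu, 0) + 12 * sigma + 12 * alpha
  peak <- min(max(x - mu, 0), upper)
  pts <- sort(unique(pmin(pmax(c(0, peak - 6 * sigma, peak + 6 * sigma,
                                 upper), 0), upper)))
  piecewise <- function(f) sum(vapply(seq_len(length(pts) - 1L), function(i)
    stats::integrate(f, pts[i], pts[i + 1L], rel.tol = 1e-12,
                     subdivisions = 1000L)$value, numeric(1)))
  piecewise(function(s) s * dens(s)) / piecewise(dens)
}

# Definitional Benjamini-Hochberg oracle: q_(i) = min_{j >= i} p_(j) m / j.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(sort(p)[i:m] * m / (i:m))), numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
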