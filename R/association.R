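#' Per-feature covariate-adjusted linear models
#'
#' Fits, for every feature, the ordinary least squares model
#' `level ~ age + sex` (aging signature) or
#' `level ~ diagnosis + age + sex` (disease signature), and reports per term:
#' the coefficient, the type-II sum of squares (the residual-SS difference
#' between the full model and the model omitting that term — the two
#' coincide for additive models), the per-term F statistic
#' `(SS_term/df_term) / (SS_error/df_error)`, its p-value, the
#' Benjamini-Hochberg q-value computed across features within each term,
#' and partial eta squared `SS_term / (SS_term + SS_error)`.
#'
#' Covariates are coded as in all of the package's design matrices:
#' sex female = 0, male = 1; diagnosis control = 0, case = 1.
#'
#' @param pm A [profile_matrix()] at stage `"log10"` (or any matrix of
#'   modeling-ready values constructed at that stage).
#' @param meta Sample metadata covering the matrix columns.
#' @param terms Model terms, an ordered subset of
#'   `c("diagnosis", "age", "sex")`.
#' @return A long-format `data.frame` (class `association_table`) with one
#'   row per feature x term: `feature_id`, `term`, `estimate`, `ss`, `df`,
#'   `statistic`, `p_value`, `q_value`, `eta_squared`, `rss`,
#'   `df_residual`.
#' @export
fit_feature_models <- function(pm, meta, terms = c("age", "sex")) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (pm$stage != "log10")
    stop("association models expect log10-stage values, got stage '",
         pm$stage, "'")
  terms <- match.arg(terms, c("diagnosis", "age", "sex"), several.ok = TRUE)
  meta <- .align_metadata(pm, meta)
  n <- nrow(meta)
  if (n < length(terms) + 2L)
    stop("need at least ", length(terms) + 2L, " samples to fit ",
         length(terms), " terms")
  Y <- t(pm$values)  # samples x features
  fit <- .fit_term_models(Y, meta, terms)
  tab <- do.call(rbind, lapply(terms, function(tm) {
    data.frame(
      feature_id = feature_ids(pm), term = tm,
      estimate = fit$estimate[, tm], ss = fit$ss[, tm], df = fit$df[[tm]],
      statistic = fit$statistic[, tm], p_value = fit$p[, tm],
      q_value = bh_adjust(fit$p[, tm]),
      eta_squared = fit$eta[, tm],
      rss = fit$rss, df_residual = fit$df_residual,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
  class(tab) <- c("association_table", "data.frame")
  attr(tab, "terms") <- terms
  tab
}

# Build the design matrix for the given terms, with column grouping.
.build_design <- function(meta, terms) {
  n <- nrow(meta)
  cols <- list(`(Intercept)` = rep(1, n))
  group <- "(Intercept)"
  for (tm in terms) {
    v <- switch(tm,
      age = meta$age,
      sex = {
        if (length(unique(meta$sex)) < 2L)
          stop("collinear term 'sex': only one sex present in the cohort")
        as.numeric(meta$sex == "male")
      },
      diagnosis = {
        if (is.null(meta$diagnosis))
          stop("metadata lacks a 'diagnosis' column")
        case <- unique(meta$diagnosis[meta$diagnosis != "control"])
        if (length(case) == 0L)
          stop("collinear term 'diagnosis': no case samples present")
        if (length(case) > 1L)
          stop("more than one non-control diagnosis present (",
               paste(case, collapse = ", "),
               "); analyze one disease against its matched controls")
        as.numeric(meta$diagnosis != "control")
      })
    cols[[tm]] <- v
    group <- c(group, tm)
  }
  X <- do.call(cbind, cols)
  list(X = X, group = group)
}

# Vectorized OLS across features sharing one design. Type-II SS per term is
# computed by the nested-model definition: refit without the term's columns
# and difference the residual sums of squares.
.fit_term_models <- function(Y, meta, terms) {
  d <- .build_design(meta, terms)
  X <- d$X
  qr_full <- qr(X)
  if (qr_full$rank < ncol(X)) {
    drop_col <- d$group[qr_full$pivot[(qr_full$rank + 1L):ncol(X)]]
    stop("rank-deficient design: collinear term(s) ",
         paste(unique(drop_col), collapse = ", "))
  }
  yty <- colSums(Y^2)
  rss_of <- function(qrx) pmax(yty - colSums(qr.qty(qrx, Y)[seq_len(qrx$rank), ,
                                                            drop = FALSE]^2), 0)
  rss_full <- rss_of(qr_full)
  beta <- qr.coef(qr_full, Y)  # p x features
  df_residual <- nrow(Y) - qr_full$rank

  nf <- ncol(Y)
  est <- ss <- stat <- p <- eta <- matrix(
    NA_real_, nf, length(terms), dimnames = list(NULL, terms))
  dfs <- setNames(vector("list", length(terms)), terms)
  for (tm in terms) {
    keep <- d$group != tm
    qr_red <- qr(X[, keep, drop = FALSE])
    ss_t <- pmax(rss_of(qr_red) - rss_full, 0)
    df_t <- sum(!keep)
    F_t <- (ss_t / df_t) / (rss_full / df_residual)
    est[, tm] <- beta[which(d$group == tm)[1L], ]
    ss[, tm] <- ss_t
    stat[, tm] <- F_t
    p[, tm] <- pf(F_t, df_t, df_residual, lower.tail = FALSE)
    denom <- ss_t + rss_full
    eta[, tm] <- ifelse(denom > 0, ss_t / denom, NA_real_)
    dfs[[tm]] <- df_t
  }
  # exact-fit limit: zero residual SS makes F infinite and p exactly 0
  p[!is.finite(stat)] <- 0
  list(estimate = est, ss = ss, statistic = stat, p = p, eta = eta,
       df = dfs, rss = rss_full, df_residual = df_residual)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1 and mapped back to the
#' input order. Monotone in p.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must be numeric, non-missing and in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Partial eta squared of a model term
#'
#' The share of variance explained by a term relative to the term plus the
#' model's error: `ss_effect / (ss_effect + ss_error)`.
#'
#' @param ss_effect,ss_error Nonnegative sums of squares (vectorized).
#' @return Values in \[0, 1\].
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0))
    stop("sums of squares must be nonnegative")
  if (any(ss_effect + ss_error == 0))
    stop("partial eta squared undefined when both sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}

#' Split significant features by direction of change
#'
#' Partitions the features significant for a term (q below threshold) into
#' those whose levels increase with the term and those that decrease, by
#' the sign of the fitted coefficient. A coefficient of exactly zero cannot
#' be significant but is classified as increasing by convention.
#'
#' @param table An [fit_feature_models()] result.
#' @param term Term to partition on (default `"age"`).
#' @param q_threshold Significance threshold on the q-value.
#' @return A list with character vectors `increasing` and `decreasing`.
#' @export
classify_directions <- function(table, term = "age", q_threshold = 0.05) {
  if (!term %in% table$term)
    stop("term '", term, "' not present in the association table")
  sub <- table[table$term == term & table$q_value < q_threshold, , drop = FALSE]
  list(increasing = sub$feature_id[sub$estimate >= 0],
       decreasing = sub$feature_id[sub$estimate < 0])
}
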