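#' Fisher's exact over-representation test against the array background
#'
#' For each annotation term, builds the 2x2 table of hit/non-hit by
#' in-term/not-in-term over the array background and tests enrichment with
#' a one-sided (greater) Fisher's exact test, whose p-value equals the
#' hypergeometric upper-tail probability for the table's margins. Term
#' members are intersected with the background before testing; terms with
#' no background member are skipped. P-values are Benjamini-Hochberg
#' adjusted across the tested terms. Up- and down-regulated hit sets should
#' be tested separately.
#'
#' @param hits Character vector of significant feature ids (must be a
#'   subset of `background`; nonempty).
#' @param background Character vector of all feature ids on the array.
#' @param sets Named list of term member vectors, e.g. from [read_gmt()].
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A `data.frame` with one row per tested term: counts
#'   (`n_hits_in_term`, `n_hits`, `n_term_background`, `n_background`),
#'   `odds_ratio` (conditional MLE), `p_value`, `q_value`, ordered by
#'   p-value.
#' @export
fisher_enrichment <- function(hits, background, sets,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  hits <- unique(as.character(hits))
  background <- unique(as.character(background))
  if (length(hits) == 0L) stop("empty hit set")
  extra <- setdiff(hits, background)
  if (length(extra))
    stop("hits must be a subset of the background; offending id(s): ",
         paste(head(extra, 5), collapse = ", "))
  rows <- lapply(names(sets), function(term) {
    members <- intersect(unique(as.character(sets[[term]])), background)
    if (length(members) == 0L) return(NULL)
    a <- length(intersect(hits, members))           # hits in term
    b <- length(hits) - a                            # hits not in term
    c_ <- length(members) - a                        # non-hit background in term
    d <- length(background) - length(hits) - c_      # non-hit, not in term
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, 2), alternative = alternative)
    data.frame(term = term,
               n_hits_in_term = a, n_hits = length(hits),
               n_term_background = length(members),
               n_background = length(background),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no annotation term overlaps the background")
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  desc <- attr(sets, "description")
  if (!is.null(desc)) out$description <- unname(desc[out$term])
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
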