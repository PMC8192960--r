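#' Feature-by-sample reactivity matrix with a processing-stage tag
#'
#' The central container of the package: a dense numeric matrix of
#' autoantibody reactivities (features in rows, samples/arrays in columns)
#' together with the preprocessing stage of its values. Stages advance only
#' in the order `raw` -> `bg_corrected` -> `quantile_normalized` -> `log10`;
#' [normexp_background_correct()], [quantile_normalize()] and
#' [preprocess_pipeline()] enforce the transitions.
#'
#' Missing values are not supported: protein-array exports are complete, and
#' every downstream model assumes a full matrix, so construction rejects
#' non-finite values rather than imputing.
#'
#' @param values Numeric matrix with unique row names (feature ids) and
#'   unique column names (sample ids).
#' @param stage Processing stage of `values`; one of `"raw"`,
#'   `"bg_corrected"`, `"quantile_normalized"`, `"log10"`.
#' @return An object of class `profile_matrix`.
#' @examples
#' m <- matrix(rexp(6, 1 / 1000), 3, 2,
#'             dimnames = list(paste0("F", 1:3), c("S1", "S2")))
#' pm <- profile_matrix(m, stage = "raw")
#' dim(pm)
#' @export
profile_matrix <- function(values, stage = "raw") {
  stage <- match.arg(stage, .STAGES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids as rownames and sample ids as colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)))
    stop("profile matrix contains missing or non-finite values; ",
         "missing reactivities are not supported")
  structure(list(values = values, stage = stage), class = "profile_matrix")
}

#' @export
dim.profile_matrix <- function(x) dim(x$values)

#' @export
as.matrix.profile_matrix <- function(x, ...) x$values

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d features x %d samples, stage '%s'\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' Feature and sample identifiers of a profile matrix
#' @param x A [profile_matrix()].
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# Move a profile matrix to the next stage, enforcing the allowed order.
.advance_stage <- function(pm, new_stage) {
  from <- match(pm$stage, .STAGES)
  to <- match(new_stage, .STAGES)
  if (is.na(to) || to != from + 1L)
    stop(sprintf("invalid stage transition '%s' -> '%s'", pm$stage, new_stage))
  pm$stage <- new_stage
  pm
}

# Check that metadata covers the matrix columns, and return metadata rows
# reordered to the column order of `pm`.
.align_metadata <- function(pm, meta) {
  .check_metadata(meta)
  idx <- match(sample_ids(pm), meta$sample_id)
  if (anyNA(idx))
    stop("metadata is missing sample(s): ",
         paste(sample_ids(pm)[is.na(idx)], collapse = ", "))
  meta[idx, , drop = FALSE]
}
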