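#' Read a feature-by-sample reactivity table
#'
#' Reads a delimited text file with one header row and one identifier column
#' into a raw-stage [profile_matrix()]. The file may hold features in rows
#' (default: header = sample ids, first column = feature ids) or samples in
#' rows (`orientation = "samples_in_rows"`); either way the result is
#' features x samples.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return A [profile_matrix()] at stage `"raw"`.
#' @export
read_profile_table <- function(path,
                               orientation = c("features_in_rows",
                                               "samples_in_rows")) {
  orientation <- match.arg(orientation)
  tab <- data.table::fread(path, data.table = FALSE, header = TRUE,
                           check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed header: expected an id column plus at least one data column")
  ids <- as.character(tab[[1L]])
  cols <- names(tab)[-1L]
  if (anyDuplicated(ids))
    stop("duplicated id(s) in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(cols))
    stop("malformed header: duplicated column id(s): ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(tab), length(cols), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    v <- tab[[j + 1L]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   as.character(v[bad[1L]]), ids[bad[1L]], cols[j]))
    if (anyNA(num))
      stop(sprintf("missing value at row '%s', column '%s'",
                   ids[which(is.na(num))[1L]], cols[j]))
    m[, j] <- num
  }
  if (orientation == "samples_in_rows") m <- t(m)
  profile_matrix(m, stage = "raw")
}

#' Write a profile matrix as a delimited table
#'
#' Values are written with 17 significant digits so that
#' `read_profile_table(write_profile_table(x))` round-trips doubles exactly.
#'
#' @param pm A [profile_matrix()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(pm, path, sep = "\t") {
  stopifnot(inherits(pm, "profile_matrix"))
  m <- pm$values
  txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
  lines <- c(
    paste(c("feature_id", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)),
           function(i) paste(c(rownames(m)[i], txt[i, ]), collapse = sep),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read the expression table of a GEO series-matrix file
#'
#' Parses the plain-text series-matrix format: metadata lines beginning with
#' `!` are skipped and the block delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end` is read as a feature-by-sample table.
#'
#' @param path Path to a series-matrix text file.
#' @return A [profile_matrix()] at stage `"raw"`.
#' @export
read_geo_series_matrix <- function(path) {
  lines <- readLines(path)
  i0 <- grep("^!series_matrix_table_begin", lines)
  i1 <- grep("^!series_matrix_table_end", lines)
  if (length(i0) != 1L || length(i1) != 1L || i1 <= i0 + 1L)
    stop("no series-matrix table block found in ", path)
  block <- lines[(i0 + 1L):(i1 - 1L)]
  block <- gsub('"', "", block, fixed = TRUE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(block, tmp)
  read_profile_table(tmp)
}

#' Read annotation sets from a GMT file
#'
#' Each line holds a term id, a description, and tab-separated member
#' feature ids. Members need not all be present on the array; enrichment
#' tests intersect each set with the array background.
#'
#' @param path Path to a GMT text file.
#' @return A named list of character vectors (members per term), with term
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": need term, description, members")
  terms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(terms))
    stop("duplicated term id(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  attr(sets, "description") <- setNames(vapply(parts, `[[`, character(1), 2L),
                                        terms)
  sets
}

#' Write a YAML run manifest
#'
#' Records inputs, parameters, seed and output files (with MD5 checksums)
#' of an analysis run, sufficient to reproduce it bit-identically.
#'
#' @param path Output path for the YAML file.
#' @param config Parameter list to echo.
#' @param seed Integer seed of the run.
#' @param outputs Character vector of output file paths.
#' @param stage Name of the pipeline stage (or `"run_all"`).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs, stage = "run_all") {
  existing <- outputs[file.exists(outputs)]
  manifest <- list(
    package = "igwave",
    version = as.character(utils::packageVersion("igwave")),
    stage = stage,
    seed = as.integer(seed),
    config = config,
    outputs = as.list(setNames(
      as.character(tools::md5sum(existing)), basename(existing)))
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
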