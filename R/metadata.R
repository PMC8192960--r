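#' Read per-sample metadata (age, sex, diagnosis)
#'
#' Reads a delimited table with columns `sample_id`, `age`, `sex` and
#' optionally `diagnosis`. Rows lacking age or sex are dropped (the cohort
#' inclusion rule: covariate-adjusted models need both) and their ids are
#' reported in a message and in the `"excluded"` attribute of the result.
#' Sex and diagnosis labels are normalized to canonical categories
#' (`female`/`male`; `control`, `ESPD`, `ASPD`, `AD`, `MS`).
#'
#' @param path Path to a tab- or comma-separated file.
#' @param extra_diagnoses Additional diagnosis labels to accept beyond the
#'   built-in set.
#' @return A `data.frame` with columns `sample_id`, `age`, `sex`,
#'   `diagnosis`; excluded sample ids in `attr(, "excluded")`.
#' @export
read_metadata <- function(path, extra_diagnoses = character()) {
  tab <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "age", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (!"diagnosis" %in% names(tab)) tab$diagnosis <- "control"
  tab$sample_id <- as.character(tab$sample_id)
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup))
    stop("duplicated sample_id(s): ", paste(unique(dup), collapse = ", "))

  age <- suppressWarnings(as.numeric(tab$age))
  sex_raw <- trimws(as.character(tab$sex))
  drop <- is.na(age) | is.na(sex_raw) | sex_raw == "" | tolower(sex_raw) == "na"
  excluded <- tab$sample_id[drop]
  if (length(excluded))
    message("excluding ", length(excluded),
            " sample(s) lacking age and/or sex: ",
            paste(excluded, collapse = ", "))
  tab <- tab[!drop, , drop = FALSE]
  age <- age[!drop]
  if (any(age <= 0)) stop("age must be positive for all included samples")

  meta <- data.frame(
    sample_id = tab$sample_id,
    age = age,
    sex = .normalize_sex(tab$sex),
    diagnosis = .normalize_diagnosis(tab$diagnosis, extra_diagnoses),
    stringsAsFactors = FALSE
  )
  attr(meta, "excluded") <- excluded
  meta
}

.normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(f = "female", female = "female", w = "female", woman = "female",
           m = "male", male = "male", man = "male")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unrecognized sex label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected female/male, or F/M)")
  out
}

.normalize_diagnosis <- function(x, extra = character()) {
  allowed <- c(.DIAGNOSES, extra)
  key <- tolower(trimws(as.character(x)))
  key[key %in% c("healthy", "normal")] <- "control"
  idx <- match(key, tolower(allowed))
  if (anyNA(idx))
    stop("unknown diagnosis label(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "),
         "; allowed labels: ", paste(allowed, collapse = ", "))
  allowed[idx]
}

.check_metadata <- function(meta) {
  if (!is.data.frame(meta))
    stop("metadata must be a data.frame")
  need <- c("sample_id", "age", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("metadata sample_ids must be unique")
  if (any(!is.finite(meta$age)) || any(meta$age <= 0))
    stop("metadata ages must be positive and non-missing")
  if (!all(meta$sex %in% c("female", "male")))
    stop("metadata sex must be 'female' or 'male'")
  invisible(meta)
}

#' Select sex- and age-matched controls for a case group
#'
#' Greedy 1:1 nearest-age matching within sex, without replacement: cases are
#' processed in descending order of the distance between their age and the
#' median age of the same-sex control pool (hard-to-match cases first), each
#' taking the available control of the same sex with the smallest absolute
#' age difference. Exact-distance ties are broken by a seeded draw, so a
#' given seed always yields the same selection.
#'
#' @param cases Metadata `data.frame` of the case group.
#' @param control_pool Metadata `data.frame` of candidate controls.
#' @param seed Integer seed governing tie-breaks.
#' @return The selected rows of `control_pool` (one per case); the
#'   case-control pairing with age differences is in `attr(, "pairs")`.
#' @export
match_controls <- function(cases, control_pool, seed = 1L) {
  .check_metadata(cases)
  .check_metadata(control_pool)
  for (s in unique(cases$sex)) {
    n_need <- sum(cases$sex == s)
    n_have <- sum(control_pool$sex == s)
    if (n_have < n_need)
      stop(sprintf("control pool exhausted for sex stratum '%s': need %d, have %d",
                   s, n_need, n_have))
  }
  pairs <- .with_seed(seed, {
    out <- vector("list", length(unique(cases$sex)))
    names(out) <- unique(cases$sex)
    for (s in unique(cases$sex)) {
      cs <- cases[cases$sex == s, , drop = FALSE]
      pool <- control_pool[control_pool$sex == s, , drop = FALSE]
      med <- median(pool$age)
      cs <- cs[order(-abs(cs$age - med), cs$sample_id), , drop = FALSE]
      avail <- rep(TRUE, nrow(pool))
      sel <- character(nrow(cs))
      dif <- numeric(nrow(cs))
      for (i in seq_len(nrow(cs))) {
        d <- abs(pool$age - cs$age[i])
        d[!avail] <- Inf
        cand <- which(d == min(d))
        pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)] else cand
        sel[i] <- pool$sample_id[pick]
        dif[i] <- d[pick]
        avail[pick] <- FALSE
      }
      out[[s]] <- data.frame(case_id = cs$sample_id, control_id = sel,
                             age_difference = dif, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(pairs) <- NULL
  matched <- control_pool[match(pairs$control_id, control_pool$sample_id), ,
                          drop = FALSE]
  rownames(matched) <- NULL
  attr(matched, "pairs") <- pairs
  matched
}
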