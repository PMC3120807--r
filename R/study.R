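#' Construct a matched case-control study object
#'
#' Validates and organises a subject-level table from an individually matched
#' case-control design: subjects are grouped into matched sets (strata), each
#' containing exactly one case and one or more controls. Within each set the
#' case is moved to the first row (the `Y_i1 = 1` labelling convention used by
#' the conditional logistic likelihood); controls keep their input order.
#'
#' @param data A data frame with one row per subject.
#' @param exposures Character vector of column names holding the `P`
#'   continuous surrogate exposures (log scale).
#' @param confounders Character vector of column names holding `K` precisely
#'   measured confounders (may be empty).
#' @param set Name of the matched-set identifier column.
#' @param case Name of the 0/1 case indicator column.
#' @param standardize_confounders If `TRUE`, centre and scale the confounder
#'   columns; the transform (means and sds) is recorded in
#'   `attr(x, "confounder_transform")`. Defaults to `FALSE` so that odds
#'   ratios stay interpretable per original unit.
#'
#' @return A tibble of class `matched_study`, rows ordered by set with the
#'   case first, carrying the design metadata as attributes.
#' @export
#' @examples
#' df <- data.frame(
#'   set = rep(c("a", "b"), each = 3),
#'   case = c(0, 1, 0, 1, 0, 0),
#'   w1 = rnorm(6)
#' )
#' matched_study(df, exposures = "w1")
matched_study <- function(data, exposures, confounders = character(),
                          set = "set", case = "case",
                          standardize_confounders = FALSE) {
  stopifnot(is.data.frame(data))
  used <- c(set, case, exposures, confounders)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)

  na_rows <- which(!stats::complete.cases(data[used]))
  if (length(na_rows) > 0) {
    abort(paste0("missing value(s) in used columns at row(s): ",
                 paste(head(na_rows, 5L), collapse = ", ")))
  }
  if (!all(data[[case]] %in% c(0, 1))) {
    abort(paste0("case column '", case, "' must be 0/1"))
  }
  num_cols <- c(exposures, confounders)
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]]) || any(!is.finite(data[[cl]]))) {
      abort(paste0("column '", cl, "' must be finite numeric"))
    }
  }

  if (standardize_confounders && length(confounders) > 0) {
    ctr <- vapply(data[confounders], mean, numeric(1))
    scl <- vapply(data[confounders], sd, numeric(1))
    scl[scl == 0] <- 1
    for (k in seq_along(confounders)) {
      data[[confounders[k]]] <- (data[[confounders[k]]] - ctr[k]) / scl[k]
    }
    transform <- list(center = ctr, scale = scl)
  } else {
    transform <- NULL
  }

  # validate set composition, then reorder case-first preserving control order
  sid <- as.character(data[[set]])
  n_cases <- tapply(data[[case]], sid, sum)
  bad <- names(n_cases)[n_cases != 1]
  if (length(bad) > 0) {
    abort(paste0("matched set(s) without exactly one case: ",
                 paste(head(bad, 5L), collapse = ", ")))
  }
  n_i <- table(sid)
  small <- names(n_i)[n_i < 2]
  if (length(small) > 0) {
    abort(paste0("matched set(s) with fewer than 2 members: ",
                 paste(head(small, 5L), collapse = ", ")))
  }
  set_levels <- unique(sid)
  if (length(set_levels) < 2) abort("a study needs at least 2 matched sets")
  ord <- order(match(sid, set_levels), -data[[case]])
  data <- data[ord, ]

  structure(
    data,
    class = c("matched_study", class(tibble::tibble()))
,
    exposures = exposures,
    confounders = confounders,
    set_col = set,
    case_col = case,
    confounder_transform = transform
  )
}

#' Read a matched case-control study from a CSV file
#'
#' @param path Path to a CSV file (header row, `.` decimal separator) with one
#'   row per subject.
#' @param exposure_cols,confounder_cols,set_col,case_col Column names; see
#'   [matched_study()].
#' @param ... Passed on to [matched_study()].
#'
#' @return A `matched_study` tibble.
#' @export
read_study <- function(path, exposure_cols, confounder_cols = character(),
                       set_col = "set", case_col = "case", ...) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  matched_study(raw, exposures = exposure_cols, confounders = confounder_cols,
                set = set_col, case = case_col, ...)
}

#' @export
print.matched_study <- function(x, ...) {
  sizes <- set_sizes(x)
  cat(sprintf("<matched_study> %d sets, %d subjects (%d cases), P=%d exposures, K=%d confounders\n",
              length(sizes), sum(sizes), length(sizes),
              length(attr(x, "exposures")), length(attr(x, "confounders"))))
  NextMethod()
}

#' Matched-set sizes
#'
#' @param study A `matched_study`.
#' @return Named integer vector of set sizes `n_i`, in study order.
#' @export
set_sizes <- function(study) {
  sid <- as.character(study[[attr(study, "set_col")]])
  tab <- table(factor(sid, levels = unique(sid)))
  setNames(as.integer(tab), names(tab))
}

# internal: matrices and 0-based offsets consumed by the compiled sampler
study_inputs <- function(study) {
  stopifnot(inherits(study, "matched_study"))
  sizes <- set_sizes(study)
  W <- as.matrix(study[attr(study, "exposures")])
  conf <- attr(study, "confounders")
  Z <- if (length(conf) > 0) as.matrix(study[conf]) else
    matrix(0, nrow(W), 0)
  list(W = W, Z = Z,
       set_size = unname(sizes),
       set_start = c(0L, cumsum(unname(sizes)))[seq_along(sizes)],
       set_ids = names(sizes))
}

#' Assemble a raw concentration table
#'
#' Holds assay measurements on the original concentration scale (e.g. ppb)
#' before limit-of-detection handling and log-molar transformation.
#' Non-detects are encoded as `NA` (an empty CSV cell) or the string `"<LOD"`.
#'
#' @param concentrations Data frame of per-subject concentrations, one column
#'   per exposure. Columns may be numeric with `NA` for non-detects, or
#'   character with `"<LOD"` markers.
#' @param lod Named numeric vector: limit of detection per exposure, on the
#'   concentration scale. All must be positive.
#' @param m Named numeric vector: unit-conversion factor per exposure
#'   (concentration units per molar unit), so that
#'   `concentration = m * exp(log_molar_value)`. All must be positive.
#'
#' @return A tibble of class `raw_concentrations` with numeric columns (`NA`
#'   marks a non-detect) and `lod`, `m` attributes.
#' @export
raw_concentration_table <- function(concentrations, lod, m) {
  concentrations <- tibble::as_tibble(concentrations)
  nm <- names(concentrations)
  if (!all(nm %in% names(lod)) || !all(nm %in% names(m))) {
    abort("`lod` and `m` must be named vectors covering every exposure column")
  }
  if (any(lod[nm] <= 0)) abort("all limits of detection must be > 0")
  if (any(m[nm] <= 0)) abort("all conversion factors `m` must be > 0")
  for (cl in nm) {
    v <- concentrations[[cl]]
    if (is.character(v)) {
      nd <- trimws(v) == "<LOD" | trimws(v) == ""
      v <- suppressWarnings(as.numeric(v))
      v[nd] <- NA_real_
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative detected concentration in column '", cl, "'"))
    }
    concentrations[[cl]] <- v
  }
  structure(concentrations,
            class = c("raw_concentrations", class(tibble::tibble())),
            lod = lod[nm], m = m[nm])
}

#' Substitute non-detects by half the limit of detection
#'
#' Every non-detect (`NA`) is replaced by `LOD/2` for its exposure; detected
#' values are unchanged. The per-exposure substitution counts are recorded in
#' `attr(x, "n_substituted")`. The operation is idempotent.
#'
#' @param table A `raw_concentrations` table.
#' @return The table with non-detects imputed.
#' @export
apply_lod <- function(table) {
  stopifnot(inherits(table, "raw_concentrations"))
  lod <- attr(table, "lod")
  counts <- setNames(integer(length(lod)), names(lod))
  for (cl in names(lod)) {
    nd <- is.na(table[[cl]])
    counts[cl] <- sum(nd)
    table[[cl]][nd] <- lod[cl] / 2
  }
  attr(table, "n_substituted") <- counts
  table
}

#' Transform concentrations to log-molar units
#'
#' Applies the natural-log molar transform `x = log(concentration / m_p)`,
#' the inverse of `concentration = m_p * exp(x)`.
#'
#' @param table A `raw_concentrations` table with all non-detects already
#'   substituted (see [apply_lod()]).
#' @return A tibble of log-molar exposures, same shape and names.
#' @export
to_log_molar <- function(table) {
  stopifnot(inherits(table, "raw_concentrations"))
  m <- attr(table, "m")
  out <- tibble::as_tibble(lapply(setNames(names(m), names(m)), function(cl) {
    v <- table[[cl]]
    if (any(is.na(v)) || any(v <= 0)) {
      abort(paste0("non-positive or missing concentration in '", cl,
                   "'; run apply_lod() first"))
    }
    log(v / m[cl])
  }))
  out
}

#' Write an odds-ratio summary table
#'
#' Writes the tidy summary to CSV and mirrors it, together with run
#' provenance (seeds, priors, error variances, chain settings), to a JSON
#' file alongside.
#'
#' @param summaries A tidy OR summary (as returned by [tidy()][tidy.me_fit]
#'   on a fit, or [summarize_or()]).
#' @param path Output CSV path; the JSON mirror replaces the extension with
#'   `.json`.
#' @param provenance Named list of run metadata stored in the JSON mirror.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path, provenance = list()) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  readr::write_csv(summaries, path)
  json_path <- sub("\\.[A-Za-z0-9]+$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(summary = summaries, provenance = provenance),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
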