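#' Construct a cohort of individual plant records
#'
#' A cohort holds one row per planted seedling of a reciprocal transplant
#' experiment: its treatment labels (site, soil origin, ecotype origin), its
#' fate (survival to reproduction, fruit count), an optional viable-seed count
#' from one intact mature fruit, and an edge-row flag. Edge plants are kept and
#' flagged so that their exclusion by [filter_analysis_set()] is an explicit,
#' auditable step.
#'
#' Record-level invariants enforced here:
#' * a plant that did not survive to reproduction has `fruits = 0` and no
#'   seed count (every planted seedling that died contributes a zero to the
#'   overall-fitness proxy, so fruits are stored as 0, not missing);
#' * a seed count implies the plant survived and set at least one fruit.
#'
#' Treatment labels are free strings, not an enum: the pipeline is generic
#' over any two-site design. The two-label constraint (site, soil and ecotype
#' drawn from the same two-label universe) is checked at analysis time, not at
#' construction.
#'
#' @param records A data frame with columns `plant_id`, `site`, `soil`,
#'   `ecotype`, `survived` (logical), `fruits` (non-negative integer),
#'   `seeds_per_fruit` (non-negative integer or `NA`), `edge` (logical).
#' @param metadata Optional named list of provenance notes (source file,
#'   generator seed, ...).
#' @return An object of class `cohort`: a list with elements `records`
#'   (tibble), `sites` (sorted label universe) and `metadata`.
#' @seealso [read_cohort()], [write_cohort()], [filter_analysis_set()]
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   plant_id = c("a", "b"), site = "A", soil = c("A", "B"), ecotype = "A",
#'   survived = c(TRUE, FALSE), fruits = c(5L, 0L),
#'   seeds_per_fruit = c(12L, NA), edge = FALSE
#' )
#' cohort(rec)
cohort <- function(records, metadata = list()) {
  records <- as_record_tibble(records)
  problems <- validate_records(records)
  if (length(problems) > 0) {
    stop(
      "Invalid plant records:\n  ",
      paste(head(problems, 20L), collapse = "\n  "),
      if (length(problems) > 20L) sprintf("\n  ... and %d more", length(problems) - 20L),
      call. = FALSE
    )
  }
  structure(
    list(
      records = records,
      sites = sort(unique(c(records$site, records$soil, records$ecotype))),
      metadata = metadata
    ),
    class = "cohort"
  )
}

# Coerce to the canonical record column set and types; structural errors
# (missing columns, uncoercible types) are reported here, row-level invariant
# violations in validate_records().
as_record_tibble <- function(records) {
  records <- tibble::as_tibble(records)
  required <- c(
    "plant_id", "site", "soil", "ecotype", "survived", "fruits",
    "seeds_per_fruit", "edge"
  )
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop(
      "Missing required column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  records <- records[required]
  records$plant_id <- as.character(records$plant_id)
  for (col in c("site", "soil", "ecotype")) {
    records[[col]] <- as.character(records[[col]])
  }
  records$survived <- coerce_flag(records$survived, "survived")
  records$edge <- coerce_flag(records$edge, "edge")
  records$fruits <- coerce_count(records$fruits, "fruits")
  records$seeds_per_fruit <- coerce_count(records$seeds_per_fruit,
    "seeds_per_fruit",
    allow_na = TRUE
  )
  records
}

coerce_flag <- function(x, name) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("Column '", name, "' contains missing values", call. = FALSE)
    return(x)
  }
  if (is.numeric(x) && all(x %in% c(0, 1))) {
    return(x == 1)
  }
  stop("Column '", name, "' must be logical or 0/1", call. = FALSE)
}

coerce_count <- function(x, name, allow_na = FALSE) {
  if (!is.numeric(x) && !all(is.na(x))) {
    stop("Column '", name, "' must be numeric counts", call. = FALSE)
  }
  x <- as.numeric(x)
  bad_na <- is.na(x) & !allow_na
  if (any(bad_na)) {
    stop("Column '", name, "' contains missing values (rows ",
      paste(head(which(bad_na), 5L), collapse = ", "), ")",
      call. = FALSE
    )
  }
  ok <- is.na(x) | (x >= 0 & x == round(x))
  if (!all(ok)) {
    stop("Column '", name, "' must hold non-negative integers (rows ",
      paste(head(which(!ok), 5L), collapse = ", "), ")",
      call. = FALSE
    )
  }
  as.integer(x)
}

# Row-numbered diagnostics for record-level invariants. Validation is total:
# every row is either accepted or named in a diagnostic; nothing is dropped.
validate_records <- function(records) {
  problems <- character(0)
  n <- nrow(records)
  if (n == 0) {
    return(problems)
  }
  for (col in c("plant_id", "site", "soil", "ecotype")) {
    bad <- which(is.na(records[[col]]) | records[[col]] == "")
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("row %d: missing %s", bad, col))
    }
  }
  dup <- which(duplicated(records$plant_id))
  if (length(dup) > 0) {
    problems <- c(problems, sprintf(
      "row %d: duplicate plant_id '%s'", dup, records$plant_id[dup]
    ))
  }
  dead_fruit <- which(!records$survived & records$fruits != 0L)
  if (length(dead_fruit) > 0) {
    problems <- c(problems, sprintf(
      "row %d: plant did not survive but has fruits > 0 (survived = FALSE implies fruits = 0)",
      dead_fruit
    ))
  }
  dead_seed <- which(!records$survived & !is.na(records$seeds_per_fruit))
  if (length(dead_seed) > 0) {
    problems <- c(problems, sprintf(
      "row %d: seed count recorded for a plant that did not survive",
      dead_seed
    ))
  }
  seed_no_fruit <- which(records$survived & !is.na(records$seeds_per_fruit) &
    records$fruits < 1L)
  if (length(seed_no_fruit) > 0) {
    problems <- c(problems, sprintf(
      "row %d: seed count present but fruits = 0 (seeds_per_fruit implies fruits >= 1)",
      seed_no_fruit
    ))
  }
  problems[order(as.integer(sub("^row (\\d+):.*$", "\\1", problems)))]
}

#' @export
print.cohort <- function(x, ...) {
  n_edge <- sum(x$records$edge)
  cat(sprintf(
    "<cohort> %d plants (%d edge) across sites: %s\n",
    nrow(x$records), n_edge, paste(x$sites, collapse = ", ")
  ))
  if (length(x$metadata) > 0) {
    cat("metadata:", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
      sep = " = ", collapse = "; "
    ), "\n")
  }
  invisible(x)
}

#' @export
format.cohort <- function(x, ...) {
  sprintf("<cohort of %d plants>", nrow(x$records))
}

is_cohort <- function(x) inherits(x, "cohort")

#' Restrict a cohort to the analysis set (non-edge plants)
#'
#' Edge-row filler plants reduce edge effects in the field layout but are not
#' scored for the analysis; this drops them, reporting how many were removed.
#'
#' @param x A [cohort()].
#' @return A cohort containing only the non-edge records; the number of
#'   removed records is reported via `message()` and recorded in the cohort
#'   metadata as `n_edge_removed`.
#' @export
filter_analysis_set <- function(x) {
  stopifnot(is_cohort(x))
  keep <- !x$records$edge
  n_removed <- sum(!keep)
  message(sprintf("filter_analysis_set: removed %d edge record(s), kept %d", n_removed, sum(keep)))
  if (sum(keep) == 0 && nrow(x$records) > 0) {
    warning("All records are edge plants; the analysis set is empty", call. = FALSE)
  }
  out <- x
  out$records <- x$records[keep, , drop = FALSE]
  out$metadata$n_edge_removed <- n_removed
  out
}
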