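#' Read a cohort from a delimited text file
#'
#' Expects a header naming the record fields (case-insensitive):
#' `plant_id, site, soil, ecotype, survived, fruits, seeds_per_fruit, edge`.
#' `survived` and `edge` may be encoded `0/1` or `true/false` (any case);
#' missing `seeds_per_fruit` is encoded as an empty field or the literal
#' `"NA"` — nothing else decodes to missing. Every malformed row produces a
#' row-numbered diagnostic (row numbers count data rows, excluding the
#' header); no row is silently dropped.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default comma.
#' @param na Strings decoding to a missing seed count.
#' @return A validated [cohort()], with `metadata$source` set to `path`.
#'   Edge records are retained and flagged, not dropped.
#' @export
read_cohort <- function(path, delim = ",", na = c("", "NA")) {
  if (!file.exists(path)) {
    stop("File not found: ", path, call. = FALSE)
  }
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(0),
    show_col_types = FALSE,
    progress = FALSE
  )
  names(raw) <- tolower(trimws(names(raw)))
  required <- c(
    "plant_id", "site", "soil", "ecotype", "survived", "fruits",
    "seeds_per_fruit", "edge"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "File ", path, " is missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- raw[required]
  n <- nrow(raw)
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) sprintf("row %d: %s", rows, what) else character(0)
  }

  parse_flag_chr <- function(x, name) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "t")] <- TRUE
    out[x %in% c("0", "false", "f")] <- FALSE
    problems <<- c(problems, note(
      which(is.na(out)),
      sprintf("%s must be 0/1 or true/false", name)
    ))
    out
  }
  parse_count_chr <- function(x, name, allow_na = FALSE) {
    x <- trimws(x)
    miss <- x %in% na | is.na(x)
    out <- rep(NA_integer_, length(x))
    ok <- grepl("^[0-9]+$", x)
    out[ok] <- as.integer(x[ok])
    bad <- !ok & !miss
    problems <<- c(problems, note(
      which(bad),
      sprintf("%s must be a non-negative integer, got '%s'", name, x[bad])
    ))
    if (!allow_na) {
      problems <<- c(problems, note(
        which(miss),
        sprintf("%s may not be missing", name)
      ))
    }
    out
  }

  survived <- parse_flag_chr(raw$survived, "survived")
  edge <- parse_flag_chr(raw$edge, "edge")
  fruits <- parse_count_chr(raw$fruits, "fruits")
  seeds <- parse_count_chr(raw$seeds_per_fruit, "seeds_per_fruit", allow_na = TRUE)
  if (length(problems) > 0) {
    stop(
      "Cannot parse ", path, ":\n  ",
      paste(head(problems, 20L), collapse = "\n  "),
      if (length(problems) > 20L) sprintf("\n  ... and %d more", length(problems) - 20L),
      call. = FALSE
    )
  }
  records <- tibble::tibble(
    plant_id = as.character(raw$plant_id),
    site = as.character(raw$site),
    soil = as.character(raw$soil),
    ecotype = as.character(raw$ecotype),
    survived = survived,
    fruits = fruits,
    seeds_per_fruit = seeds,
    edge = edge
  )
  cohort(records, metadata = list(source = path))
}

#' Write a cohort to a delimited text file
#'
#' Writes the canonical comma-delimited form: `survived` and `edge` as `0/1`,
#' missing seed counts as empty fields, UTF-8. [read_cohort()] on the result
#' reproduces the cohort field-for-field.
#'
#' @param x A [cohort()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(x, path) {
  stopifnot(is_cohort(x))
  out <- x$records
  out$survived <- as.integer(out$survived)
  out$edge <- as.integer(out$edge)
  readr::write_csv(out, path, na = "")
  invisible(path)
}
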