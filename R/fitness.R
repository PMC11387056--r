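#' Per-cell fitness component summaries
#'
#' For every observed (site, soil, ecotype) treatment cell, computes the four
#' fitness summaries:
#' * `survival` — mean of the survived-to-reproduction flag over planted
#'   seedlings;
#' * `fecundity` — mean fruits per reproductive plant (missing when nothing
#'   survived);
#' * `seeds_per_fruit` — mean viable seeds over the measured fruits (missing
#'   when no survivor was measured);
#' * `overall` — mean, over all planted seedlings, of fruit count times the
#'   cell mean seeds per fruit: the seeds-per-planted-seedling proxy for
#'   overall fitness. Dead plants contribute 0; survivors without a seed
#'   measurement still contribute their fruits through the cell mean.
#'
#' When all four are defined they satisfy the product identity
#' `overall = survival * fecundity * seeds_per_fruit` exactly (up to floating
#' point), because dead plants carry `fruits = 0`. An all-dead cell has
#' `overall = 0` even though `seeds_per_fruit` is undefined (every planted
#' seedling produced zero seeds); a cell with survivors but no seed
#' measurement has `overall` missing — the cell-mean multiplier cannot be
#' applied and is never imputed from other cells.
#'
#' @param x A [cohort()]; edge records, if any, are excluded with a warning
#'   (use [filter_analysis_set()] for an explicit, logged exclusion).
#' @return A tibble with one row per cell across the full site x soil x
#'   ecotype crossing of observed labels, columns `site, soil, ecotype,
#'   n_planted, n_survived, n_seed_measured, survival, fecundity,
#'   seeds_per_fruit, overall`. Combinations absent from the data get
#'   `n_planted = 0` and missing means, with a warning.
#' @export
summarize_cells <- function(x) {
  stopifnot(is_cohort(x))
  rec <- x$records
  if (any(rec$edge)) {
    warning("Cohort contains edge records; excluding them from summaries", call. = FALSE)
    rec <- rec[!rec$edge, , drop = FALSE]
  }
  sites <- sort(unique(rec$site))
  soils <- sort(unique(rec$soil))
  ecos <- sort(unique(rec$ecotype))
  grid <- expand.grid(
    ecotype = ecos, soil = soils, site = sites,
    stringsAsFactors = FALSE
  )[c("site", "soil", "ecotype")]
  out <- vector("list", nrow(grid))
  empty <- character(0)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sel <- rec$site == g$site & rec$soil == g$soil & rec$ecotype == g$ecotype
    n <- sum(sel)
    if (n == 0) {
      empty <- c(empty, sprintf("(%s, %s, %s)", g$site, g$soil, g$ecotype))
    }
    st <- cell_stats(rec$survived[sel], rec$fruits[sel], rec$seeds_per_fruit[sel])
    out[[i]] <- tibble::tibble(
      site = g$site, soil = g$soil, ecotype = g$ecotype,
      n_planted = n,
      n_survived = sum(rec$survived[sel]),
      n_seed_measured = sum(!is.na(rec$seeds_per_fruit[sel])),
      survival = st[1], fecundity = st[2],
      seeds_per_fruit = st[3], overall = st[4]
    )
  }
  if (length(empty) > 0) {
    warning(
      "Empty treatment cell(s): ", paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(rbind, out)
}

# Core per-cell statistic kernel shared by summaries, bootstrap and
# permutation replicates. Returns c(survival, fecundity, seeds_per_fruit,
# overall); overall = mean(fruits) * mean(seeds) holds because dead plants
# have fruits = 0, and resolves to 0 when mean(fruits) = 0 regardless of the
# (undefined) seed mean.
cell_stats <- function(survived, fruits, seeds) {
  n <- length(survived)
  if (n == 0L) {
    return(rep(NA_real_, 4L))
  }
  n_surv <- sum(survived)
  surv <- n_surv / n
  total_fruits <- sum(fruits)
  fec <- if (n_surv > 0L) total_fruits / n_surv else NA_real_
  measured <- seeds[!is.na(seeds)]
  spf <- if (length(measured) > 0L) sum(measured) / length(measured) else NA_real_
  mean_fruits <- total_fruits / n
  overall <- if (mean_fruits == 0) 0 else mean_fruits * spf
  c(surv, fec, spf, overall)
}

#' Check the multiplicative-proxy identity of a cell summary
#'
#' Verifies `overall = survival * fecundity * seeds_per_fruit` to a relative
#' tolerance, for rows of a [summarize_cells()] table where all four
#' components are defined.
#'
#' @param summary A one-or-more-row cell summary tibble with columns
#'   `survival, fecundity, seeds_per_fruit, overall`, all defined.
#' @param tol Relative tolerance (default `1e-12`).
#' @return Logical vector, one value per row.
#' @export
check_product_identity <- function(summary, tol = 1e-12) {
  product <- summary$survival * summary$fecundity * summary$seeds_per_fruit
  if (anyNA(product) || anyNA(summary$overall)) {
    stop("check_product_identity requires all four components to be defined", call. = FALSE)
  }
  scale <- pmax(abs(summary$overall), abs(product), 1)
  abs(summary$overall - product) <= tol * scale
}
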