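#' Selection coefficient against the non-local ecotype
#'
#' `s = 1 - w_nonlocal / w_local`, where the `w` are mean absolute fitness
#' values of the local and non-local ecotype in the same site-soil cell.
#' Positive `s` means the local ecotype is favoured; `s = 1` exactly when the
#' non-local ecotype has zero mean fitness and the local does not; `s` is
#' undefined (`NA`) when the local mean is zero, including the 0/0 case.
#'
#' @param w_local,w_nonlocal Non-negative mean absolute fitness values
#'   (vectorized).
#' @return Numeric vector of selection coefficients, `NA` where undefined.
#' @export
#' @examples
#' selection_coefficient(10, 5) # 0.5
#' selection_coefficient(5, 10) # -1, non-local favoured
selection_coefficient <- function(w_local, w_nonlocal) {
  if (any(w_local < 0, na.rm = TRUE) || any(w_nonlocal < 0, na.rm = TRUE)) {
    stop("Mean fitness values must be non-negative", call. = FALSE)
  }
  s <- 1 - w_nonlocal / w_local
  s[!is.finite(s)] <- NA_real_
  s
}

#' Resampling plan for bootstrap and permutation inference
#'
#' @param n_boot Number of stratified bootstrap samples for confidence
#'   intervals (default 1000; 0 skips CIs).
#' @param n_perm Number of within-site soil permutations (default 1000).
#' @param ci_level Confidence level for percentile intervals (default 0.95).
#' @param seed Integer RNG seed governing both resampling streams.
#' @param tail Tail convention for the permutation p value: `"signed"`
#'   (default) doubles the permutation tail in the direction of the observed
#'   difference; `"absolute"` uses the proportion of permuted `|delta_s|` at
#'   least the observed `|delta_s|`.
#' @param plain_p If `TRUE`, report the plain doubled proportion instead of
#'   the default add-one–corrected `p = min(1, 2 (1 + k) / (n_perm + 1))`,
#'   which never returns 0 and is valid in finite samples.
#' @return An object of class `resampling_plan`.
#' @export
resampling_plan <- function(n_boot = 1000L, n_perm = 1000L, ci_level = 0.95,
                            seed = 1L, tail = c("signed", "absolute"),
                            plain_p = FALSE) {
  tail <- match.arg(tail)
  n_boot <- as.integer(n_boot)
  n_perm <- as.integer(n_perm)
  if (is.na(n_boot) || n_boot < 0L) stop("n_boot must be >= 0", call. = FALSE)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    stop("ci_level must be in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_boot = n_boot, n_perm = n_perm, ci_level = ci_level,
      seed = as.integer(seed), tail = tail, plain_p = isTRUE(plain_p)
    ),
    class = "resampling_plan"
  )
}

# ---- internal analysis representation -------------------------------------
#
# Records are recoded to integer site/soil/ecotype indices over the two-label
# universe, and split into the 8 design strata. All resampling loops work on
# plain numeric vectors for speed.

prep_analysis <- function(x, local_map = NULL) {
  stopifnot(is_cohort(x))
  rec <- x$records
  if (any(rec$edge)) {
    rec <- rec[!rec$edge, , drop = FALSE]
  }
  if (nrow(rec) == 0) stop("No non-edge records to analyse", call. = FALSE)
  labs <- sort(unique(c(rec$site, rec$soil, rec$ecotype)))
  if (length(labs) != 2L) {
    stop(
      "Analysis requires a two-label site/soil/ecotype universe; found: ",
      paste(labs, collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(local_map)) {
    local_map <- setNames(labs, labs)
  }
  obs_sites <- sort(unique(rec$site))
  if (!all(obs_sites %in% names(local_map))) {
    stop(
      "local_map must name the local ecotype for site(s): ",
      paste(setdiff(obs_sites, names(local_map)), collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(local_map[obs_sites] %in% labs)) {
    stop("local_map values must be ecotype labels", call. = FALSE)
  }
  site_i <- match(rec$site, labs)
  soil_i <- match(rec$soil, labs)
  eco_i <- match(rec$ecotype, labs)
  local_eco <- match(local_map[labs], labs) # per site index
  stratum <- (site_i - 1L) * 4L + (soil_i - 1L) * 2L + eco_i
  # every referenced cell (both ecotypes in every observed site-soil) must be
  # non-empty, and in particular the local ecotype must be present
  counts <- tabulate(stratum, nbins = 8L)
  for (si in seq_along(labs)) {
    if (!any(site_i == si)) next
    for (so in 1:2) {
      if (!any(site_i == si & soil_i == so)) {
        stop(
          "Site '", labs[si], "' lacks soil '", labs[so], "' records",
          call. = FALSE
        )
      }
      for (e in 1:2) {
        if (counts[(si - 1L) * 4L + (so - 1L) * 2L + e] == 0L) {
          stop(
            "Empty treatment cell: site '", labs[si], "', soil '", labs[so],
            "', ecotype '", labs[e], "'",
            if (e == local_eco[si]) " (the local ecotype is absent)" else "",
            call. = FALSE
          )
        }
      }
    }
  }
  list(
    labs = labs,
    local_eco = local_eco,
    site_i = site_i, soil_i = soil_i, eco_i = eco_i,
    survived = as.numeric(rec$survived),
    fruits = as.numeric(rec$fruits),
    seeds = as.numeric(rec$seeds_per_fruit),
    stratum = stratum
  )
}

# s for all 4 site-soil pairs x 4 components from an 8 x 4 matrix of cell
# stats (rows keyed (site-1)*4 + (soil-1)*2 + ecotype).
s_from_stats <- function(stats, local_eco) {
  out <- matrix(NA_real_, 4L, 4L)
  r <- 0L
  for (si in 1:2) {
    el <- local_eco[si]
    en <- 3L - el
    for (so in 1:2) {
      r <- r + 1L
      w_l <- stats[(si - 1L) * 4L + (so - 1L) * 2L + el, ]
      w_n <- stats[(si - 1L) * 4L + (so - 1L) * 2L + en, ]
      s <- 1 - w_n / w_l
      s[!is.finite(s)] <- NA_real_
      out[r, ] <- s
    }
  }
  out # rows: (site1,soil1), (site1,soil2), (site2,soil1), (site2,soil2)
}

stats_by_stratum <- function(p, idx_list) {
  stats <- matrix(NA_real_, 8L, 4L)
  for (k in 1:8) {
    ix <- idx_list[[k]]
    if (length(ix) > 0L) {
      stats[k, ] <- cell_stats(p$survived[ix] > 0, p$fruits[ix], p$seeds[ix])
    }
  }
  stats
}

#' Selection coefficients with stratified bootstrap confidence intervals
#'
#' For each site-soil combination and each fitness component (survival,
#' fecundity, seeds per fruit, overall), estimates selection against the
#' non-local ecotype, `s = 1 - w_nonlocal / w_local`, from the full-data cell
#' means, and attaches a percentile bootstrap confidence interval: records
#' are resampled with replacement independently within every (site, soil,
#' ecotype) stratum at its original size, and `s` — including the
#' seeds-per-fruit cell-mean multiplier of the overall proxy — is recomputed
#' on each resample. Bootstrap replicates on which `s` is undefined (a
#' resampled local-ecotype mean of zero) are dropped and counted; if more
#' than 5% drop, the interval is flagged unreliable.
#'
#' @param x A [cohort()]. Edge records are excluded.
#' @param local_map Named character vector mapping each site label to its
#'   local ecotype label; default: the ecotype whose label equals the site
#'   label is local.
#' @param plan A [resampling_plan()]; `plan$n_boot = 0` skips the bootstrap
#'   (CI columns are `NA`).
#' @return A tibble with columns `site, soil, component, s_hat, ci_low,
#'   ci_high, n_boot_used, n_boot_dropped, ci_flagged`.
#' @export
estimate_selection <- function(x, local_map = NULL, plan = resampling_plan()) {
  stopifnot(inherits(plan, "resampling_plan"))
  p <- prep_analysis(x, local_map)
  idx_full <- lapply(1:8, function(k) which(p$stratum == k))
  s_point <- s_from_stats(stats_by_stratum(p, idx_full), p$local_eco)

  n_boot <- plan$n_boot
  boot <- NULL
  if (n_boot > 0L) {
    set.seed(plan$seed)
    boot <- array(NA_real_, dim = c(n_boot, 4L, 4L))
    sizes <- lengths(idx_full)
    for (b in seq_len(n_boot)) {
      idx_b <- vector("list", 8L)
      for (k in 1:8) {
        if (sizes[k] > 0L) {
          idx_b[[k]] <- idx_full[[k]][sample.int(sizes[k], sizes[k], replace = TRUE)]
        } else {
          idx_b[[k]] <- integer(0)
        }
      }
      boot[b, , ] <- s_from_stats(stats_by_stratum(p, idx_b), p$local_eco)
    }
  }

  alpha <- (1 - plan$ci_level) / 2
  comps <- component_levels()
  labs <- p$labs
  rows <- vector("list", 16L)
  r <- 0L
  pair <- 0L
  for (si in 1:2) {
    for (so in 1:2) {
      pair <- pair + 1L
      for (ci in 1:4) {
        r <- r + 1L
        lo <- hi <- NA_real_
        used <- dropped <- 0L
        flagged <- FALSE
        if (!is.null(boot)) {
          reps <- boot[, pair, ci]
          ok <- !is.na(reps)
          used <- sum(ok)
          dropped <- n_boot - used
          if (used > 0L) {
            q <- quantile(reps[ok], c(alpha, 1 - alpha), names = FALSE, type = 7)
            lo <- q[1]
            hi <- q[2]
          }
          flagged <- dropped > 0.05 * n_boot
        }
        rows[[r]] <- tibble::tibble(
          site = labs[si], soil = labs[so], component = comps[ci],
          s_hat = s_point[pair, ci], ci_low = lo, ci_high = hi,
          n_boot_used = used, n_boot_dropped = dropped, ci_flagged = flagged
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$ci_flagged)) {
    warning(
      "More than 5% of bootstrap replicates had undefined s for some ",
      "site-soil-component; those intervals are flagged unreliable",
      call. = FALSE
    )
  }
  out
}

# Per-site delta_s (4 components) given this site's soil labels. soil_v holds
# global soil indices (1/2); the soil local to the site is the one whose
# label matches the site label, i.e. index `si`.
site_delta <- function(soil_v, eco_v, survived, fruits, seeds, si, el) {
  en <- 3L - el
  stats <- matrix(NA_real_, 4L, 4L) # rows (soil-1)*2 + eco
  for (so in 1:2) {
    for (e in 1:2) {
      ix <- which(soil_v == so & eco_v == e)
      if (length(ix) > 0L) {
        stats[(so - 1L) * 2L + e, ] <- cell_stats(survived[ix] > 0, fruits[ix], seeds[ix])
      }
    }
  }
  s_soil <- function(so) {
    s <- 1 - stats[(so - 1L) * 2L + en, ] / stats[(so - 1L) * 2L + el, ]
    s[!is.finite(s)] <- NA_real_
    s
  }
  s_soil(si) - s_soil(3L - si)
}

perm_p_value <- function(obs, perm_mat, tail, plain, exhaustive) {
  vapply(seq_along(obs), function(ci) {
    d <- obs[ci]
    if (is.na(d)) {
      return(NA_real_)
    }
    reps <- perm_mat[, ci]
    reps <- reps[!is.na(reps)]
    n_valid <- length(reps)
    if (n_valid == 0L) {
      return(NA_real_)
    }
    k <- if (tail == "absolute") {
      sum(abs(reps) >= abs(d))
    } else if (d >= 0) {
      sum(reps >= d)
    } else {
      sum(reps <= d)
    }
    p <- if (exhaustive || plain) {
      2 * k / n_valid
    } else {
      2 * (1 + k) / (n_valid + 1)
    }
    min(1, p)
  }, numeric(1))
}

#' Permutation test for a difference in selection between soil types
#'
#' Tests, within each site, the null hypothesis that selection against the
#' non-local ecotype is the same on the two soil types. The statistic is
#' `delta_s = s(soil local to the site) - s(non-local soil)` for each fitness
#' component. Under the null, soil labels are exchangeable within a site:
#' each permutation replicate shuffles the soil labels uniformly among all
#' non-edge records of the site (each record's ecotype and observations ride
#' with it; per-soil totals are preserved) and recomputes `delta_s` from
#' scratch, including the per-cell seeds-per-fruit multiplier of the overall
#' proxy. The two-sided p value doubles the permutation tail in the direction
#' of the observed difference (or uses absolute values, per the plan), with
#' an add-one correction by default. Permutation replicates on which
#' `delta_s` is undefined (an empty or zero-mean resampled cell, possible
#' only in tiny cohorts) are dropped and counted.
#'
#' With `exhaustive = TRUE` all distinguishable within-site soil-label
#' assignments are enumerated instead of sampled (feasible for small sites);
#' the p value is then the exact doubled tail proportion over the
#' enumeration, which contains the observed assignment, with no add-one
#' correction.
#'
#' @inheritParams estimate_selection
#' @param exhaustive Enumerate all soil-label assignments instead of sampling
#'   `plan$n_perm` of them.
#' @return A tibble with columns `site, component, delta_s, p_value, n_perm,
#'   n_perm_dropped, tail_convention`; `n_perm` counts the valid (non-dropped)
#'   replicates actually used.
#' @export
soil_contrast <- function(x, local_map = NULL, plan = resampling_plan(),
                          exhaustive = FALSE) {
  stopifnot(inherits(plan, "resampling_plan"))
  p <- prep_analysis(x, local_map)
  set.seed(plan$seed + 1L)
  comps <- component_levels()
  labs <- p$labs
  rows <- vector("list", 2L)
  for (si in 1:2) {
    in_site <- which(p$site_i == si)
    if (length(in_site) == 0L) next
    soil_v <- p$soil_i[in_site]
    eco_v <- p$eco_i[in_site]
    surv_v <- p$survived[in_site]
    fruit_v <- p$fruits[in_site]
    seed_v <- p$seeds[in_site]
    el <- p$local_eco[si]
    n_site <- length(in_site)
    obs <- site_delta(soil_v, eco_v, surv_v, fruit_v, seed_v, si, el)

    if (exhaustive) {
      ones <- which(soil_v == 1L)
      n1 <- length(ones)
      subsets <- combn(n_site, n1)
      n_rep <- ncol(subsets)
      perm_mat <- matrix(NA_real_, n_rep, 4L)
      for (j in seq_len(n_rep)) {
        soil_p <- rep(2L, n_site)
        soil_p[subsets[, j]] <- 1L
        perm_mat[j, ] <- site_delta(soil_p, eco_v, surv_v, fruit_v, seed_v, si, el)
      }
    } else {
      n_rep <- plan$n_perm
      perm_mat <- matrix(NA_real_, n_rep, 4L)
      for (j in seq_len(n_rep)) {
        soil_p <- soil_v[sample.int(n_site)]
        perm_mat[j, ] <- site_delta(soil_p, eco_v, surv_v, fruit_v, seed_v, si, el)
      }
    }
    pvals <- perm_p_value(obs, perm_mat, plan$tail, plan$plain_p, exhaustive)
    n_valid <- colSums(!is.na(perm_mat))
    rows[[si]] <- tibble::tibble(
      site = labs[si], component = comps, delta_s = obs, p_value = pvals,
      n_perm = as.integer(n_valid),
      n_perm_dropped = as.integer(nrow(perm_mat) - n_valid),
      tail_convention = plan$tail
    )
  }
  do.call(rbind, rows)
}
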