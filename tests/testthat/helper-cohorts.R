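# Builders and independent oracles shared across tests. The oracles are
# written as plain, direct arithmetic on data frames so that they exercise a
# different code path from the package's resampling kernels.

record_row <- function(plant_id, site, soil, ecotype, survived, fruits,
                       seeds = NA_integer_, edge = FALSE) {
  tibble::tibble(
    plant_id = plant_id, site = site, soil = soil, ecotype = ecotype,
    survived = survived, fruits = as.integer(fruits),
    seeds_per_fruit = as.integer(seeds), edge = edge
  )
}

# A full 2x2x2 cohort with `per_cell` plants per cell; fruit/seed values vary
# deterministically by cell and plant so cells are distinguishable.
make_full_cohort <- function(per_cell = 3L, sites = c("A", "B"),
                             all_survive = TRUE) {
  rows <- list()
  id <- 0L
  for (site in sites) {
    for (soil in sites) {
      for (eco in sites) {
        for (i in seq_len(per_cell)) {
          id <- id + 1L
          survived <- all_survive || (i %% 2L == 1L)
          fruits <- if (survived) id %% 7L + 1L else 0L
          seeds <- if (survived && i %% 2L == 1L) id %% 5L + 10L else NA_integer_
          rows[[id]] <- record_row(
            paste0("p", id), site, soil, eco, survived, fruits, seeds
          )
        }
      }
    }
  }
  cohort(do.call(rbind, rows))
}

# Oracle: per-cell fitness components by direct arithmetic on a record frame.
oracle_cell_means <- function(df) {
  if (nrow(df) == 0) {
    return(c(
      survival = NA_real_, fecundity = NA_real_,
      seeds_per_fruit = NA_real_, overall = NA_real_
    ))
  }
  surv <- mean(df$survived)
  fec <- if (any(df$survived)) mean(df$fruits[df$survived]) else NA_real_
  measured <- df$seeds_per_fruit[!is.na(df$seeds_per_fruit)]
  spf <- if (length(measured) > 0) mean(measured) else NA_real_
  overall <- if (mean(df$fruits) == 0) 0 else mean(df$fruits * spf)
  c(survival = surv, fecundity = fec, seeds_per_fruit = spf, overall = overall)
}

# Oracle: the four selection coefficients of one site-soil cell pair.
oracle_s <- function(df_local, df_nonlocal) {
  w_l <- oracle_cell_means(df_local)
  w_n <- oracle_cell_means(df_nonlocal)
  s <- 1 - w_n / w_l
  s[!is.finite(s)] <- NA_real_
  s
}

# Oracle: delta_s for one site given an explicit soil-label assignment.
oracle_site_delta <- function(df_site, soil_labels, site_label, local_eco,
                              nonlocal_eco) {
  soils <- sort(unique(df_site$soil))
  local_soil <- site_label
  other_soil <- setdiff(soils, local_soil)
  s_on_soil <- function(soil_lab) {
    oracle_s(
      df_site[soil_labels == soil_lab & df_site$ecotype == local_eco, ],
      df_site[soil_labels == soil_lab & df_site$ecotype == nonlocal_eco, ]
    )
  }
  s_on_soil(local_soil) - s_on_soil(other_soil)
}

# Oracle: exact two-sided permutation p by exhaustive enumeration of all
# distinguishable soil-label assignments within one site. Assignments on
# which delta_s is undefined are dropped from numerator and denominator,
# mirroring the documented behaviour. Returns the doubled tail in the
# direction of the observed delta (or of |delta| for tail = "absolute"),
# capped at 1.
oracle_exact_p <- function(df_site, site_label, local_eco, nonlocal_eco,
                           tail = "signed") {
  soils <- sort(unique(df_site$soil))
  n <- nrow(df_site)
  n1 <- sum(df_site$soil == soils[1])
  obs <- oracle_site_delta(
    df_site, df_site$soil, site_label, local_eco, nonlocal_eco
  )
  subsets <- utils::combn(n, n1)
  deltas <- matrix(NA_real_, ncol(subsets), 4L)
  for (j in seq_len(ncol(subsets))) {
    lab <- rep(soils[2], n)
    lab[subsets[, j]] <- soils[1]
    deltas[j, ] <- oracle_site_delta(
      df_site, lab, site_label, local_eco, nonlocal_eco
    )
  }
  p <- numeric(4L)
  for (ci in 1:4) {
    d <- obs[ci]
    reps <- deltas[!is.na(deltas[, ci]), ci]
    if (is.na(d) || length(reps) == 0) {
      p[ci] <- NA_real_
      next
    }
    k <- if (tail == "absolute") {
      sum(abs(reps) >= abs(d))
    } else if (d >= 0) {
      sum(reps >= d)
    } else {
      sum(reps <= d)
    }
    p[ci] <- min(1, 2 * k / length(reps))
  }
  list(delta_s = obs, p = p)
}

# Inline zero-truncated negative binomial mean, kept separate from the
# package's ztnb_mean().
oracle_ztnb_mean <- function(mu, size) {
  mu / (1 - (size / (size + mu))^size)
}
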