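#' Inject a true between-soil difference in selection into a config
#'
#' Returns a modified generator configuration whose true overall-fitness
#' soil contrast at `site`, `delta_s_true = s(local soil) - s(non-local
#' soil)`, equals `delta_s` exactly. The effect is injected by rescaling the
#' non-local ecotype's mean seeds per fruit on the non-local soil at that
#' site: overall expected fitness is linear in the seed mean, so the required
#' factor has a closed form. Writing `s_l` and `s_nl` for the base config's
#' true overall selection on the two soils, the non-local relative fitness on
#' the non-local soil must become `1 - s_l + delta_s`, so the seed mean is
#' multiplied by `(1 - s_l + delta_s) / (1 - s_nl)`.
#'
#' Only the seed-mean channel is perturbed (it touches exactly one component
#' and inverts in closed form); `delta_s = 0` returns the config unchanged.
#'
#' @param base A [generator_config()].
#' @param site Site label at which to inject the effect.
#' @param delta_s Target true soil contrast on the overall-fitness selection
#'   scale. Values making the implied non-local mean non-positive are
#'   rejected.
#' @return A [generator_config()].
#' @export
inject_soil_effect <- function(base, site, delta_s) {
  stopifnot(inherits(base, "generator_config"))
  if (!site %in% base$sites) {
    stop("Unknown site: ", site, call. = FALSE)
  }
  if (delta_s == 0) {
    return(base)
  }
  te <- derive_true_effects(base)
  s_tab <- te$s_true[te$s_true$site == site & te$s_true$component == "overall", ]
  nonlocal_soil <- setdiff(base$sites, site)
  nonlocal_eco <- setdiff(base$sites, site)
  s_l <- s_tab$s_true[s_tab$soil == site]
  s_nl <- s_tab$s_true[s_tab$soil == nonlocal_soil]
  target_rel <- 1 - s_l + delta_s # required w_nl / w_l on the non-local soil
  if (target_rel <= 0) {
    stop(
      "delta_s = ", delta_s, " would require a non-positive non-local mean ",
      "fitness at site '", site, "'",
      call. = FALSE
    )
  }
  factor <- target_rel / (1 - s_nl)
  out <- base
  sel <- out$cells$site == site & out$cells$soil == nonlocal_soil &
    out$cells$ecotype == nonlocal_eco
  out$cells$seed_mean[sel] <- out$cells$seed_mean[sel] * factor
  out
}

#' Define a power-analysis scenario
#'
#' A grid of injected true soil contrasts and per-cell sample sizes over
#' which to measure the operating characteristics of the soil-permutation
#' test by Monte Carlo simulation.
#'
#' @param base_config A [generator_config()] describing the no-soil-effect
#'   baseline (site-level selection only).
#' @param delta_s_grid Numeric vector of injected true `delta_s` values
#'   (overall-fitness selection scale).
#' @param n_grid Integer vector of per-cell sample sizes; every design cell
#'   is set to the same size.
#' @param n_sims Simulated datasets per grid point.
#' @param alpha Nominal level of the test (default 0.05).
#' @param site Site at which the effect is injected and the test evaluated;
#'   default the first site of `base_config`.
#' @param seed Integer RNG seed for the whole sweep.
#' @return An object of class `power_scenario`.
#' @export
power_scenario <- function(base_config, delta_s_grid, n_grid, n_sims = 200L,
                           alpha = 0.05, site = NULL, seed = 1L) {
  stopifnot(inherits(base_config, "generator_config"))
  if (is.null(site)) site <- base_config$sites[1]
  if (!site %in% base_config$sites) stop("Unknown site: ", site, call. = FALSE)
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  if (length(n_grid) > 0 && any(n_grid < 1)) {
    stop("n_grid entries must be >= 1", call. = FALSE)
  }
  structure(
    list(
      base_config = base_config,
      delta_s_grid = as.numeric(delta_s_grid),
      n_grid = as.integer(n_grid),
      n_sims = n_sims, alpha = alpha, site = site, seed = as.integer(seed)
    ),
    class = "power_scenario"
  )
}

#' Monte Carlo power of the soil-permutation test
#'
#' For every (delta_s, n) grid point, generates `n_sims` cohorts from the
#' base configuration with the effect injected via [inject_soil_effect()],
#' runs [soil_contrast()], and records the rejection rate of the
#' overall-fitness contrast at the scenario's site at level `alpha`, its
#' Monte Carlo standard error `sqrt(r (1 - r) / n_sims)`, and the mean
#' estimated contrast.
#'
#' Power sweeps default to reduced resampling (no bootstrap, a few hundred
#' permutations) as a fidelity/runtime trade-off; pass a custom `plan` to
#' change this.
#'
#' @param scenario A [power_scenario()].
#' @param plan A [resampling_plan()] used for each simulated dataset; its
#'   seed is overridden per simulation from the scenario seed.
#' @param verbose Report progress per grid point.
#' @return A tibble with columns `delta_s, n, rejection_rate, mc_se,
#'   mean_delta_s_hat, n_sims`.
#' @export
run_power <- function(scenario,
                      plan = resampling_plan(n_boot = 0L, n_perm = 200L),
                      verbose = FALSE) {
  stopifnot(inherits(scenario, "power_scenario"))
  grid <- expand.grid(
    n = scenario$n_grid, delta_s = scenario$delta_s_grid,
    KEEP.OUT.ATTRS = FALSE
  )[c("delta_s", "n")]
  if (nrow(grid) == 0L) {
    warning("Empty power grid; returning an empty result table", call. = FALSE)
    return(tibble::tibble(
      delta_s = numeric(0), n = integer(0), rejection_rate = numeric(0),
      mc_se = numeric(0), mean_delta_s_hat = numeric(0), n_sims = integer(0)
    ))
  }
  set.seed(scenario$seed)
  seeds <- matrix(
    sample.int(2147483646L, nrow(grid) * scenario$n_sims * 2L),
    ncol = 2L
  )
  rows <- vector("list", nrow(grid))
  sim_idx <- 0L
  for (g in seq_len(nrow(grid))) {
    cfg <- scenario$base_config
    cfg$cells$n <- as.integer(grid$n[g])
    cfg <- inject_soil_effect(cfg, scenario$site, grid$delta_s[g])
    reject <- logical(scenario$n_sims)
    delta_hat <- numeric(scenario$n_sims)
    for (i in seq_len(scenario$n_sims)) {
      sim_idx <- sim_idx + 1L
      cfg$seed <- seeds[sim_idx, 1L]
      sim_plan <- plan
      sim_plan$seed <- seeds[sim_idx, 2L]
      contr <- soil_contrast(generate_cohort(cfg), plan = sim_plan)
      row <- contr[contr$site == scenario$site & contr$component == "overall", ]
      reject[i] <- !is.na(row$p_value) && row$p_value <= scenario$alpha
      delta_hat[i] <- row$delta_s
    }
    r <- mean(reject)
    rows[[g]] <- tibble::tibble(
      delta_s = grid$delta_s[g], n = as.integer(grid$n[g]),
      rejection_rate = r,
      mc_se = sqrt(r * (1 - r) / scenario$n_sims),
      mean_delta_s_hat = mean(delta_hat, na.rm = TRUE),
      n_sims = scenario$n_sims
    )
    if (verbose) {
      message(sprintf(
        "power: delta_s = %.4g, n = %d -> rejection rate %.3f (mc se %.3f)",
        grid$delta_s[g], grid$n[g], r, rows[[g]]$mc_se
      ))
    }
  }
  do.call(rbind, rows)
}

#' Read a power scenario from YAML
#'
#' Scalar fields `delta_s_grid`, `n_grid`, `n_sims`, `alpha`, `site`, `seed`,
#' plus an optional `base_config` block in [read_generator_config()] format
#' (defaults to the package's default design).
#'
#' @param path YAML file path.
#' @return A [power_scenario()].
#' @export
read_power_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  base <- if (!is.null(y$base_config)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(y$base_config, tmp)
    read_generator_config(tmp)
  } else {
    generator_config()
  }
  power_scenario(
    base_config = base,
    delta_s_grid = as.numeric(unlist(y$delta_s_grid)),
    n_grid = as.integer(unlist(y$n_grid)),
    n_sims = y$n_sims %||% 200L,
    alpha = y$alpha %||% 0.05,
    site = y$site %||% NULL,
    seed = y$seed %||% 1L
  )
}
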