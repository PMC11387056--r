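#' Configure the synthetic cohort generator
#'
#' The generator emulates the statistical structure of a two-site reciprocal
#' transplant experiment on two soils: per-cell Bernoulli survival to
#' reproduction, overdispersed (negative binomial) fruit counts among
#' survivors conditioned on being at least 1 (a reproductive plant has
#' fruits), and per-fruit viable-seed counts measured on a random subsample of
#' survivors (those that still had an intact mature fruit at harvest).
#'
#' The default design transplants 256 local and 264 non-local seedlings on
#' each soil type at each site (2080 seedlings in total across 8 cells); the
#' extra non-local plants compensate for their typically lower winter
#' survival. Default survival, fecundity and seed parameters describe strong
#' adaptive differentiation at both sites — roughly four- to six-fold overall
#' fitness advantages of the local ecotype — with fecundity-driven selection
#' at the first site and survival-driven selection at the second, and no soil
#' effect (both soils share all parameters within a site). A plant's ecotype
#' (and a soil) is "local" at a site when its label equals the site label.
#'
#' @param sites Character vector of the two site labels. Soils and ecotypes
#'   use the same label universe.
#' @param cells Optional data frame with one row per (site, soil, ecotype)
#'   cell and columns `site, soil, ecotype, n, surv_prob, fruit_mean,
#'   seed_mean`. Defaults to the 8-cell design described above.
#' @param fruit_dispersion,seed_dispersion Negative binomial size parameters
#'   for fruit and seed counts (larger is closer to Poisson).
#' @param measure_prob Probability that a reproductive plant contributes a
#'   seeds-per-fruit measurement, independent of its size
#'   (missing-completely-at-random subsampling).
#' @param seed Integer RNG seed; identical config implies identical cohort.
#' @return An object of class `generator_config`.
#' @seealso [generate_cohort()], [derive_true_effects()]
#' @export
generator_config <- function(sites = c("Italy", "Sweden"),
                             cells = NULL,
                             fruit_dispersion = 1.5,
                             seed_dispersion = 8,
                             measure_prob = 0.7,
                             seed = 1L) {
  if (length(sites) != 2L || anyNA(sites) || sites[1] == sites[2]) {
    stop("'sites' must be two distinct labels", call. = FALSE)
  }
  sites <- as.character(sites)
  if (is.null(cells)) {
    cells <- default_cells(sites)
  }
  cells <- tibble::as_tibble(cells)
  cfg <- structure(
    list(
      sites = sites,
      cells = cells,
      fruit_dispersion = fruit_dispersion,
      seed_dispersion = seed_dispersion,
      measure_prob = measure_prob,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_config(cfg)
  cfg
}

# Default 8-cell parameter table. Site 1 shows fecundity-dominated selection
# (~4.4-fold overall local advantage), site 2 survival-dominated selection
# (~6.1-fold); soils are exchangeable within site (no true soil effect).
default_cells <- function(sites) {
  base <- list(
    # site 1: local then non-local
    list(surv = 0.75, fruit = 9.0, seed = 30),
    list(surv = 0.60, fruit = 3.6, seed = 19),
    # site 2: local then non-local
    list(surv = 0.70, fruit = 6.0, seed = 25),
    list(surv = 0.35, fruit = 3.0, seed = 14.5)
  )
  rows <- list()
  for (si in 1:2) {
    for (soil in sites) {
      for (eco in sites) {
        local <- eco == sites[si]
        par <- base[[(si - 1) * 2 + if (local) 1L else 2L]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          site = sites[si], soil = soil, ecotype = eco,
          n = if (local) 256L else 264L,
          surv_prob = par$surv, fruit_mean = par$fruit, seed_mean = par$seed
        )
      }
    }
  }
  do.call(rbind, rows)
}

validate_config <- function(cfg) {
  cells <- cfg$cells
  required <- c("site", "soil", "ecotype", "n", "surv_prob", "fruit_mean", "seed_mean")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("Config cells table is missing column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  labs <- cfg$sites
  full <- expand.grid(site = labs, soil = labs, ecotype = labs, stringsAsFactors = FALSE)
  key <- function(d) paste(d$site, d$soil, d$ecotype, sep = "\r")
  if (!setequal(key(cells), key(full)) || nrow(cells) != 8L) {
    stop("Config cells must cover each of the 8 site x soil x ecotype cells exactly once",
      call. = FALSE
    )
  }
  check_range <- function(x, name, lo, hi = Inf, open_lo = FALSE) {
    bad <- !is.finite(x) | (if (open_lo) x <= lo else x < lo) | x > hi
    if (any(bad)) {
      stop("Config field '", name, "' out of range", call. = FALSE)
    }
  }
  check_range(cells$n, "n", 0)
  check_range(cells$surv_prob, "surv_prob", 0, 1)
  check_range(cells$fruit_mean, "fruit_mean", 0, open_lo = TRUE)
  check_range(cells$seed_mean, "seed_mean", 0, open_lo = TRUE)
  check_range(cfg$fruit_dispersion, "fruit_dispersion", 0, open_lo = TRUE)
  check_range(cfg$seed_dispersion, "seed_dispersion", 0, open_lo = TRUE)
  check_range(cfg$measure_prob, "measure_prob", 0, 1)
  if (!is.finite(cfg$seed)) stop("Config field 'seed' must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "<generator_config> sites %s / %s; %d plants; fruit size %.3g, seed size %.3g, measure_prob %.3g, seed %d\n",
    x$sites[1], x$sites[2], sum(x$cells$n),
    x$fruit_dispersion, x$seed_dispersion, x$measure_prob, x$seed
  ))
  print(x$cells)
  invisible(x)
}

# Mean of a negative binomial (mean mu, size) truncated to >= 1.
# P(X = 0) = (size / (size + mu))^size, computed on the log scale so that the
# Poisson limit (size -> Inf) is stable.
ztnb_mean <- function(mu, size) {
  p0 <- exp(-size * log1p(mu / size))
  mu / (1 - p0)
}

# Draw zero-truncated negative binomial via inverse CDF: uniform on (P0, 1]
# pushed through qnbinom is exact and vectorized.
rztnbinom <- function(n, mu, size) {
  if (n == 0L) {
    return(integer(0))
  }
  p0 <- exp(-size * log1p(mu / size))
  u <- p0 + runif(n) * (1 - p0)
  as.integer(qnbinom(u, size = size, mu = mu))
}

#' Generate a synthetic cohort
#'
#' Draws, for every design cell, `n` plant records: survival is Bernoulli
#' with the cell's survival probability; survivors receive a zero-truncated
#' negative binomial fruit count with the cell's (untruncated) mean and the
#' shared dispersion; each survivor contributes a seeds-per-fruit count with
#' probability `measure_prob`, drawn negative binomial with the cell's seed
#' mean. Identical config (including seed) yields an identical cohort.
#'
#' @param config A [generator_config()].
#' @return A [cohort()] with no edge records, metadata recording the seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_config(config)
  set.seed(config$seed)
  cells <- config$cells
  parts <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    n <- cell$n
    survived <- runif(n) < cell$surv_prob
    fruits <- integer(n)
    n_surv <- sum(survived)
    fruits[survived] <- rztnbinom(n_surv, mu = cell$fruit_mean, size = config$fruit_dispersion)
    seeds <- rep(NA_integer_, n)
    measured <- survived & (runif(n) < config$measure_prob)
    seeds[measured] <- as.integer(rnbinom(sum(measured),
      size = config$seed_dispersion, mu = cell$seed_mean
    ))
    parts[[i]] <- tibble::tibble(
      plant_id = sprintf(
        "%s.%s.%s.%04d", cell$site, cell$soil, cell$ecotype, seq_len(n)
      ),
      site = cell$site, soil = cell$soil, ecotype = cell$ecotype,
      survived = survived, fruits = fruits, seeds_per_fruit = seeds,
      edge = FALSE
    )
  }
  cohort(do.call(rbind, parts), metadata = list(generator_seed = config$seed))
}

#' True fitness components and selection coefficients implied by a config
#'
#' Computes, in closed form, the per-cell expected fitness components the
#' generator targets — survival probability, zero-truncated mean fruits per
#' reproductive plant, mean seeds per fruit, and their product (expected seeds
#' per planted seedling) — and the implied true selection coefficients
#' `s = 1 - w_nonlocal / w_local` for each site, soil and component, plus the
#' true between-soil difference in overall-fitness selection at each site,
#' `delta_s = s(local soil) - s(non-local soil)`.
#'
#' The fruit component uses the zero-truncated mean (the generator conditions
#' fruit counts of reproductive plants on being at least 1), so these truths
#' are exact for the generator's sampling model. The seeds-per-fruit truth is
#' the measurement-model mean: subsampling of survivors for seed counting is
#' assumed unbiased.
#'
#' @param config A [generator_config()].
#' @return A list with class `true_effects`: `cell_means` (tibble of expected
#'   components per cell), `s_true` (tibble site/soil/component/s_true) and
#'   `delta_s_true` (named numeric, overall-fitness scale, one per site).
#' @export
derive_true_effects <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_config(config)
  cells <- config$cells
  cells$fecundity <- ztnb_mean(cells$fruit_mean, config$fruit_dispersion)
  cells$overall <- cells$surv_prob * cells$fecundity * cells$seed_mean
  comps <- component_levels()
  sites <- config$sites
  s_rows <- list()
  for (site in sites) {
    local_eco <- site
    nonlocal_eco <- setdiff(sites, site)
    for (soil in sites) {
      loc <- cells[cells$site == site & cells$soil == soil & cells$ecotype == local_eco, ]
      non <- cells[cells$site == site & cells$soil == soil & cells$ecotype == nonlocal_eco, ]
      w_l <- c(loc$surv_prob, loc$fecundity, loc$seed_mean, loc$overall)
      w_n <- c(non$surv_prob, non$fecundity, non$seed_mean, non$overall)
      if (any(w_l == 0)) {
        stop(
          "True selection undefined: local-ecotype mean is zero in cell (",
          site, ", ", soil, ")",
          call. = FALSE
        )
      }
      s_rows[[length(s_rows) + 1L]] <- tibble::tibble(
        site = site, soil = soil, component = comps, s_true = 1 - w_n / w_l
      )
    }
  }
  s_true <- do.call(rbind, s_rows)
  delta <- vapply(sites, function(site) {
    s_site <- s_true[s_true$site == site & s_true$component == "overall", ]
    s_site$s_true[s_site$soil == site] -
      s_site$s_true[s_site$soil == setdiff(sites, site)]
  }, numeric(1))
  structure(
    list(
      cell_means = cells[c(
        "site", "soil", "ecotype", "surv_prob", "fecundity",
        "seed_mean", "overall"
      )],
      s_true = s_true,
      delta_s_true = delta
    ),
    class = "true_effects"
  )
}

#' @export
print.true_effects <- function(x, ...) {
  cat("<true_effects>\n")
  print(x$s_true)
  cat("delta_s_true (overall):\n")
  print(x$delta_s_true)
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML mirrors [generator_config()]: scalar fields plus a `cells` list
#' of 8 per-cell maps.
#'
#' @param path YAML file path.
#' @return For `read_generator_config`, a [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  cells <- NULL
  if (!is.null(y$cells)) {
    cells <- do.call(rbind, lapply(y$cells, function(r) tibble::as_tibble(r)))
  }
  generator_config(
    sites = y$sites %||% c("Italy", "Sweden"),
    cells = cells,
    fruit_dispersion = y$fruit_dispersion %||% 1.5,
    seed_dispersion = y$seed_dispersion %||% 8,
    measure_prob = y$measure_prob %||% 0.7,
    seed = y$seed %||% 1L
  )
}

#' @rdname read_generator_config
#' @param config A [generator_config()] to serialize.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  y <- list(
    sites = config$sites,
    fruit_dispersion = config$fruit_dispersion,
    seed_dispersion = config$seed_dispersion,
    measure_prob = config$measure_prob,
    seed = config$seed,
    cells = lapply(seq_len(nrow(config$cells)), function(i) as.list(config$cells[i, ]))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
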