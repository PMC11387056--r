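#' Plot per-cell fitness component means with bootstrap CIs
#'
#' A plain means-and-intervals display: one panel per fitness component, cell
#' means with stratified-bootstrap percentile intervals, ecotypes side by
#' side within each site-soil combination.
#'
#' @param x A [cohort()].
#' @param plan A [resampling_plan()] (only `n_boot`, `ci_level` and `seed`
#'   are used).
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
plot_cell_means <- function(x, plan = resampling_plan(n_boot = 500L)) {
  p <- prep_analysis(x)
  idx_full <- lapply(1:8, function(k) which(p$stratum == k))
  point <- stats_by_stratum(p, idx_full)
  alpha <- (1 - plan$ci_level) / 2
  boot <- array(NA_real_, dim = c(plan$n_boot, 8L, 4L))
  set.seed(plan$seed)
  sizes <- lengths(idx_full)
  for (b in seq_len(plan$n_boot)) {
    idx_b <- lapply(1:8, function(k) {
      if (sizes[k] > 0L) idx_full[[k]][sample.int(sizes[k], sizes[k], replace = TRUE)] else integer(0)
    })
    boot[b, , ] <- stats_by_stratum(p, idx_b)
  }
  labs <- p$labs
  rows <- list()
  for (k in 1:8) {
    si <- (k - 1L) %/% 4L + 1L
    so <- ((k - 1L) %/% 2L) %% 2L + 1L
    e <- (k - 1L) %% 2L + 1L
    for (ci in 1:4) {
      reps <- boot[, k, ci]
      reps <- reps[!is.na(reps)]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = labs[si], soil = paste(labs[so], "soil"), ecotype = labs[e],
        component = component_levels()[ci],
        mean = point[k, ci],
        ci_low = if (length(reps)) quantile(reps, alpha, names = FALSE) else NA_real_,
        ci_high = if (length(reps)) quantile(reps, 1 - alpha, names = FALSE) else NA_real_
      )
    }
  }
  d <- do.call(rbind, rows)
  d$component <- factor(d$component, levels = component_levels())
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = interaction(.data$soil, .data$site, sep = "\n"),
      y = .data$mean, colour = .data$ecotype
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "cell mean (95% bootstrap CI)", colour = "ecotype") +
    ggplot2::theme_minimal()
}

#' Plot a power curve
#'
#' @param results Output of [run_power()].
#' @return A ggplot object: rejection rate against injected `delta_s`, one
#'   line per per-cell sample size, with +/- 2 Monte Carlo SE ribbons.
#' @export
plot_power <- function(results) {
  results$n <- factor(results$n)
  ggplot2::ggplot(
    results,
    ggplot2::aes(x = .data$delta_s, y = .data$rejection_rate, colour = .data$n)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(0, .data$rejection_rate - 2 * .data$mc_se),
        ymax = pmin(1, .data$rejection_rate + 2 * .data$mc_se),
        fill = .data$n
      ),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(paste("injected true ", Delta * s, " (overall fitness)")),
      y = "rejection rate", colour = "n per cell", fill = "n per cell"
    ) +
    ggplot2::theme_minimal()
}
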