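small_config <- function(n = 50L, seed = 1L, ...) {
  cfg <- generator_config(seed = seed, ...)
  cfg$cells$n <- as.integer(n)
  cfg
}

test_that("survival and measurement probabilities act as hard boundaries", {
  cfg <- small_config(n = 40L)
  cfg$cells$surv_prob[1] <- 0
  co <- generate_cohort(cfg)
  cell1 <- co$records[co$records$site == cfg$cells$site[1] &
    co$records$soil == cfg$cells$soil[1] &
    co$records$ecotype == cfg$cells$ecotype[1], ]
  expect_true(all(!cell1$survived))
  expect_true(all(cell1$fruits == 0L))
  expect_true(all(is.na(cell1$seeds_per_fruit)))

  cfg2 <- small_config(n = 40L, measure_prob = 1)
  cfg2$cells$surv_prob <- 1
  co2 <- generate_cohort(cfg2)
  expect_true(all(co2$records$survived))
  expect_true(all(co2$records$fruits >= 1L))
  expect_true(all(!is.na(co2$records$seeds_per_fruit)))
})

test_that("identical config and seed reproduce a byte-identical cohort file", {
  cfg <- small_config(n = 30L, seed = 99L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the data
  cfg2 <- small_config(n = 30L, seed = 100L)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg2), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("fruit counts of survivors match the zero-truncated negative binomial mean", {
  cfg <- small_config(n = 10000L, seed = 7L)
  cfg$cells$surv_prob <- 1
  cfg$cells$fruit_mean[1] <- 8
  co <- generate_cohort(cfg)
  cell1 <- co$records[co$records$site == cfg$cells$site[1] &
    co$records$soil == cfg$cells$soil[1] &
    co$records$ecotype == cfg$cells$ecotype[1], ]
  truth <- oracle_ztnb_mean(8, cfg$fruit_dispersion)
  se <- stats::sd(cell1$fruits) / sqrt(nrow(cell1))
  expect_lt(abs(mean(cell1$fruits) - truth), 3 * se)
  expect_true(all(cell1$fruits >= 1L))
  # and the analytic truth exceeds the untruncated mean
  expect_gt(truth, 8)
})

test_that("derive_true_effects matches closed-form arithmetic", {
  # all 8 cells identical: no selection anywhere, exactly
  cfg <- generator_config()
  cfg$cells$surv_prob <- 0.5
  cfg$cells$fruit_mean <- 5
  cfg$cells$seed_mean <- 20
  te <- derive_true_effects(cfg)
  expect_true(all(te$s_true$s_true == 0))
  expect_true(all(te$delta_s_true == 0))

  # survival and fruits equal, local seed mean 10x the non-local:
  # s = 0.9 through seeds and overall, 0 elsewhere
  cfg2 <- cfg
  local <- cfg2$cells$ecotype == cfg2$cells$site
  cfg2$cells$seed_mean <- ifelse(local, 40, 4)
  te2 <- derive_true_effects(cfg2)
  s2 <- te2$s_true
  expect_equal(s2$s_true[s2$component == "overall"], rep(0.9, 4))
  expect_equal(s2$s_true[s2$component == "seeds_per_fruit"], rep(0.9, 4))
  expect_equal(s2$s_true[s2$component == "survival"], rep(0, 4))

  # a 4.4-fold overall fitness ratio implies s = 1 - 1/4.4
  cfg3 <- cfg
  cfg3$cells$seed_mean <- ifelse(local, 44, 10)
  te3 <- derive_true_effects(cfg3)
  expect_equal(
    te3$s_true$s_true[te3$s_true$component == "overall"],
    rep(1 - 1 / 4.4, 4)
  )

  # the fecundity truth is the zero-truncated mean, not the raw parameter
  cfg4 <- cfg
  cfg4$cells$fruit_mean <- ifelse(local, 8, 2)
  te4 <- derive_true_effects(cfg4)
  expected <- 1 - oracle_ztnb_mean(2, cfg4$fruit_dispersion) /
    oracle_ztnb_mean(8, cfg4$fruit_dispersion)
  expect_equal(
    te4$s_true$s_true[te4$s_true$component == "fecundity"],
    rep(expected, 4)
  )
  untruncated <- 1 - 2 / 8
  expect_false(isTRUE(all.equal(expected, untruncated)))
})

test_that("the default design is soil-null and sized to the field experiment", {
  cfg <- generator_config()
  expect_equal(sum(cfg$cells$n), 2080L)
  local <- cfg$cells$ecotype == cfg$cells$site
  expect_true(all(cfg$cells$n[local] == 256L))
  expect_true(all(cfg$cells$n[!local] == 264L))
  te <- derive_true_effects(cfg)
  expect_identical(unname(te$delta_s_true), c(0, 0))
})

test_that("invalid configs are rejected naming the offending field", {
  cfg <- generator_config()
  cfg$cells$surv_prob[2] <- 1.2
  expect_error(generate_cohort(cfg), "surv_prob")
  cfg2 <- generator_config()
  cfg2$cells$fruit_mean[1] <- 0
  expect_error(generate_cohort(cfg2), "fruit_mean")
  cfg3 <- generator_config()
  cfg3$cells <- cfg3$cells[-1, ]
  expect_error(generate_cohort(cfg3), "8 site x soil x ecotype cells")
  expect_error(generator_config(measure_prob = -0.1), "measure_prob")
})

test_that("analysis-side point estimates converge to the generator truths", {
  cfg <- small_config(n = 20000L, seed = 11L)
  co <- generate_cohort(cfg)
  plan <- resampling_plan(n_boot = 100L, seed = 3L)
  est <- estimate_selection(co, plan = plan)
  te <- derive_true_effects(cfg)
  merged <- merge(est, te$s_true, by = c("site", "soil", "component"))
  expect_equal(nrow(merged), 16L)
  # bootstrap SD as the Monte Carlo scale for each estimate
  for (i in seq_len(nrow(merged))) {
    half_width <- (merged$ci_high[i] - merged$ci_low[i]) / (2 * 1.96)
    expect_lt(
      abs(merged$s_hat[i] - merged$s_true[i]),
      3 * max(half_width, 1e-4)
    )
  }
})

test_that("generator configs round-trip through YAML", {
  cfg <- small_config(n = 12L, seed = 5L, measure_prob = 0.6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$cells, cfg$cells)
  expect_equal(back$measure_prob, 0.6)
  expect_equal(back$seed, cfg$seed)
  expect_identical(
    generate_cohort(back)$records,
    generate_cohort(cfg)$records
  )
})
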