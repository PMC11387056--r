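test_that("the selection coefficient follows s = 1 - w_nonlocal / w_local", {
  expect_equal(selection_coefficient(10, 5), 0.5)
  expect_equal(selection_coefficient(7, 7), 0)
  expect_equal(selection_coefficient(5, 10), -1)
  expect_equal(selection_coefficient(3, 0), 1)
  expect_true(is.na(selection_coefficient(0, 3)))
  expect_true(is.na(selection_coefficient(0, 0)))
  expect_error(selection_coefficient(-1, 2), "non-negative")
  expect_error(selection_coefficient(1, -2), "non-negative")
})

test_that("s is monotone in non-local fitness, scale invariant, and bounded by 1", {
  set.seed(424)
  for (i in 1:1000) {
    w_l <- stats::runif(1, 0.01, 100)
    w_n1 <- stats::runif(1, 0, 100)
    w_n2 <- w_n1 + stats::runif(1, 0.01, 10)
    expect_gt(
      selection_coefficient(w_l, w_n1),
      selection_coefficient(w_l, w_n2)
    )
    c_scale <- stats::runif(1, 0.01, 50)
    expect_equal(
      selection_coefficient(c_scale * w_l, c_scale * w_n1),
      selection_coefficient(w_l, w_n1),
      tolerance = 1e-12
    )
    expect_lte(selection_coefficient(w_l, w_n1), 1)
  }
})

test_that("zero-variance strata give degenerate bootstrap intervals equal to the point estimate", {
  # every plant within a stratum identical: all resamples reproduce the data
  rows <- list()
  id <- 0L
  for (site in c("A", "B")) {
    for (soil in c("A", "B")) {
      for (eco in c("A", "B")) {
        fruits <- if (eco == site) 10L else 5L
        for (i in 1:3) {
          id <- id + 1L
          rows[[id]] <- record_row(
            paste0("p", id), site, soil, eco, TRUE, fruits, 20L
          )
        }
      }
    }
  }
  co <- cohort(do.call(rbind, rows))
  est <- estimate_selection(co, plan = resampling_plan(n_boot = 50L, seed = 2L))
  expect_equal(est$ci_low, est$s_hat)
  expect_equal(est$ci_high, est$s_hat)
  expect_equal(
    est$s_hat[est$component == "fecundity"], rep(0.5, 4)
  )
  expect_equal(est$n_boot_dropped, rep(0L, 16L))
})

test_that("estimate_selection recovers generator truths within bootstrap error", {
  cfg <- generator_config(seed = 61L)
  cfg$cells$n <- 2000L
  co <- generate_cohort(cfg)
  est <- estimate_selection(co, plan = resampling_plan(n_boot = 200L, seed = 6L))
  te <- derive_true_effects(cfg)
  merged <- merge(est, te$s_true, by = c("site", "soil", "component"))
  half_width <- (merged$ci_high - merged$ci_low) / (2 * 1.96)
  expect_true(all(abs(merged$s_hat - merged$s_true) < 4 * half_width))
})

test_that("n_boot = 0 skips intervals but keeps point estimates", {
  co <- make_full_cohort(per_cell = 4L)
  est <- estimate_selection(co, plan = resampling_plan(n_boot = 0L))
  expect_true(all(is.na(est$ci_low)))
  expect_true(all(is.na(est$ci_high)))
  expect_true(all(!is.na(est$s_hat)))
  expect_equal(est$n_boot_used, rep(0L, 16L))
})

test_that("analysis rejects bad label universes and missing local ecotypes", {
  bad <- cohort(rbind(
    record_row("p1", "A", "A", "A", TRUE, 2),
    record_row("p2", "B", "B", "C", TRUE, 2)
  ))
  expect_error(estimate_selection(bad), "two-label")

  missing_local <- cohort(rbind(
    record_row("p1", "A", "A", "B", TRUE, 2),
    record_row("p2", "A", "B", "B", TRUE, 2)
  ))
  expect_error(estimate_selection(missing_local), "local ecotype is absent")
})

test_that("sampled permutation p equals the exhaustive-enumeration oracle on small sites", {
  set.seed(88)
  # 8 plants per site, 2 per cell, fruit and seed values varied; everyone
  # survives so all components are defined in every permutation replicate
  rows <- list()
  id <- 0L
  for (site in c("A", "B")) {
    for (soil in c("A", "B")) {
      for (eco in c("A", "B")) {
        for (i in 1:2) {
          id <- id + 1L
          rows[[id]] <- record_row(
            paste0("p", id), site, soil, eco, TRUE,
            fruits = sample(1:12, 1), seeds = sample(5:30, 1)
          )
        }
      }
    }
  }
  co <- cohort(do.call(rbind, rows))
  df <- co$records

  for (tail in c("signed", "absolute")) {
    res <- soil_contrast(co,
      plan = resampling_plan(n_perm = 10L, seed = 1L, tail = tail),
      exhaustive = TRUE
    )
    for (site in c("A", "B")) {
      oracle <- oracle_exact_p(
        df[df$site == site, ],
        site_label = site,
        local_eco = site, nonlocal_eco = setdiff(c("A", "B"), site),
        tail = tail
      )
      got <- res[res$site == site, ]
      expect_equal(got$delta_s, unname(oracle$delta_s), tolerance = 1e-12)
      expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
      expect_equal(got$n_perm + got$n_perm_dropped, rep(choose(8L, 4L), 4L))
    }
  }
})

test_that("identical soils within site give delta_s = 0 and p capped at 1", {
  rows <- list()
  id <- 0L
  for (site in c("A", "B")) {
    for (eco in c("A", "B")) {
      for (i in 1:2) {
        for (soil in c("A", "B")) {
          id <- id + 1L
          # the two soils receive literally identical records
          rows[[id]] <- record_row(
            paste0("p", id), site, soil, eco, TRUE,
            fruits = 3L + i + (eco == site) * 5L, seeds = 10L + i
          )
        }
      }
    }
  }
  co <- cohort(do.call(rbind, rows))
  res <- soil_contrast(co, plan = resampling_plan(seed = 4L), exhaustive = TRUE)
  expect_equal(res$delta_s, rep(0, 8))
  expect_equal(res$p_value, rep(1, 8))
})

test_that("relabelling which soil is local negates delta_s and preserves p", {
  co <- make_full_cohort(per_cell = 3L)
  plan <- resampling_plan(n_perm = 50L, seed = 9L)
  res <- soil_contrast(co, plan = plan, exhaustive = TRUE)

  # swap the soil labels everywhere: what was the local soil becomes non-local
  swapped_rec <- co$records
  swapped_rec$soil <- ifelse(swapped_rec$soil == "A", "B", "A")
  res_swapped <- soil_contrast(cohort(swapped_rec), plan = plan, exhaustive = TRUE)

  expect_equal(res_swapped$delta_s, -res$delta_s, tolerance = 1e-12)
  expect_equal(res_swapped$p_value, res$p_value, tolerance = 1e-12)
})

test_that("permutation p values are honestly reported with the add-one correction", {
  co <- make_full_cohort(per_cell = 3L)
  plan <- resampling_plan(n_perm = 19L, seed = 10L)
  res <- soil_contrast(co, plan = plan)
  # with k exceedances out of n valid, p = min(1, 2 (1 + k) / (n + 1)) > 0
  expect_true(all(res$p_value > 0))
  expect_true(all(res$p_value <= 1))
  expect_true(all(res$p_value >= 2 / (res$n_perm + 1)))

  plain <- soil_contrast(
    co,
    plan = resampling_plan(n_perm = 19L, seed = 10L, plain_p = TRUE)
  )
  # same permutations under the same seed, plain proportion convention
  expect_true(all(plain$p_value <= res$p_value + 1e-12))
})
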