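# Synthetic cohort generator: determinism, demographic structure, stream
# invariants, parity null/effect construction.

test_that("configuration validation rejects malformed inputs", {
  expect_error(cohort_config(group_probs = c(0.5, 0.4, 0.2)), class = "ctgdss_config_error")
  expect_error(cohort_config(nulliparous_duration_multiplier = 0.8), class = "ctgdss_config_error")
  expect_error(cohort_config(nulliparity_prob_by_group = c(0.5, 1.2, 0.3)), class = "ctgdss_config_error")
  bad_trans <- matrix(c(0.5, 0.25, 0.25, 1, 0, 0, 1, 0, 0), 3, byrow = TRUE)
  expect_error(
    group_dynamics(fhr_trans = bad_trans), # non-zero diagonal
    class = "ctgdss_config_error"
  )
})

test_that("identical configurations reproduce the cohort bit for bit", {
  a <- make_small_cohort(n = 40, seed = 7)
  b <- make_small_cohort(n = 40, seed = 7)
  expect_identical(a$births, b$births)
  expect_identical(a$events, b$events)
})

test_that("degenerate group probabilities yield a single-group cohort", {
  cfg <- cohort_config(n_births = 50, group_probs = c(1, 0, 0), seed = 3)
  coh <- sample_cohort(cfg, simulate_streams = FALSE)
  expect_true(all(coh$births$group == "healthy"))
})

test_that("event streams cover the labor exactly and satisfy run invariants", {
  coh <- make_small_cohort(n = 25, seed = 11)
  expect_identical(nrow(validate_cohort(coh)), 0L)
  cover <- dplyr::summarise(
    dplyr::group_by(coh$events, id, channel),
    total = sum(dwell_s), .groups = "drop"
  )
  cover <- dplyr::left_join(cover, coh$births[, c("id", "duration_min")], by = "id")
  expect_equal(cover$total, cover$duration_min * 60, tolerance = 1e-12)
})

test_that("nulliparous prevalence matches the configured group-wise rates", {
  # overall share under the default mixture
  coh <- sample_cohort(cohort_config(n_births = 40000, seed = 2), simulate_streams = FALSE)
  frac <- mean(coh$births$parity == "nulliparous")
  expect_lt(abs(frac - 0.584), 2 * sqrt(0.584 * 0.416 / 40000))

  # per-group rates on an enriched draw
  cfg <- cohort_config(
    n_births = 10000, group_probs = c(0.4, 0.3, 0.3), seed = 5
  )
  coh2 <- sample_cohort(cfg, simulate_streams = FALSE)
  p_ref <- c(healthy = 0.578, acidosis = 0.645, hie = 0.668)
  for (g in names(p_ref)) {
    b <- coh2$births[coh2$births$group == g, ]
    se <- sqrt(p_ref[[g]] * (1 - p_ref[[g]]) / nrow(b))
    expect_lt(abs(mean(b$parity == "nulliparous") - p_ref[[g]]), 1.96 * se)
  }
})

test_that("nulliparous labors are stochastically longer", {
  coh <- sample_cohort(cohort_config(n_births = 4000, seed = 13), simulate_streams = FALSE)
  d_np <- coh$births$duration_min[coh$births$parity == "nulliparous"]
  d_mp <- coh$births$duration_min[coh$births$parity == "multiparous"]
  expect_gt(median(d_np), 1.2 * median(d_mp))
})

test_that("caesarean labels follow the configured group-by-parity rates", {
  rates0 <- matrix(0, 3, 2)
  coh0 <- sample_cohort(
    cohort_config(n_births = 200, caesarean_rate_by_group_parity = rates0, seed = 1),
    simulate_streams = FALSE
  )
  expect_false(any(coh0$births$caesarean))
  rates1 <- matrix(1, 3, 2)
  coh1 <- sample_cohort(
    cohort_config(n_births = 200, caesarean_rate_by_group_parity = rates1, seed = 1),
    simulate_streams = FALSE
  )
  expect_true(all(coh1$births$caesarean))

  coh <- sample_cohort(cohort_config(n_births = 20000, seed = 17), simulate_streams = FALSE)
  hn <- coh$births[coh$births$group == "healthy" & coh$births$parity == "nulliparous", ]
  se <- sqrt(0.416 * (1 - 0.416) / nrow(hn))
  expect_lt(abs(mean(hn$caesarean) - 0.416), 2 * se)
})

test_that("without dropouts every fully covered epoch is fully valid", {
  coh <- make_small_cohort(n = 15, seed = 23, dropout = 0)
  expect_false(any(coh$events$state == "invalid"))
  ep <- segment_epochs(coh)
  expect_true(all(ep$epochs$valid_fraction >= 0.8))
  full <- floor(coh$births$duration_min[match(ep$epochs$id, coh$births$id)] / 20)
  covered <- ep$epochs$epoch_index < full
  expect_true(all(ep$epochs$valid_fraction[covered] == 1))
})

test_that("with the parity null, streams given duration are identical across parity", {
  cfg <- cohort_config(n_births = 1, parity_dynamics_effect = 0, seed = 1)
  set.seed(42)
  a <- simulate_labor("hie", "nulliparous", 90, cfg)
  set.seed(42)
  b <- simulate_labor("hie", "multiparous", 90, cfg)
  expect_identical(a, b)
})

test_that("a positive parity effect raises nulliparous deceleration occupancy", {
  cfg <- cohort_config(n_births = 1, parity_dynamics_effect = 2, seed = 1)
  occ <- function(parity, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      lab <- simulate_labor("hie", parity, 60, cfg)
      fhr <- lab$fhr
      sum(fhr$dwell_s[fhr$state == "deceleration"]) / sum(fhr$dwell_s)
    }, numeric(1))
  }
  o_np <- occ("nulliparous", 1:150)
  o_mp <- occ("multiparous", 151:300)
  expect_gt(mean(o_np), mean(o_mp))
  expect_lt(rank_sum_test(o_np, o_mp)$p_value, 0.01)
})

test_that("under the null, epoch features are parity-invariant within group", {
  coh <- sample_cohort(cohort_config(
    n_births = 500, group_probs = c(1, 0, 0),
    duration_mean_multiparous_min = 80, seed = 31
  ))
  fe <- extract_features(segment_epochs(coh), coh$births)
  e1 <- fe[fe$epoch_index == 1, ]
  dec <- e1$occ_D.C + e1$occ_D.R
  p <- rank_sum_test(
    dec[e1$parity == "nulliparous"],
    dec[e1$parity == "multiparous"]
  )$p_value
  expect_gt(p, 0.01)
})

test_that("doubled deceleration dynamics raise mean deceleration occupancy", {
  dyn_hi <- default_dynamics()
  dyn_hi$healthy <- group_dynamics(
    fhr_dwell_s = c(baseline = 150, acceleration = 25, deceleration = 50),
    fhr_trans = ctgdss:::default_fhr_trans(0.6),
    up_dwell_s = c(contraction = 60, rest = 190),
    coupling = 0.3
  )
  occ_for <- function(dynamics, seeds) {
    cfg <- cohort_config(n_births = 1, dynamics = dynamics, seed = 1)
    vapply(seeds, function(s) {
      set.seed(s)
      fhr <- simulate_labor("healthy", "multiparous", 45, cfg)$fhr
      sum(fhr$dwell_s[fhr$state == "deceleration"]) / sum(fhr$dwell_s)
    }, numeric(1))
  }
  base <- occ_for(default_dynamics(), 1:100)
  high <- occ_for(dyn_hi, 101:200)
  expect_gt(mean(high), mean(base))
})
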