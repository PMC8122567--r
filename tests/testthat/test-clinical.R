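test_that("H-score reproduces hand-computed values and bounds", {
  expect_equal(h_score(100, 3), 300)
  expect_equal(h_score(100, 0), 0)
  expect_equal(h_score(c(50, 25, 25), c(1, 2, 3)), 175)
  expect_error(h_score(c(60, 60), c(1, 2)), "more than 100")
  expect_error(h_score(50, 4), "grades")
  expect_error(h_score(-5, 1), "\\[0,100\\]")
  # bounded by 300 over random valid inputs; zero iff stained grades are zero
  set.seed(1)
  for (i in 1:25) {
    pi_ <- diff(c(0, sort(runif(3, 0, 100)))); int <- sample(0:3, 3, TRUE)
    s <- h_score(pi_, int)
    expect_lte(s, 300)
    expect_equal(s == 0, all(int[pi_ > 0] == 0))
  }
})

test_that("tumor volume and migration area follow their formulas", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(0, 0), 0)
  expect_warning(v <- tumor_volume(5, 10), "swapped")
  expect_equal(v, 125)
  expect_error(tumor_volume(-1, 1), "non-negative")

  expect_equal(relative_migration_area(100, 60), 40)
  expect_equal(relative_migration_area(80, 80), 0)
  expect_equal(relative_migration_area(50, 0), 100)
  expect_error(relative_migration_area(0, 10), "positive")
})

test_that("risk groups follow the median-cutoff rule with ties excluded", {
  rec <- data.frame(
    patient_id = paste0("p", 1:5),
    psi = c(0.2, 0.8, 0.2, 0.5, 0.8),
    expression = c(90, 10, 10, 50, 95))
  # medians: psi 0.5, expression 50
  out <- assign_risk_groups(rec)
  expect_equal(out$risk_group,
               c("high",       # low PSI, high expression
                 "low",        # high PSI, low expression
                 "excluded",   # low PSI but low expression (mixed)
                 "excluded",   # ties both cutoffs
                 "excluded"))  # concordant-high profile has no risk home
  expect_equal(attr(out, "psi_cutoff"), 0.5)
  # all-identical values: everyone ties the cutoff
  same <- data.frame(psi = rep(0.4, 4), expression = rep(7, 4))
  expect_warning(o2 <- assign_risk_groups(same), "no patient")
  expect_true(all(o2$risk_group == "excluded"))
  expect_error(assign_risk_groups(data.frame(psi = 1, expression = 1)),
               ">= 2")
})

test_that("KM estimator matches hand product-limit computation", {
  k1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(k1$n_risk, c(3, 2, 1))

  k2 <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(k2$survival, 0.5)
  expect_equal(k2$time, 5)

  # all censored: survival stays at 1 (no event rows)
  k3 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_equal(nrow(k3), 0L)

  # censoring reduces risk sets only: oracle cross-check on random data
  set.seed(12)
  tm <- rexp(40); ev <- rbinom(40, 1, 0.7)
  k4 <- km_estimate(tm, ev)
  expect_equal(k4$survival, km_oracle(tm, ev))
  expect_true(all(diff(k4$survival) <= 1e-12))  # non-increasing

  # no censoring: KM equals the empirical survival function
  k5 <- km_estimate(1:10, rep(1, 10))
  expect_equal(k5$survival, (9:0) / 10)
  expect_error(km_estimate(-1, 1), "negative")
})

test_that("log-rank behaves under identical groups and label swaps", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4); ev <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  r <- logrank_test(tm, ev, g)
  expect_equal(r$chi_square, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
  # swapping labels leaves the statistic unchanged
  tm2 <- c(1, 5, 2, 8, 3, 9, 4, 12); ev2 <- c(1, 1, 1, 0, 1, 1, 0, 1)
  r1 <- logrank_test(tm2, ev2, g)
  r2 <- logrank_test(tm2, ev2, rev(g))
  expect_equal(r1$chi_square, r2$chi_square, tolerance = 1e-9)
  expect_warning(r0 <- logrank_test(c(1, 2), c(0, 0), c("a", "b")),
                 "no events")
  expect_true(is.na(r0$p_value))
})

test_that("permutation log-rank p agrees with exhaustive enumeration", {
  tm <- c(1, 3, 5, 7, 2, 9, 11, 14)
  ev <- c(1, 1, 1, 0, 1, 1, 1, 1)
  g <- rep(c("hi", "lo"), each = 4)
  exact <- logrank_perm_oracle(tm, ev, g)  # all C(8,4) relabelings
  B <- 4000
  r <- logrank_test(tm, ev, g, permutations = B, perm_seed = 3)
  mc_se <- sqrt(exact * (1 - exact) / B)
  expect_lt(abs(r$p_permutation - exact), 3 * mc_se + 2 / B)
})

test_that("log-rank has power at hazard ratio 3 and risk groups separate", {
  hits <- 0L
  for (s in 1:20) {
    co <- simulate_survival_cohort(500, c(high = 0.06, low = 0.02),
                                   censor_rate = 0.2, seed = 1000 + s)
    p <- logrank_test(co$time, co$event, co$latent_group)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of replicates reject

  rs <- risk_stratify(simulate_survival_cohort(400, seed = 2))
  expect_gt(rs$n_high, 0); expect_gt(rs$n_low, 0)
  expect_lt(rs$logrank$p_value, 0.01)
  # high-risk curve sits below low-risk at the shared horizon
  t_star <- min(max(rs$km$high$time), max(rs$km$low$time))
  s_at <- function(km, t) {
    i <- findInterval(t, km$time); if (i == 0) 1 else km$survival[i]
  }
  expect_lt(s_at(rs$km$high, t_star), s_at(rs$km$low, t_star))
})
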