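# Constant fitting: simulation of endpoint measurements, least-squares
# estimation of (K1, K2), and bootstrap confidence intervals.

test_that("simulate_measurements is exact at zero noise and reproducible", {
  conds <- measurement_conditions()
  d0 <- simulate_measurements(0.16, 0.35, conds, noise_cv = 0,
                              n_replicates = 2)
  truth <- vapply(seq_len(nrow(conds)), function(i) {
    solve_equilibrium(transglycosylation_system(
      0.16, 0.35, conds$N1_0_mM[i], conds$B2_0_mM[i],
      conds$P_0_mM[i]))$yield_fraction
  }, numeric(1))
  expect_equal(d0$yield_fraction, rep(truth, each = 2), tolerance = 1e-12)

  d1 <- simulate_measurements(0.16, 0.35, conds, noise_cv = 0.05,
                              n_replicates = 3, seed = 99)
  d2 <- simulate_measurements(0.16, 0.35, conds, noise_cv = 0.05,
                              n_replicates = 3, seed = 99)
  expect_identical(d1, d2)
  expect_identical(names(d1),
                   c("condition_id", "replicate", "N1_0_mM", "B2_0_mM",
                     "P_0_mM", "yield_fraction", "temperature_C", "pH"))
})

test_that("simulated noise has the requested coefficient of variation", {
  one <- measurement_conditions(phosphate_equivs = 1)
  d <- simulate_measurements(0.16, 0.35, one, noise_cv = 0.05,
                             n_replicates = 1000, seed = 5)
  cv <- sd(d$yield_fraction) / mean(d$yield_fraction)
  expect_gt(cv, 0.04)
  expect_lt(cv, 0.06)
})

test_that("noiseless fits recover the generating constants to machine precision", {
  d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
                             noise_cv = 0, n_replicates = 1)
  fit <- fit_constants(d)
  expect_equal(fit$K1_hat, 0.16, tolerance = 1e-6)
  expect_equal(fit$K2_hat, 0.35, tolerance = 1e-6)
  expect_lt(fit$loss, 1e-20)

  # loss at the truth is locally optimal against +/- 20 % perturbations
  loss_at <- function(K1, K2) {
    pred <- vapply(seq_len(nrow(d)), function(i) {
      solve_equilibrium(transglycosylation_system(
        K1, K2, d$N1_0_mM[i], d$B2_0_mM[i], d$P_0_mM[i]))$yield_fraction
    }, numeric(1))
    sum((pred - d$yield_fraction)^2)
  }
  for (f1 in c(0.8, 1, 1.2)) {
    for (f2 in c(0.8, 1, 1.2)) {
      if (f1 == 1 && f2 == 1) next
      expect_gt(loss_at(0.16 * f1, 0.35 * f2), loss_at(0.16, 0.35))
    }
  }
})

test_that("noisy fits recover both constants with small median error across seeds", {
  errs <- vapply(1:20, function(s) {
    d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
                               noise_cv = 0.05, n_replicates = 3, seed = s)
    fit <- fit_constants(d)
    c(abs(fit$K1_hat - 0.16) / 0.16, abs(fit$K2_hat - 0.35) / 0.35)
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.15)
  expect_lt(median(errs[2, ]), 0.15)
})

test_that("a single phosphate level is unidentifiable unless K1 is fixed", {
  one <- measurement_conditions(phosphate_equivs = 1)
  d <- simulate_measurements(0.16, 0.35, one, noise_cv = 0, n_replicates = 3)
  expect_error(fit_constants(d), "identifiable",
               class = "npyield_identifiability_error")
  fit <- fit_constants(d, fix_K1 = 0.16)
  expect_identical(fit$K1_hat, 0.16)
  expect_equal(fit$K2_hat, 0.35, tolerance = 1e-5)
})

test_that("the fit is invariant to record order and unit rescaling", {
  d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
                             noise_cv = 0.05, n_replicates = 3, seed = 17)
  fit <- fit_constants(d)

  shuffled <- d[rev(seq_len(nrow(d))), ]
  fit_sh <- fit_constants(shuffled)
  expect_equal(fit_sh$K1_hat, fit$K1_hat, tolerance = 1e-8)
  expect_equal(fit_sh$K2_hat, fit$K2_hat, tolerance = 1e-8)

  # mM -> uM applied consistently leaves the dimensionless constants alone
  um <- d
  um$N1_0_mM <- um$N1_0_mM * 1000
  um$B2_0_mM <- um$B2_0_mM * 1000
  um$P_0_mM <- um$P_0_mM * 1000
  fit_um <- fit_constants(um)
  expect_equal(fit_um$K1_hat, fit$K1_hat, tolerance = 1e-6)
  expect_equal(fit_um$K2_hat, fit$K2_hat, tolerance = 1e-6)
})

test_that("measurement validation rejects malformed tables", {
  d <- simulate_measurements(0.16, 0.35, measurement_conditions())
  bad <- d
  bad$yield_fraction[1] <- 1.5
  expect_error(fit_constants(bad), class = "npyield_domain_error")
  expect_error(fit_constants(d[, setdiff(names(d), "P_0_mM")]),
               "P_0_mM", class = "npyield_parse_error")
  expect_error(fit_constants(d[0, ]), class = "npyield_domain_error")
})

test_that("bootstrap intervals are reproducible and collapse on noiseless data", {
  d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
                             noise_cv = 0.05, n_replicates = 3, seed = 8)
  ci_a <- bootstrap_confidence(d, n_boot = 100, seed = 4)
  ci_b <- bootstrap_confidence(d, n_boot = 100, seed = 4)
  expect_identical(ci_a$K1_interval, ci_b$K1_interval)
  expect_identical(ci_a$K2_interval, ci_b$K2_interval)
  expect_lt(ci_a$K1_interval[1], ci_a$K1_interval[2])
  expect_true(all(c(ci_a$K1_interval, ci_a$K2_interval) > 0))
  expect_lte(ci_a$n_failed, 20)

  d0 <- simulate_measurements(0.16, 0.35, measurement_conditions(),
                              noise_cv = 0, n_replicates = 3)
  ci0 <- bootstrap_confidence(d0, n_boot = 100, seed = 4)
  expect_lt(diff(ci0$K1_interval), 1e-8)
  expect_lt(diff(ci0$K2_interval), 1e-8)
  expect_equal(ci0$K1_interval[1], 0.16, tolerance = 1e-6)

  expect_error(bootstrap_confidence(d, n_boot = 50, seed = 1),
               class = "npyield_domain_error")
})
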