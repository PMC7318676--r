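# Core equilibrium model: apparent constants, closed-form ideal yield, and
# the full coupled-equilibrium solver. Reference values were frozen from the
# independent grid-refinement oracle in helper-oracle.R.

test_that("apparent_constant computes [base][P1P]/([nucleoside][P]) and guards the domain", {
  expect_identical(apparent_constant(1, 1, 1, 1), 1)
  # phosphorolysis-only equilibrium of 1 mM uridine + 1 mM phosphate at K = 0.16:
  # extent 2/7 solves xi^2 = K (N0 - xi)(P0 - xi)
  expect_equal(apparent_constant(0.7143, 0.2857, 0.2857, 0.7143), 0.16,
               tolerance = 1e-3)
  expect_error(apparent_constant(1, 0.5, 0.5, 0), "phosphate",
               class = "npyield_domain_error")
  expect_error(apparent_constant(0, 0.5, 0.5, 1), "nucleoside",
               class = "npyield_domain_error")
})

test_that("ideal_yield matches the feasibility-filtered quadratic roots", {
  # K_N = 1 degenerates to the linear case x = N1_0 B2_0 / (N1_0 + B2_0)
  res <- ideal_yield(1, 1, 0.5)
  expect_equal(res$N2_eq, 1 / 3, tolerance = 1e-12)
  expect_equal(res$yield_fraction, 2 / 3, tolerance = 1e-12)

  # the uridine -> adenosine pair at two donor equivalents
  res16 <- ideal_yield(16, 1, 0.5)
  expect_equal(res16$N2_eq, 0.4734014, tolerance = 1e-6)
  expect_equal(res16$yield_fraction, 0.9468027, tolerance = 1e-6)

  # the uridine -> 5-ethynyluridine pair (K_N = 0.16/0.35)
  res_eu <- ideal_yield(16 / 35, 1, 0.5)
  expect_equal(res_eu$N2_eq, 0.2739290, tolerance = 1e-6)
  expect_equal(res_eu$yield_fraction, 0.5478580, tolerance = 1e-6)

  # against polyroot: one feasible root, equal to the returned N2
  for (case in list(c(16, 1, 0.5), c(16 / 35, 1, 0.5), c(0.05, 3, 1),
                    c(7.3, 0.4, 2.2))) {
    roots <- ideal_roots(case[1], case[2], case[3])
    expect_length(roots$feasible, 1L)
    expect_equal(ideal_yield(case[1], case[2], case[3])$N2_eq,
                 roots$feasible, tolerance = 1e-9)
  }

  expect_error(ideal_yield(0, 1, 0.5), class = "npyield_domain_error")
  expect_error(ideal_yield(16, 1, 0), class = "npyield_domain_error")
})

test_that("ideal_yield root selection is feasible and the other branch is not", {
  set.seed(11)
  for (i in 1:200) {
    K_N <- 10^runif(1, -2, 2)
    N1_0 <- runif(1, 0.01, 10)
    B2_0 <- runif(1, 0.01, 10)
    x <- ideal_yield(K_N, N1_0, B2_0)$N2_eq
    expect_gte(x, 0)
    expect_lte(x, min(N1_0, B2_0))
    roots <- ideal_roots(K_N, N1_0, B2_0)
    rejected <- roots$all[which.max(abs(roots$all - x))]
    if (length(roots$all) == 2L) {
      expect_true(rejected < -1e-12 | rejected > min(N1_0, B2_0) + 1e-12)
    }
  }
})

test_that("solve_equilibrium reproduces independently derived equilibria", {
  # high-K2 product (5-ethynyluridine analog) at 10 equivalents of phosphate
  st <- solve_equilibrium(
    transglycosylation_system(0.16, 0.35, N1_0 = 1, B2_0 = 0.5, P_0 = 5))
  expect_equal(st$N2, 0.1169385, tolerance = 1e-6)
  expect_equal(st$yield_fraction, 0.2338771, tolerance = 1e-6)

  # low-K2 product (adenosine analog) at the same loading
  st2 <- solve_equilibrium(
    transglycosylation_system(0.16, 0.01, N1_0 = 1, B2_0 = 0.5, P_0 = 5))
  expect_equal(st2$N2, 0.4303614, tolerance = 1e-6)
  expect_equal(st2$yield_fraction, 0.8607227, tolerance = 1e-6)

  # vanishing acceptor: xi2 -> 0 and xi1 approaches the single-reaction
  # phosphorolysis equilibrium xi^2 = K1 (N1_0 - xi)(P_0 - xi), i.e. 2/7
  st3 <- solve_equilibrium(
    transglycosylation_system(0.16, 0.35, N1_0 = 1, B2_0 = 1e-12, P_0 = 1))
  expect_equal(st3$xi1, 2 / 7, tolerance = 1e-6)
  expect_lt(st3$xi2, 1e-12)
})

test_that("a phosphorus-free system is frozen at its initial composition", {
  sys <- transglycosylation_system(0.16, 0.35, N1_0 = 1, B2_0 = 0.5, P_0 = 0)
  st <- solve_equilibrium(sys)
  expect_identical(st$yield_fraction, 0)
  expect_identical(st$N1, sys$N1_0)
  expect_identical(st$B2, sys$B2_0)
  expect_identical(st$P1P, 0)
})

test_that("the low-phosphate limit recovers the closed-form ideal yield", {
  cases <- list(c(0.16, 0.35), c(0.16, 0.01), c(2, 0.5), c(0.05, 0.05))
  for (ks in cases) {
    st <- solve_equilibrium(
      transglycosylation_system(ks[1], ks[2], N1_0 = 1, B2_0 = 0.5,
                                P_0 = 1e-9))
    expect_equal(st$yield_fraction,
                 ideal_yield(ks[1] / ks[2], 1, 0.5)$yield_fraction,
                 tolerance = 1e-6)
  }
})

test_that("solver states conserve mass and satisfy both constraints on random systems", {
  set.seed(42)
  for (i in 1:200) {
    sys <- random_system()
    st <- solve_equilibrium(sys)
    expect_lt(abs((st$N1 + st$B1) - (sys$N1_0 + sys$B1_0)), 1e-12)
    expect_lt(abs((st$N2 + st$B2) - (sys$N2_0 + sys$B2_0)), 1e-12)
    expect_lt(abs((st$N1 + st$N2 + st$P1P) -
                    (sys$N1_0 + sys$N2_0 + sys$P1P_0)), 1e-12)
    expect_lt(abs((st$P + st$P1P) - (sys$P_0 + sys$P1P_0)), 1e-12)
    expect_lt(st$residual_K1, 1e-10)
    expect_lt(st$residual_K2, 1e-10)
    expect_true(all(c(st$N1, st$B1, st$N2, st$B2, st$P, st$P1P) >= 0))
  }
})

test_that("yield_vs_phosphate orders, reproduces and bounds the yields", {
  pred <- yield_vs_phosphate(0.16, 0.35, 1, 0.5, c(0.2, 1, 10))
  expect_equal(pred$ideal_yield, 0.5478580, tolerance = 1e-6)
  expect_equal(pred$yields_at_phosphate$yield_fraction,
               c(0.5265571, 0.4624835, 0.2338771), tolerance = 1e-6)
  # phosphate can only diminish the yield
  expect_true(all(pred$ideal_yield >=
                    pred$yields_at_phosphate$yield_fraction))
  expect_true(all(diff(pred$yields_at_phosphate$yield_fraction) <= 0))

  empty <- yield_vs_phosphate(0.16, 0.01, 1, 0.5, numeric(0))
  expect_identical(nrow(empty$yields_at_phosphate), 0L)
  expect_equal(empty$ideal_yield, 0.9468027, tolerance = 1e-6)
})

test_that("phosphate_gap matches the ideal-minus-equilibrium difference", {
  expect_equal(phosphate_gap(0.16, 0.35, 1, 0.5, 10), 31.39809,
               tolerance = 1e-5)
  expect_equal(phosphate_gap(0.16, 0.01, 1, 0.5, 10), 8.608002,
               tolerance = 1e-5)
  expect_identical(phosphate_gap(0.16, 0.35, 1, 0.5, 0), 0)
  expect_gte(min(phosphate_gap(0.16, 0.35, 1, 0.5, c(0.1, 1, 5))), 0)
})

test_that("system constructor validates constants and concentrations", {
  expect_error(transglycosylation_system(-1, 0.5, 1, 0.5, 1),
               class = "npyield_domain_error")
  expect_error(transglycosylation_system(0.16, 0.35, -1, 0.5, 1),
               class = "npyield_domain_error")
  expect_error(transglycosylation_system(0.16, 0.35, 1, 0, 1),
               "B2_0", class = "npyield_domain_error")
  expect_error(solve_equilibrium(list(K1 = 1)),
               class = "npyield_domain_error")
  expect_error(phosphorolysis_entry("", 0.16),
               class = "npyield_domain_error")
  expect_error(phosphorolysis_entry("uridine", Inf),
               class = "npyield_domain_error")
})
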