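# Independent grid-refinement oracle for the coupled equilibrium, and a
# random-system sampler. The oracle shares nothing with the package solver:
# it scans a 2-D grid over the reaction extents (xi1, xi2), scores each
# feasible point by the sum of squared relative residuals of the two
# equilibrium constraints, and refines around the best point.

oracle_solve <- function(K1, K2, N1_0, B1_0 = 0, N2_0 = 0, B2_0, P_0,
                         P1P_0 = 0, n = 41, rounds = 70) {
  resid2 <- function(xi1, xi2) {
    N1 <- N1_0 - xi1; B1 <- B1_0 + xi1
    P1P <- P1P_0 + xi1 - xi2; P <- P_0 - xi1 + xi2
    N2 <- N2_0 + xi2; B2 <- B2_0 - xi2
    t1 <- B1 * P1P; t2 <- K1 * N1 * P
    t3 <- B2 * P1P; t4 <- K2 * N2 * P
    s1 <- pmax(abs(t1), abs(t2), 1e-300)
    s2 <- pmax(abs(t3), abs(t4), 1e-300)
    ((t1 - t2) / s1)^2 + ((t3 - t4) / s2)^2
  }
  lo1 <- -B1_0; hi1 <- N1_0
  lo2 <- -N2_0; hi2 <- B2_0
  best <- c(0, 0)
  for (r in seq_len(rounds)) {
    x1 <- seq(lo1, hi1, length.out = n)
    x2 <- seq(lo2, hi2, length.out = n)
    g <- expand.grid(xi1 = x1, xi2 = x2)
    ok <- (P1P_0 + g$xi1 - g$xi2 >= 0) & (P_0 - g$xi1 + g$xi2 >= 0) &
      (g$xi1 >= -B1_0) & (g$xi1 <= N1_0) &
      (g$xi2 >= -N2_0) & (g$xi2 <= B2_0)
    v <- rep(Inf, nrow(g))
    v[ok] <- resid2(g$xi1[ok], g$xi2[ok])
    i <- which.min(v)
    best <- c(g$xi1[i], g$xi2[i])
    # shrink gently (x0.5 per round) so the refinement window can track a
    # curved residual valley toward the root instead of collapsing onto a
    # non-root valley point
    d1 <- 0.25 * (hi1 - lo1); d2 <- 0.25 * (hi2 - lo2)
    lo1 <- max(-B1_0, best[1] - d1); hi1 <- min(N1_0, best[1] + d1)
    lo2 <- max(-N2_0, best[2] - d2); hi2 <- min(B2_0, best[2] + d2)
  }
  # downhill-simplex polish of the same residual surface (penalized outside
  # the feasible region); grids alone can stall in curved residual valleys
  pen <- function(p) {
    xi1 <- p[1]; xi2 <- p[2]
    if (xi1 < -B1_0 || xi1 > N1_0 || xi2 < -N2_0 || xi2 > B2_0 ||
        P1P_0 + xi1 - xi2 < 0 || P_0 - xi1 + xi2 < 0) return(1e10)
    resid2(xi1, xi2)
  }
  for (k in 1:3) {
    nm <- stats::optim(best, pen, method = "Nelder-Mead",
                       control = list(maxit = 4000, reltol = 1e-30))
    best <- nm$par
  }
  xi1 <- best[1]; xi2 <- best[2]
  list(N1 = N1_0 - xi1, B1 = B1_0 + xi1, N2 = N2_0 + xi2, B2 = B2_0 - xi2,
       P = P_0 - xi1 + xi2, P1P = P1P_0 + xi1 - xi2,
       xi1 = xi1, xi2 = xi2, yield_fraction = xi2 / B2_0)
}

# Random system with K in [1e-3, 10] (log-uniform) and all six initial
# concentrations in (0, 10] mM.
random_system <- function() {
  transglycosylation_system(
    K1 = 10^stats::runif(1, -3, 1), K2 = 10^stats::runif(1, -3, 1),
    N1_0 = stats::runif(1, 1e-3, 10), B2_0 = stats::runif(1, 1e-3, 10),
    P_0 = stats::runif(1, 1e-3, 10), B1_0 = stats::runif(1, 1e-3, 10),
    N2_0 = stats::runif(1, 1e-3, 10), P1P_0 = stats::runif(1, 1e-3, 10)
  )
}

# Feasible roots of the ideal-yield quadratic found independently of the
# package's closed form, via polyroot() and feasibility filtering.
ideal_roots <- function(K_N, N1_0, B2_0) {
  z <- polyroot(c(K_N * N1_0 * B2_0, -K_N * (N1_0 + B2_0), K_N - 1))
  re <- Re(z)[abs(Im(z)) < 1e-9]
  list(all = re,
       feasible = re[re >= -1e-12 & re <= min(N1_0, B2_0) + 1e-12])
}
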