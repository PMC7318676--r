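# Vectorized coupled-equilibrium solver in reaction extents.
#
# Parametrization (all in mM):
#   xi1 = extent of donor phosphorolysis   N1 + P  -> B1 + P1P
#   xi2 = extent of product synthesis      B2 + P1P -> N2 + P
# so that
#   N1 = N1_0 - xi1,  B1 = B1_0 + xi1,  N2 = N2_0 + xi2,  B2 = B2_0 - xi2,
#   P  = P_0 - xi1 + xi2,  P1P = P1P_0 + xi1 - xi2.
# The four conservation laws (donor pool, acceptor pool, ribose, phosphorus)
# hold exactly for every (xi1, xi2), so the solver only has to satisfy the two
# equilibrium constraints
#   K1 = [B1][P1P] / ([N1][P])   and   K2 = [B2][P1P] / ([N2][P]).
#
# The inner variable is delta = xi1 - xi2, the net shift of the phosphorus
# pool ([P1P] = P1P_0 + delta, [P] = P_0 - delta). Working in delta rather
# than xi1 avoids catastrophic cancellation at low phosphate, where xi1 and
# xi2 agree to many digits but their difference carries all the information.
#
# At fixed xi2 the K1 constraint, written residual-form
#   f(delta) = [B1][P1P] - K1 [N1][P]
#            = (1 - K1) delta^2 + [u + P1P_0 + K1 (v + P_0)] delta
#              + u P1P_0 - K1 v P_0,       u = B1_0 + xi2, v = N1_0 - xi2,
# is a quadratic in delta that is strictly increasing on the feasible bracket
# [max(-B1_0 - xi2, -P1P_0), min(N1_0 - xi2, P_0)]
# (f' = [B1]+[P1P] + K1([N1]+[P]) >= 0), so it has exactly one feasible root,
# taken in closed form: on the increasing branch of the parabola the feasible
# root is the larger root when the parabola opens upward (K1 < 1) and the
# smaller root when it opens downward (K1 > 1); for K1 = 1 the quadratic
# degenerates to a line. The outer residual
#   g(xi2) = [B2][P1P] - K2 [N2][P]      (at delta = delta*(xi2))
# changes sign across the feasible xi2 bracket by construction (g >= 0 at the
# lower end where N2 or P vanishes, g <= 0 at the upper end where B2 or P1P
# vanishes), so bracketed bisection on xi2 is unconditionally convergent.
#
# All arithmetic is vectorized over systems; the fitting module solves whole
# measurement sets in one call.

solve_extents <- function(K1, K2, N1_0, B1_0, N2_0, B2_0, P_0, P1P_0,
                          tol = 1e-12, max_iter = 200L) {
  n <- max(length(K1), length(K2), length(N1_0), length(B1_0), length(N2_0),
           length(B2_0), length(P_0), length(P1P_0))
  K1 <- rep_len(K1, n); K2 <- rep_len(K2, n)
  N1_0 <- rep_len(N1_0, n); B1_0 <- rep_len(B1_0, n)
  N2_0 <- rep_len(N2_0, n); B2_0 <- rep_len(B2_0, n)
  P_0 <- rep_len(P_0, n); P1P_0 <- rep_len(P1P_0, n)

  # no phosphorus anywhere: the system is frozen at its initial composition
  frozen <- (P_0 + P1P_0) <= 0
  a0 <- 1 - K1
  lin <- a0 == 0

  # closed-form root of the K1 constraint at fixed xi2 (see header comment)
  inner_delta <- function(xi2) {
    dlo <- pmax(-B1_0 - xi2, -P1P_0)
    dhi <- pmin(N1_0 - xi2, P_0)
    dhi <- pmax(dhi, dlo)
    u <- B1_0 + xi2
    v <- N1_0 - xi2
    b <- u + P1P_0 + K1 * (v + P_0)
    cc <- u * P1P_0 - K1 * v * P_0
    disc <- b * b - 4 * a0 * cc
    disc[disc < 0] <- 0
    s <- rep(1, length(b)); s[b < 0] <- -1
    qq <- -0.5 * (b + s * sqrt(disc))
    r1 <- qq / a0
    r2 <- cc / qq
    x <- ifelse(a0 > 0, pmax(r1, r2), pmin(r1, r2))
    if (any(lin)) x[lin] <- -cc[lin] / b[lin]
    bad <- !is.finite(x)
    if (any(bad)) {
      # fully degenerate coefficients: f is monotone on the bracket, bisect
      blo <- dlo[bad]; bhi <- dhi[bad]
      xib <- xi2[bad]
      fb <- function(d) {
        (B1_0[bad] + xib + d) * (P1P_0[bad] + d) -
          K1[bad] * (N1_0[bad] - xib - d) * (P_0[bad] - d)
      }
      for (it in 1:120) {
        mid <- 0.5 * (blo + bhi)
        up <- fb(mid) <= 0
        blo <- ifelse(up, mid, blo)
        bhi <- ifelse(up, bhi, mid)
      }
      x[bad] <- 0.5 * (blo + bhi)
    }
    pmin(pmax(x, dlo), dhi)
  }

  # feasible xi2 bracket: N2 >= 0 and a non-empty inner bracket at both ends
  lo <- pmax(-N2_0, -(P_0 + B1_0))
  hi <- pmin(B2_0, N1_0 + P1P_0)
  hi <- pmax(hi, lo)
  lo[frozen] <- 0
  hi[frozen] <- 0

  eps_stop <- .Machine$double.eps * (pmax(abs(lo), abs(hi)) +
                                       1e-3 * (hi - lo)) + 5e-324
  iters <- 0L
  while (iters < max_iter) {
    iters <- iters + 1L
    mid <- 0.5 * (lo + hi)
    delta <- inner_delta(mid)
    g <- (B2_0 - mid) * (P1P_0 + delta) - K2 * (N2_0 + mid) * (P_0 - delta)
    pos <- g >= 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    if (all(hi - lo <= eps_stop)) break
  }

  xi2 <- 0.5 * (lo + hi)
  xi2[frozen] <- 0
  delta <- inner_delta(xi2)
  delta[frozen] <- 0

  # relative residuals of the two constraints at the returned extents
  N1 <- N1_0 - xi2 - delta; B1 <- B1_0 + xi2 + delta
  N2 <- N2_0 + xi2; B2 <- B2_0 - xi2
  P <- P_0 - delta; P1P <- P1P_0 + delta
  sc1 <- pmax(abs(B1 * P1P), abs(K1 * N1 * P))
  sc2 <- pmax(abs(B2 * P1P), abs(K2 * N2 * P))
  r1 <- ifelse(sc1 > 0, abs(B1 * P1P - K1 * N1 * P) / sc1, 0)
  r2 <- ifelse(sc2 > 0, abs(B2 * P1P - K2 * N2 * P) / sc2, 0)
  r1[frozen] <- 0
  r2[frozen] <- 0

  list(xi1 = xi2 + delta, xi2 = xi2, delta = delta,
       residual_K1 = r1, residual_K2 = r2,
       iterations = iters, converged = (r1 <= tol & r2 <= tol) | frozen,
       frozen = frozen)
}

# Vectorized yield (fraction of B2_0) for default setups (no pre-existing
# B1, N2 or P1P); used by the fitting objective and the design inversions.
yield_at <- function(K1, K2, N1_0, B2_0, P_0, tol = 1e-12, max_iter = 200L) {
  ext <- solve_extents(K1, K2, N1_0, 0, 0, B2_0, P_0, 0,
                       tol = tol, max_iter = max_iter)
  ext$xi2 / B2_0
}
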