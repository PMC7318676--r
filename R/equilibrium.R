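#' Apparent equilibrium constant of phosphorolysis from a composition
#'
#' Computes the dimensionless apparent equilibrium constant of a nucleoside
#' phosphorolysis, `K = (base * p1p) / (nucleoside * phosphate)`, from one
#' equilibrium composition. All concentrations must be in the same unit
#' (conventionally mM); the result is unit-free.
#'
#' @param nucleoside Equilibrium nucleoside concentration (> 0).
#' @param base Equilibrium free-nucleobase concentration (>= 0).
#' @param p1p Equilibrium pentose-1-phosphate concentration (>= 0).
#' @param phosphate Equilibrium inorganic-phosphate concentration (> 0).
#'
#' @return The apparent equilibrium constant (numeric scalar).
#' @examples
#' # phosphorolysis-only equilibrium of 1 mM uridine + 1 mM phosphate, K = 0.16
#' apparent_constant(nucleoside = 0.7143, base = 0.2857,
#'                   p1p = 0.2857, phosphate = 0.7143)
#' @export
apparent_constant <- function(nucleoside, base, p1p, phosphate) {
  check_number(nucleoside, "nucleoside", lower = 0, strict = TRUE)
  check_number(base, "base", lower = 0)
  check_number(p1p, "p1p", lower = 0)
  check_number(phosphate, "phosphate", lower = 0, strict = TRUE)
  (base * p1p) / (nucleoside * phosphate)
}

#' Ideal (zero-phosphate) transglycosylation yield
#'
#' In the limit of vanishing phosphate no sugar is sequestered as
#' pentose-1-phosphate and none of the product nucleoside is phosphorolyzed
#' back, so the coupled system reduces to the net reaction
#' `N1 + B2 <-> B1 + N2` with equilibrium constant `K_N = K1/K2`. The product
#' concentration `x = [N2]` then solves the quadratic
#' \deqn{(K_N - 1)\,x^2 - K_N (N_{1,0} + B_{2,0})\,x + K_N N_{1,0} B_{2,0} = 0,}
#' of which exactly one root is physically feasible
#' (`0 <= x <= min(N1_0, B2_0)`). For `K_N = 1` the quadratic degenerates and
#' the exact linear solution `x = N1_0 B2_0 / (N1_0 + B2_0)` is used.
#'
#' @param K_N Net equilibrium constant `K1/K2` (> 0).
#' @param N1_0 Initial sugar donor concentration in mM (>= 0).
#' @param B2_0 Initial acceptor base concentration in mM (> 0).
#'
#' @return A list with `N2_eq` (equilibrium product concentration, mM) and
#'   `yield_fraction` (`N2_eq / B2_0`, in `[0, 1]`).
#' @examples
#' # uridine -> adenosine at two donor equivalents: ~94.7 % ideal yield
#' ideal_yield(K_N = 0.16 / 0.01, N1_0 = 1, B2_0 = 0.5)
#' @seealso [solve_equilibrium()] for finite phosphate concentrations.
#' @export
ideal_yield <- function(K_N, N1_0, B2_0) {
  check_number(K_N, "K_N", lower = 0, strict = TRUE)
  check_number(N1_0, "N1_0", lower = 0)
  check_number(B2_0, "B2_0", lower = 0, strict = TRUE)
  if (abs(K_N - 1) < 1e-9) {
    x <- N1_0 * B2_0 / (N1_0 + B2_0)
  } else {
    s <- N1_0 + B2_0
    disc <- K_N * (K_N * N1_0^2 - 2 * K_N * N1_0 * B2_0 + K_N * B2_0^2 +
                     4 * N1_0 * B2_0)
    x <- (K_N * s - sqrt(disc)) / (2 * (K_N - 1))
  }
  x <- min(max(x, 0), min(N1_0, B2_0))
  list(N2_eq = x, yield_fraction = x / B2_0)
}

#' Solve the full transglycosylation equilibrium
#'
#' Finds the equilibrium composition of all six species (donor nucleoside N1,
#' donor base B1, product nucleoside N2, acceptor base B2, phosphate P and
#' pentose-1-phosphate P1P) satisfying the two phosphorolysis equilibrium
#' constraints with complete mass balance. The state is parametrized by two
#' reaction extents, so the four conservation laws (donor pool, acceptor pool,
#' ribose, phosphorus) hold exactly by construction; the two nonlinear
#' constraints are solved by bracketed bisection on the product-formation
#' extent with a closed-form inner solve of the donor constraint (see the
#' package vignette for the scheme and its convergence argument).
#'
#' If the system contains no phosphorus at all (`P_0 + P1P_0 = 0`) neither
#' half-reaction can proceed and the initial state is returned unchanged:
#' phosphate is catalytic, and the ideal yield is the limit `P_0 -> 0+`, not
#' the `P_0 = 0` state.
#'
#' @param system A [transglycosylation_system()].
#' @param tol Relative residual tolerance on both equilibrium constraints
#'   (default `1e-12`).
#' @param max_iter Iteration cap for the outer bisection (default 200).
#'
#' @return An object of class `"equilibrium_state"`: the six equilibrium
#'   concentrations (mM), `yield_fraction` (product formed relative to
#'   `B2_0`), the extents `xi1`, `xi2`, and the achieved relative residuals.
#' @examples
#' sys <- transglycosylation_system(K1 = 0.16, K2 = 0.35,
#'                                  N1_0 = 1, B2_0 = 0.5, P_0 = 5)
#' solve_equilibrium(sys)  # ~23.4 % yield at 10 equivalents of phosphate
#' @export
solve_equilibrium <- function(system, tol = 1e-12, max_iter = 200L) {
  if (!inherits(system, "transglycosylation_system")) {
    stop_domain("`system` must be a transglycosylation_system object")
  }
  check_number(tol, "tol", lower = 0, strict = TRUE)
  ext <- solve_extents(system$K1, system$K2, system$N1_0, system$B1_0,
                       system$N2_0, system$B2_0, system$P_0, system$P1P_0,
                       tol = tol, max_iter = max_iter)
  if (!ext$converged) {
    stop_convergence(
      sprintf(paste0("equilibrium solver did not reach tol = %g within %d ",
                     "iterations (relative residuals: K1 %.3g, K2 %.3g)"),
              tol, max_iter, ext$residual_K1, ext$residual_K2),
      residuals = c(K1 = ext$residual_K1, K2 = ext$residual_K2))
  }
  new_equilibrium_state(system, ext$xi2, ext$delta,
                        ext$residual_K1, ext$residual_K2, ext$iterations)
}

#' Yield as a function of the phosphate loading
#'
#' Computes the ideal (zero-phosphate-limit) yield and the full-equilibrium
#' yield at each requested phosphate loading, expressed in equivalents
#' relative to the starting acceptor base (`P_0 = equiv * B2_0`).
#'
#' @param K1,K2 Apparent equilibrium constants of phosphorolysis of the sugar
#'   donor and the product nucleoside.
#' @param N1_0 Initial sugar donor concentration in mM.
#' @param B2_0 Initial acceptor base concentration in mM.
#' @param phosphate_equivs Numeric vector of phosphate loadings in
#'   equivalents of `B2_0` (each >= 0); may be empty.
#' @param tol Passed to [solve_equilibrium()].
#'
#' @return An object of class `"yield_prediction"`: a list with
#'   `ideal_yield` (fraction), `N2_ideal` (mM), a data frame
#'   `yields_at_phosphate` with columns `phosphate_equiv`, `P_0_mM`,
#'   `yield_fraction` (ordered as the input), and the generating `system`
#'   settings.
#' @examples
#' yield_vs_phosphate(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
#'                    phosphate_equivs = c(0.2, 1, 10))
#' @export
yield_vs_phosphate <- function(K1, K2, N1_0, B2_0, phosphate_equivs,
                               tol = 1e-12) {
  if (length(phosphate_equivs)) {
    check_number(phosphate_equivs, "phosphate_equivs", lower = 0,
                 len = length(phosphate_equivs))
  }
  system <- transglycosylation_system(K1, K2, N1_0 = N1_0, B2_0 = B2_0,
                                      P_0 = 0)
  ideal <- ideal_yield(system$K_N, N1_0, B2_0)
  if (length(phosphate_equivs)) {
    # an entry of 0 equivalents means the catalytic zero-phosphate limit,
    # i.e. the ideal yield, not the frozen P_0 = 0 state
    yf <- rep(ideal$yield_fraction, length(phosphate_equivs))
    pos <- phosphate_equivs > 0
    if (any(pos)) {
      yf[pos] <- yield_at(K1, K2, N1_0, B2_0, phosphate_equivs[pos] * B2_0,
                          tol = tol)
    }
  } else {
    yf <- numeric(0)
  }
  structure(
    list(
      ideal_yield = ideal$yield_fraction,
      N2_ideal = ideal$N2_eq,
      yields_at_phosphate = data.frame(
        phosphate_equiv = as.numeric(phosphate_equivs),
        P_0_mM = as.numeric(phosphate_equivs) * B2_0,
        yield_fraction = yf
      ),
      system = system
    ),
    class = "yield_prediction"
  )
}

#' Phosphate gap: yield lost to a finite phosphate loading
#'
#' The phosphate gap is the difference, in percentage points, between the
#' ideal (zero-phosphate-limit) yield and the full-equilibrium yield at a
#' given phosphate loading. Phosphate can only diminish the yield (it
#' sequesters sugar as pentose-1-phosphate and phosphorolyzes the product
#' back), so the gap is non-negative and grows with the loading.
#'
#' @inheritParams yield_vs_phosphate
#' @param phosphate_equiv Phosphate loading(s) in equivalents of `B2_0`
#'   (>= 0); vectorized.
#' @param tol Passed to [solve_equilibrium()].
#'
#' @return The gap in percentage points (same length as `phosphate_equiv`).
#' @examples
#' # the high-K2 product loses > 30 percentage points at 10 equivalents
#' phosphate_gap(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
#'               phosphate_equiv = 10)
#' @export
phosphate_gap <- function(K1, K2, N1_0, B2_0, phosphate_equiv, tol = 1e-12) {
  check_number(phosphate_equiv, "phosphate_equiv", lower = 0,
               len = length(phosphate_equiv))
  system <- transglycosylation_system(K1, K2, N1_0 = N1_0, B2_0 = B2_0,
                                      P_0 = 0)
  ideal <- ideal_yield(system$K_N, N1_0, B2_0)$yield_fraction
  yf <- rep(ideal, length(phosphate_equiv))
  pos <- phosphate_equiv > 0
  if (any(pos)) {
    yf[pos] <- yield_at(K1, K2, N1_0, B2_0, phosphate_equiv[pos] * B2_0,
                        tol = tol)
  }
  pmax(100 * (ideal - yf), 0)
}
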