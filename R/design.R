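#' Sugar donor loading required for a target ideal yield
#'
#' Analytic inverse of the ideal-yield relation: for a target product
#' concentration `x = target_yield * B2_0`, the net-reaction equilibrium
#' `K_N = [N2][B1] / ([N1][B2])` gives the required initial donor
#' concentration in closed form,
#' \deqn{N_{1,0} = x + \frac{x^2}{K_N (B_{2,0} - x)}.}
#' Systems with a low `K_N` need a large donor excess to push the yield past
#' 50 %, whereas `K_N` of order 5-15 reaches > 90 % with roughly twofold
#' excess.
#'
#' @param K_N Net equilibrium constant `K1/K2` (> 0).
#' @param target_yield Target yield as a fraction of `B2_0`, in `(0, 1)`.
#'   A yield of 1 is unreachable at any finite donor loading.
#' @param B2_0 Initial acceptor base concentration in mM (> 0).
#'
#' @return Required initial donor concentration `N1_0` in mM. Substituting it
#'   back into [ideal_yield()] reproduces `target_yield`.
#' @examples
#' donor_for_target_yield(K_N = 16, target_yield = 0.90, B2_0 = 0.5)
#' @export
donor_for_target_yield <- function(K_N, target_yield, B2_0) {
  check_number(K_N, "K_N", lower = 0, strict = TRUE)
  check_number(B2_0, "B2_0", lower = 0, strict = TRUE)
  if (!is.numeric(target_yield) || length(target_yield) != 1L ||
      is.na(target_yield) || target_yield <= 0 || target_yield >= 1) {
    stop_domain("`target_yield` must lie strictly between 0 and 1; a yield of 1 is unreachable at finite donor loading")
  }
  x <- target_yield * B2_0
  x + x^2 / (K_N * (B2_0 - x))
}

#' Sugar donor loading required for a target yield at finite phosphate
#'
#' Numeric inverse of the full equilibrium model: finds the smallest initial
#' donor concentration whose solved equilibrium yield reaches
#' `target_yield` at the given phosphate loading. The yield is strictly
#' increasing in the donor loading but saturates below 1 at finite phosphate,
#' so an unreachable target raises an infeasibility error reporting the
#' asymptotic (large-donor) yield. At `P_0 = 0` the full solver is frozen;
#' that case is interpreted as the catalytic zero-phosphate limit and
#' delegates to the analytic [donor_for_target_yield()].
#'
#' @param K1,K2 Apparent equilibrium constants of phosphorolysis of donor and
#'   product.
#' @param target_yield Target yield as a fraction of `B2_0`, in `(0, 1)`.
#' @param B2_0 Initial acceptor base concentration in mM (> 0).
#' @param P_0 Initial phosphate concentration in mM (>= 0).
#' @param tol Bisection tolerance on the donor concentration in mM
#'   (default `1e-9`).
#'
#' @return Required initial donor concentration `N1_0` in mM; solving the
#'   equilibrium at the returned loading gives a yield in
#'   `[target_yield, target_yield + 1e-6]`.
#' @examples
#' donor_for_target_yield_with_phosphate(K1 = 0.16, K2 = 0.35,
#'                                       target_yield = 0.235,
#'                                       B2_0 = 0.5, P_0 = 5)
#' @export
donor_for_target_yield_with_phosphate <- function(K1, K2, target_yield, B2_0,
                                                  P_0, tol = 1e-9) {
  check_number(K1, "K1", lower = 0, strict = TRUE)
  check_number(K2, "K2", lower = 0, strict = TRUE)
  check_number(B2_0, "B2_0", lower = 0, strict = TRUE)
  check_number(P_0, "P_0", lower = 0)
  if (!is.numeric(target_yield) || length(target_yield) != 1L ||
      is.na(target_yield) || target_yield <= 0 || target_yield >= 1) {
    stop_domain("`target_yield` must lie strictly between 0 and 1")
  }
  if (P_0 <= 0) {
    return(donor_for_target_yield(K1 / K2, target_yield, B2_0))
  }
  yield_of <- function(N1) yield_at(K1, K2, N1, B2_0, P_0)
  hi <- max(B2_0, 1)
  cap <- 1e6 * B2_0
  while (yield_of(hi) < target_yield && hi < cap) hi <- hi * 2
  if (yield_of(hi) < target_yield) {
    stop_infeasible(sprintf(
      paste0("target yield %.4g is unreachable at P_0 = %g mM: the ",
             "large-donor asymptotic yield is %.4g"),
      target_yield, P_0, yield_of(cap)))
  }
  lo <- 0
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (yield_of(mid) >= target_yield) hi <- mid else lo <- mid
  }
  hi
}

#' Largest phosphate loading keeping the yield loss within a budget
#'
#' Finds the largest initial phosphate concentration whose phosphate gap
#' (ideal yield minus full-equilibrium yield, in percentage points) does not
#' exceed `max_gap`. The gap is monotone increasing in the phosphate loading
#' and bounded above by the ideal yield itself (in percent), so when even an
#' arbitrarily large loading never exceeds the budget the function returns an
#' infinite sentinel rather than erroring: a planner consuming a table of
#' budgets needs a comparable value.
#'
#' @inheritParams donor_for_target_yield_with_phosphate
#' @param N1_0 Initial sugar donor concentration in mM.
#' @param max_gap Tolerated yield loss in percentage points (> 0).
#' @param tol Round-trip tolerance on the gap at the returned loading, in
#'   percentage points (default `1e-3`).
#'
#' @return A list with `P_0_mM`, `phosphate_equiv` (relative to `B2_0`) and
#'   `gap_pp`, the gap actually attained at the returned loading (within
#'   `tol` of `max_gap`, or below it at the infinite sentinel).
#' @examples
#' max_phosphate_for_deviation(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
#'                             max_gap = 4)
#' @export
max_phosphate_for_deviation <- function(K1, K2, N1_0, B2_0, max_gap,
                                        tol = 1e-3) {
  check_number(max_gap, "max_gap", lower = 0, strict = TRUE)
  gap_of <- function(P) phosphate_gap(K1, K2, N1_0, B2_0, P / B2_0)
  P_big <- 1e9
  if (gap_of(P_big) <= max_gap) {
    return(list(P_0_mM = Inf, phosphate_equiv = Inf, gap_pp = gap_of(P_big)))
  }
  lo <- 0
  hi <- P_big
  for (it in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    if (gap_of(mid) <= max_gap) lo <- mid else hi <- mid
    if (lo > 0 && max_gap - gap_of(lo) <= tol) break
  }
  list(P_0_mM = lo, phosphate_equiv = lo / B2_0, gap_pp = gap_of(lo))
}

#' Yield landscape over equilibrium constants and loadings
#'
#' Evaluates the ideal and phosphate-adjusted yields over a full factorial
#' grid of donor/product equilibrium constants, donor excesses and phosphate
#' loadings. The output is long-format (one observation per row), ordered
#' lexicographically over the input grids (`K1` slowest, then `K2`, donor,
#' phosphate; the ideal row first within each cell), so it is deterministic
#' and directly serializable or plottable.
#'
#' @param K1_values,K2_values Positive numeric vectors of apparent
#'   equilibrium constants of phosphorolysis.
#' @param donor_equivs Donor loadings in equivalents of `B2_0` (> 0).
#' @param phosphate_equivs Phosphate loadings in equivalents of `B2_0`
#'   (>= 0); may be empty, in which case only ideal rows are produced.
#' @param B2_0 Initial acceptor base concentration in mM (> 0).
#' @param tol Passed to [solve_equilibrium()].
#'
#' @return A data frame with columns `K1`, `K2`, `K_N`, `donor_equiv`,
#'   `N1_0_mM`, `yield_type` (`"ideal"` or `"equilibrium"`),
#'   `phosphate_equiv` and `P_0_mM` (`NA` for ideal rows), and
#'   `yield_fraction`.
#' @examples
#' yield_landscape(K1_values = 0.16, K2_values = c(0.01, 0.35),
#'                 donor_equivs = 2, phosphate_equivs = c(0.2, 1, 10),
#'                 B2_0 = 0.5)
#' @export
yield_landscape <- function(K1_values, K2_values, donor_equivs,
                            phosphate_equivs = numeric(0), B2_0, tol = 1e-12) {
  check_number(K1_values, "K1_values", lower = 0, strict = TRUE,
               len = length(K1_values))
  check_number(K2_values, "K2_values", lower = 0, strict = TRUE,
               len = length(K2_values))
  check_number(donor_equivs, "donor_equivs", lower = 0, strict = TRUE,
               len = length(donor_equivs))
  if (length(phosphate_equivs)) {
    check_number(phosphate_equivs, "phosphate_equivs", lower = 0,
                 len = length(phosphate_equivs))
  }
  check_number(B2_0, "B2_0", lower = 0, strict = TRUE)
  if (!length(K1_values) || !length(K2_values) || !length(donor_equivs)) {
    stop_domain("all of K1_values, K2_values and donor_equivs must be non-empty")
  }
  rows <- list()
  k <- 0L
  for (K1 in sort(K1_values)) {
    for (K2 in sort(K2_values)) {
      for (de in sort(donor_equivs)) {
        N1_0 <- de * B2_0
        pred <- yield_vs_phosphate(K1, K2, N1_0, B2_0,
                                   sort(phosphate_equivs), tol = tol)
        cell <- data.frame(
          K1 = K1, K2 = K2, K_N = K1 / K2,
          donor_equiv = de, N1_0_mM = N1_0,
          yield_type = c("ideal",
                         rep("equilibrium", length(phosphate_equivs))),
          phosphate_equiv = c(NA_real_, sort(phosphate_equivs)),
          P_0_mM = c(NA_real_, sort(phosphate_equivs) * B2_0),
          yield_fraction = c(pred$ideal_yield,
                             pred$yields_at_phosphate$yield_fraction)
        )
        k <- k + 1L
        rows[[k]] <- cell
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
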