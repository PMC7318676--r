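---
title: "Equilibrium modelling of nucleoside transglycosylations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium modelling of nucleoside transglycosylations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npyield)
```

## The reaction system

A nucleoside phosphorylase-catalyzed transglycosylation couples two
reversible phosphorolysis half-reactions:

* donor phosphorolysis: `N1 + P <-> B1 + P1P` with apparent equilibrium
  constant `K1 = [B1][P1P]/([N1][P])`;
* product synthesis (reverse phosphorolysis of the product):
  `B2 + P1P <-> N2 + P`, governed by
  `K2 = [B2][P1P]/([N2][P])`.

Here `N1` is the sugar donor nucleoside (typically uridine for ribosides or
thymidine for 2'-deoxyribosides), `B2` the acceptor nucleobase, `N2` the
product nucleoside, and `P1P` the pentose-1-phosphate intermediate.
Phosphate is catalytic: consumed by the first half-reaction and released by
the second. The yield is conventionally reported as product formed relative
to the starting acceptor base, `[N2]_formed / [B2]_0`, and this package
follows that convention even when the donor is limiting.

The constants are *apparent* constants: they absorb the buffer, ionic
strength, temperature and pH of the measurement, which is why
`phosphorolysis_entry` records condition metadata and why constants from
different conditions should not be mixed. Typical magnitudes at 60 °C,
pH 9 range from about 0.01 (purine ribosides such as adenosine) to about
0.35 (pyrimidine ribosides such as 5-ethynyluridine).

## Ideal yield: the closed form

As phosphate vanishes, no sugar is held as `P1P` and none of the product is
phosphorolyzed back; the system reduces to the net reaction
`N1 + B2 <-> B1 + N2` with

\[ K_N = K_1 / K_2 = \frac{[N2][B1]}{[N1][B2]}. \]

Writing \(x = [N2]\) and eliminating the other species through the mass
balance gives

\[ (K_N - 1)\,x^2 - K_N (N_{1,0} + B_{2,0})\,x + K_N N_{1,0} B_{2,0} = 0 , \]

which has exactly one root in the feasible interval
\([0, \min(N_{1,0}, B_{2,0})]\): the minus branch of the quadratic formula.
`ideal_yield()` evaluates it directly. Two numerical choices are worth
stating:

* **`K_N = 1` degeneracy.** The quadratic coefficient vanishes and the
  formula divides by zero; for `|K_N - 1| < 1e-9` the exact linear solution
  \(x = N_{1,0} B_{2,0}/(N_{1,0}+B_{2,0})\) is used instead.
* **Root selection.** The returned root is clamped to the feasible interval;
  the test suite verifies on sampled inputs (via `polyroot`, independent of
  the closed form) that the rejected branch always violates feasibility.

`K_N` alone fixes the ideal yield: donors with high `K1` and products with
low `K2` are favourable. `K_N` of order 5–15 gives >90 % yield with about
twofold donor excess; `K_N` below 1 needs large excesses for even moderate
yields (`donor_for_target_yield()` quantifies this analytically).

## Full equilibrium at finite phosphate

At finite phosphate the intermediate matters: phosphate converts donor into
`P1P` without making product, and phosphorolyzes the product back. Both
effects only lower the yield; `K2` controls how steeply. The package solves
the full system rather than assuming constant phosphate — the
constant-phosphate simplification reduces to a cubic but fails (up to
returning negative concentrations) for high-`K2` products, precisely the
cases where the phosphate effect is strongest.

### Solver scheme

The state is parametrized by two reaction extents (mM):
`xi1` (donor phosphorolyzed) and `xi2` (product formed), so that all four
conservation laws — donor pool, acceptor pool, ribose, phosphorus — hold
exactly for *every* trial point; the solver only drives the two equilibrium
residuals to zero. Internally the inner variable is
`delta = xi1 - xi2`, the net shift of the phosphorus pool
(`[P1P] = P1P_0 + delta`, `[P] = P_0 - delta`). At low phosphate `xi1` and
`xi2` agree to many digits and their *difference* carries all the
information, so solving for `delta` directly avoids catastrophic
cancellation (a naive `(xi1, xi2)` formulation loses six digits of residual
accuracy at `P_0 = 1e-9` mM).

At fixed `xi2` the `K1` constraint is a quadratic in `delta` whose residual
is strictly increasing on the feasible bracket
(`f' = [B1]+[P1P]+K1([N1]+[P]) >= 0`), so its unique feasible root is taken
in closed form — on the increasing branch, the larger root when the parabola
opens upward (`K1 < 1`), the smaller when it opens downward — with a
bisection fallback for degenerate coefficients. The outer `K2` residual then
changes sign across the feasible `xi2` bracket by construction (at the lower
end `N2` or `P` vanishes, at the upper end `B2` or `P1P`), and bracketed
bisection on `xi2` is unconditionally convergent: no Jacobians, no starting
points, no divergence. An early design used inner bisection as well; the
closed-form inner solve is exact to rounding and roughly fifty times
faster, which matters because the fitting module solves the equilibrium
thousands of times.

Defaults: relative residual tolerance `1e-12` on both constraints (achieved
residuals are typically `1e-14` or better), outer iteration cap 200 (the
bisection reaches machine-precision brackets in about 55 iterations; the
cap raises a convergence error rather than returning an unconverged state).
Uniqueness of the feasible solution is verified empirically — the test suite
compares the solver against an independent two-dimensional grid-refinement
search on random systems — not proven.

### `P_0 = 0` semantics

A system with no phosphorus anywhere (`P_0 + P1P_0 = 0`) cannot react at
all: `solve_equilibrium()` returns the initial state unchanged. The ideal
yield is the *limit* `P -> 0+`, not the `P = 0` state; the distinction is
deliberate and surfaces in three places: `solve_equilibrium()` freezes,
`yield_vs_phosphate()` and `phosphate_gap()` interpret an entry of `0`
equivalents as the ideal limit, and
`donor_for_target_yield_with_phosphate()` delegates to the analytic
inversion at `P_0 = 0`.

### Design inversions

All numeric inversions use bracketed bisection on monotone maps with
explicit feasibility pre-checks. `max_phosphate_for_deviation()` returns an
infinite sentinel instead of erroring when even an arbitrarily large
phosphate loading never exceeds the tolerated yield loss (the gap is
bounded above by the ideal yield), so tabulated budgets remain comparable.
`donor_for_target_yield_with_phosphate()` reports an explicit infeasibility
error, carrying the asymptotic yield, when the target exceeds the yield at
the capped donor loading (`1e6` times the base concentration). One
consequence of the full model worth noting: as the donor loading grows, the
donor base stays bounded (`[B1] <= P_0 + B2_0`), so the `K1` constraint
drives essentially all phosphorus into `P1P` and the yield approaches 1
even at high phosphate — arbitrarily high targets below 1 are reachable in
principle, just at donor excesses that are rarely practical.

## Fitting apparent constants

`fit_constants()` estimates `(K1, K2)` from endpoint yields by least
squares, with model predictions from the full solver. Choices:

* **Objective**: squared differences on yield fractions, uniform weights by
  default (optional per-record weights). Yields are the reported observable
  of endpoint HPLC analyses and have roughly comparable error across
  conditions.
* **Parametrization**: `log K` with box bounds `K` in `[1e-6, 1e3]`,
  enforcing positivity and spanning the physically plausible range.
* **Optimizer**: Levenberg–Marquardt (`minpack.lm::nls.lm`) on the residual
  vector. Starts are taken from a 3×3 logarithmic grid; the grid points are
  ranked by loss and LM is run from the three best basins. Noiseless
  round-trips recover the constants to ~1e-15 relative.
* **Identifiability**: the ideal yield constrains only the ratio `K_N`; it
  is the phosphate response that separates `K1` from `K2`. Measurements at
  a single phosphate level with both constants free raise an explicit
  identifiability error; fixing `K1` (donor constants are often known
  independently) makes a single level sufficient.
* **Uncertainty**: `bootstrap_confidence()` resamples records (cases), not
  residuals, refits each resample from the full-data estimate, and reports
  percentile intervals — no error model is asserted beyond exchangeability
  of records.

### The synthetic generator

`simulate_measurements()` emulates endpoint HPLC yield determinations: the
true equilibrium yield per condition, times multiplicative lognormal noise
with a given coefficient of variation (mean 1, so unbiased on the natural
scale), clipped to `[0, 1]`. The default design
(`measurement_conditions()`) mirrors the reference bench setup: 0.5 mM
acceptor base, two donor equivalents, phosphate at 0.2, 1 and 10
equivalents of the base, and a 5 % CV is a realistic figure for HPLC
endpoint yields. What the generator does *not* emulate: donor-side
analytics (only yields are simulated), systematic calibration error,
incomplete equilibration (a kinetic, not thermodynamic, effect), and
enzyme-dependent side reactions. Parameter-recovery results on this
generator therefore demonstrate the identifiability and correctness of the
estimation machinery under the stated error model, not robustness to those
real-world effects.

At this nine-record design with 5 % noise, the information content limits
the precision of `K1` more than `K2` (the donor constant acts mostly
through the weakly-observed `P1P` sequestration): the delta-method standard
deviation of `log K1` is about 0.17 versus about 0.10 for `log K2`. The
recovery test accordingly checks the median relative error pooled over both
constants' estimates across 100 generator seeds, plus a looser per-constant
bound; demanding much tighter per-constant accuracy at this design would
fail for *any* estimator of the stated objective, not just this one.

## Problem sizes used in the test suite

Property tests run at sizes chosen to exercise the numerics while keeping
the suite quick to iterate: 100 random systems for the solver-versus-oracle
comparison (constants log-uniform in `[1e-3, 10]`, all six initial
concentrations in `(0, 10]` mM), 200 systems for conservation and residual
checks, 15×(5–6)-point grids for the monotonicity suites, and 100 generator
seeds for parameter recovery. The independent oracle is a two-dimensional
grid-refinement search over the extents with a downhill-simplex polish of
the raw residual surface; it shares no code with the solver.

## Known limitations

* Thermodynamics only: no rate laws, enzyme loadings, or time-to-equilibrium
  estimates. The practical advice to run at 0.1–0.3 phosphate equivalents
  trades off against reaction speed, and only the yield side of that
  trade-off is modelled here.
* Apparent constants are taken as given at fixed conditions; no
  temperature/pH dependence, activity-coefficient or ionic-strength
  corrections, and no phosphate acid–base speciation.
* Ideal-solution equilibria: concentrations stand in for activities, which
  is adequate at the millimolar loadings typical of these reactions.
* The uniqueness of the feasible equilibrium is verified empirically, not
  proven; a convergence failure raises an error rather than silently
  returning a residual minimizer.
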