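# npyield

Equilibrium yield prediction and optimization for nucleoside
phosphorylase-catalyzed transglycosylations.

## The problem

Nucleoside phosphorylases (NPases) reversibly cleave a nucleoside with
phosphate into its free nucleobase and a pentose-1-phosphate (P1P). Coupling
two such half-reactions in one pot transfers the sugar from a donor
nucleoside **N1** to an acceptor base **B2**, producing the nucleoside of
interest **N2** — a protecting-group-free enzymatic glycosylation used to
make natural and base-modified nucleosides (including antiviral and
anticancer drugs). Because both half-reactions are reversible equilibria,
the attainable yield is a thermodynamic quantity: it is fixed by the two
apparent equilibrium constants of phosphorolysis,

    K1 = [B1][P1P] / ([N1][P])        (sugar donor)
    K2 = [B2][P1P] / ([N2][P])        (product nucleoside)

and by the initial loadings of donor, base and phosphate. `npyield`
implements this equilibrium model for synthesis planning: which donor
excess, which phosphate loading, which expected yield — and, inversely,
which constants explain a set of measured endpoint yields.

## The model

* **Ideal yield** (phosphate → 0+): the coupled system reduces to the net
  reaction `N1 + B2 <-> B1 + N2` with `K_N = K1/K2`, whose product
  concentration solves a quadratic with exactly one physically feasible
  root — `ideal_yield()` evaluates it in closed form.
* **Full equilibrium**: at finite phosphate, some sugar is sequestered as
  P1P and the product is itself phosphorolyzed. `solve_equilibrium()` finds
  the composition of all six species satisfying both equilibrium constraints
  with exact mass balance, via a reaction-extent parametrization and
  bracketed bisection (see the vignette for the scheme).
* **Design inversions**: `donor_for_target_yield()` (analytic),
  `donor_for_target_yield_with_phosphate()`, `max_phosphate_for_deviation()`
  and `yield_landscape()` answer planning questions directly.
* **Fitting**: `fit_constants()` estimates (K1, K2) from endpoint yield
  measurements across phosphate levels by least squares (Levenberg-
  Marquardt in log-K space, multi-start), with `bootstrap_confidence()`
  for case-resampling intervals and `simulate_measurements()` as the
  synthetic generator.

## Worked example

Uridine as sugar donor (`K1 = 0.16` at 60 °C, pH 9), 1 mM donor, 0.5 mM
acceptor base. Adenine (product adenosine, `K2 = 0.01`) versus
5-ethynyluracil (product 5-ethynyluridine, `K2 = 0.35`):

```r
library(npyield)

# low-K2 product: high ideal yield, mild phosphate sensitivity
ideal_yield(K_N = 0.16 / 0.01, N1_0 = 1, B2_0 = 0.5)$yield_fraction
#> [1] 0.9468027

# high-K2 product: lower ideal yield ...
yield_vs_phosphate(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
                   phosphate_equivs = c(0.2, 1, 10))
#> <yield_prediction>
#>   K1 = 0.16, K2 = 0.35 (K_N = 0.457143); N1_0 = 1 mM, B2_0 = 0.5 mM
#>   ideal yield (P -> 0+): 54.7858%
#>      0.2 equiv phosphate (0.1 mM): 52.6557%
#>        1 equiv phosphate (0.5 mM): 46.2483%
#>       10 equiv phosphate (5 mM): 23.3877%

# ... and a large phosphate gap at 10 equivalents
phosphate_gap(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
              phosphate_equiv = 10)
#> [1] 31.39809
```

The 54.8 % ideal yield collapses to 23.4 % at 10 phosphate equivalents — a
31.4 percentage-point loss — while the adenosine case only drops from
94.7 % to 86.1 %. Keeping phosphate at 0.1–0.3 equivalents of the starting
base preserves nearly the full ideal yield for any product:

```r
max_phosphate_for_deviation(K1 = 0.16, K2 = 0.35, N1_0 = 1, B2_0 = 0.5,
                            max_gap = 4)$phosphate_equiv
#> [1] 0.3999503
```

A command-line interface wraps the same functions
(`inst/cli/npyield`): subcommands `predict`, `solve`, `sensitivity`,
`design`, `landscape`, `fit` and `simulate`.

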