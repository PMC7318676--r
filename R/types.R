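#' Apparent equilibrium constant of phosphorolysis for one nucleoside
#'
#' A `phosphorolysis_entry` records the dimensionless apparent equilibrium
#' constant of the phosphorolysis of a single nucleoside,
#' \deqn{K = \frac{[\mathrm{base}][\mathrm{P1P}]}{[\mathrm{nucleoside}][\mathrm{P}]},}
#' together with the conditions (temperature, pH) under which it applies.
#' Apparent constants are condition-specific, so the metadata is part of the
#' record's identity.
#'
#' @param species_id Non-empty character label for the nucleoside
#'   (e.g. `"uridine"`).
#' @param K Dimensionless apparent equilibrium constant of phosphorolysis;
#'   must be finite and > 0.
#' @param temperature_C Temperature in degrees Celsius (may be `NA`).
#' @param pH pH of the measurement (may be `NA`).
#' @param source Free-text provenance note.
#'
#' @return An object of class `"phosphorolysis_entry"`: a list with the
#'   five fields above.
#' @examples
#' phosphorolysis_entry("uridine", K = 0.16, temperature_C = 60, pH = 9)
#' @export
phosphorolysis_entry <- function(species_id, K, temperature_C = NA_real_,
                                 pH = NA_real_, source = "") {
  if (!is.character(species_id) || length(species_id) != 1L ||
      is.na(species_id) || !nzchar(species_id)) {
    stop_domain("`species_id` must be a non-empty character string")
  }
  check_number(K, "K", lower = 0, strict = TRUE)
  structure(
    list(species_id = species_id, K = as.numeric(K),
         temperature_C = as.numeric(temperature_C), pH = as.numeric(pH),
         source = as.character(source)),
    class = "phosphorolysis_entry"
  )
}

#' @export
print.phosphorolysis_entry <- function(x, ...) {
  cat(sprintf("<phosphorolysis_entry> %s: K = %g (T = %g C, pH = %g)\n",
              x$species_id, x$K, x$temperature_C, x$pH))
  invisible(x)
}

#' Define a transglycosylation reaction system
#'
#' A transglycosylation couples two phosphorolysis half-reactions: the sugar
#' donor nucleoside N1 is phosphorolyzed to its base B1 and a
#' pentose-1-phosphate (P1P), which then glycosylates the acceptor base B2 to
#' give the product nucleoside N2. Phosphate is consumed in the first step and
#' released in the second, so it acts catalytically. The system is fully
#' described by the two apparent equilibrium constants of phosphorolysis and
#' the six initial concentrations.
#'
#' @param K1 Apparent equilibrium constant of phosphorolysis of the sugar
#'   donor nucleoside (dimensionless, > 0).
#' @param K2 Apparent equilibrium constant of phosphorolysis of the product
#'   nucleoside (dimensionless, > 0).
#' @param N1_0 Initial sugar donor concentration in mM (>= 0).
#' @param B2_0 Initial acceptor base concentration in mM (> 0; the yield is
#'   defined relative to it).
#' @param P_0 Initial inorganic phosphate concentration in mM (>= 0).
#' @param B1_0 Initial donor base concentration in mM (default 0).
#' @param N2_0 Initial product nucleoside concentration in mM (default 0).
#' @param P1P_0 Initial pentose-1-phosphate concentration in mM (default 0).
#'
#' @return An object of class `"transglycosylation_system"`; a list with the
#'   eight fields plus the derived net constant `K_N = K1/K2`.
#' @examples
#' # adenosine synthesis from adenine with uridine as sugar donor
#' transglycosylation_system(K1 = 0.16, K2 = 0.01,
#'                           N1_0 = 1, B2_0 = 0.5, P_0 = 5)
#' @seealso [solve_equilibrium()], [ideal_yield()]
#' @export
transglycosylation_system <- function(K1, K2, N1_0, B2_0, P_0,
                                      B1_0 = 0, N2_0 = 0, P1P_0 = 0) {
  check_number(K1, "K1", lower = 0, strict = TRUE)
  check_number(K2, "K2", lower = 0, strict = TRUE)
  check_number(N1_0, "N1_0", lower = 0)
  check_number(B2_0, "B2_0", lower = 0, strict = TRUE)
  check_number(P_0, "P_0", lower = 0)
  check_number(B1_0, "B1_0", lower = 0)
  check_number(N2_0, "N2_0", lower = 0)
  check_number(P1P_0, "P1P_0", lower = 0)
  K_N <- K1 / K2
  if (!is.finite(K_N) || K_N <= 0) {
    stop_domain("derived K_N = K1/K2 must be finite and > 0")
  }
  structure(
    list(K1 = as.numeric(K1), K2 = as.numeric(K2), K_N = K_N,
         N1_0 = as.numeric(N1_0), B1_0 = as.numeric(B1_0),
         N2_0 = as.numeric(N2_0), B2_0 = as.numeric(B2_0),
         P_0 = as.numeric(P_0), P1P_0 = as.numeric(P1P_0)),
    class = "transglycosylation_system"
  )
}

#' @export
print.transglycosylation_system <- function(x, ...) {
  cat("<transglycosylation_system>\n")
  cat(sprintf("  K1 = %g, K2 = %g  (K_N = %g)\n", x$K1, x$K2, x$K_N))
  cat(sprintf("  initial [mM]: N1 = %g, B1 = %g, N2 = %g, B2 = %g, P = %g, P1P = %g\n",
              x$N1_0, x$B1_0, x$N2_0, x$B2_0, x$P_0, x$P1P_0))
  invisible(x)
}

# Internal constructor for solver output; conservation holds by construction
# of the extent parametrization, not by re-validation here.
new_equilibrium_state <- function(system, xi2, delta, residual_K1, residual_K2,
                                  iterations) {
  xi1 <- xi2 + delta
  structure(
    list(
      N1 = system$N1_0 - xi1,
      B1 = system$B1_0 + xi1,
      N2 = system$N2_0 + xi2,
      B2 = system$B2_0 - xi2,
      P = system$P_0 - delta,
      P1P = system$P1P_0 + delta,
      yield_fraction = xi2 / system$B2_0,
      xi1 = xi1, xi2 = xi2,
      residual_K1 = residual_K1, residual_K2 = residual_K2,
      iterations = iterations,
      system = system
    ),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state>\n")
  cat(sprintf("  [mM]: N1 = %.6g, B1 = %.6g, N2 = %.6g, B2 = %.6g, P = %.6g, P1P = %.6g\n",
              x$N1, x$B1, x$N2, x$B2, x$P, x$P1P))
  cat(sprintf("  yield = %.4f%% of B2_0 (extents: xi1 = %.6g, xi2 = %.6g mM)\n",
              100 * x$yield_fraction, x$xi1, x$xi2))
  cat(sprintf("  relative residuals: K1 %.3g, K2 %.3g\n",
              x$residual_K1, x$residual_K2))
  invisible(x)
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat("<yield_prediction>\n")
  cat(sprintf("  K1 = %g, K2 = %g (K_N = %g); N1_0 = %g mM, B2_0 = %g mM\n",
              x$system$K1, x$system$K2, x$system$K_N,
              x$system$N1_0, x$system$B2_0))
  cat(sprintf("  ideal yield (P -> 0+): %.4f%%\n", 100 * x$ideal_yield))
  if (nrow(x$yields_at_phosphate)) {
    for (i in seq_len(nrow(x$yields_at_phosphate))) {
      r <- x$yields_at_phosphate[i, ]
      cat(sprintf("  %6.3g equiv phosphate (%g mM): %.4f%%\n",
                  r$phosphate_equiv, r$P_0_mM, 100 * r$yield_fraction))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.yield_prediction <- function(x, ...) {
  out <- data.frame(
    K1 = x$system$K1, K2 = x$system$K2, K_N = x$system$K_N,
    N1_0_mM = x$system$N1_0, B2_0_mM = x$system$B2_0,
    ideal_yield = x$ideal_yield
  )
  if (nrow(x$yields_at_phosphate)) {
    ys <- as.list(x$yields_at_phosphate$yield_fraction)
    names(ys) <- sprintf("yield_at_%gequiv",
                         x$yields_at_phosphate$phosphate_equiv)
    out <- cbind(out, as.data.frame(ys, check.names = FALSE))
  }
  out
}
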