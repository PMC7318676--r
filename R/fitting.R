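# Estimation of apparent equilibrium constants (K1, K2) from endpoint
# composition measurements, plus the synthetic measurement generator used for
# parameter-recovery studies.

MEASUREMENT_COLUMNS <- c("condition_id", "replicate", "N1_0_mM", "B2_0_mM",
                         "P_0_mM", "yield_fraction", "temperature_C", "pH")

validate_measurements <- function(data) {
  if (!is.data.frame(data)) {
    stop_domain("measurements must be a data frame")
  }
  needed <- c("N1_0_mM", "B2_0_mM", "P_0_mM", "yield_fraction")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    stop_parse(sprintf("measurement table is missing column(s): %s",
                       paste(missing, collapse = ", ")))
  }
  if (!nrow(data)) stop_domain("measurement table has no rows")
  num <- vapply(needed, function(cl) is.numeric(data[[cl]]), logical(1))
  if (!all(num)) {
    stop_parse(sprintf("non-numeric measurement column(s): %s",
                       paste(needed[!num], collapse = ", ")))
  }
  if (anyNA(data[needed])) stop_domain("measurement table contains NA values")
  if (any(data$N1_0_mM < 0) || any(data$B2_0_mM <= 0) || any(data$P_0_mM < 0)) {
    stop_domain("initial concentrations must be >= 0 (B2_0_mM > 0)")
  }
  if (any(data$yield_fraction < 0 | data$yield_fraction > 1)) {
    stop_domain("yield_fraction must lie in [0, 1]")
  }
  invisible(data)
}

#' Experimental design for endpoint measurements
#'
#' Convenience constructor for the condition table consumed by
#' [simulate_measurements()] and mirrored by real endpoint data: one row per
#' phosphate level at a fixed donor excess. The defaults reproduce the
#' reference bench setup (0.5 mM acceptor base, two donor equivalents, and
#' phosphate at 0.2, 1 and 10 equivalents of the base).
#'
#' @param donor_equiv Donor loading in equivalents of `B2_0`.
#' @param B2_0 Acceptor base concentration in mM.
#' @param phosphate_equivs Phosphate loadings in equivalents of `B2_0`.
#'
#' @return A data frame with columns `condition_id`, `N1_0_mM`, `B2_0_mM`,
#'   `P_0_mM`.
#' @examples
#' measurement_conditions()
#' @export
measurement_conditions <- function(donor_equiv = 2, B2_0 = 0.5,
                                   phosphate_equivs = c(0.2, 1, 10)) {
  data.frame(
    condition_id = sprintf("P%g", phosphate_equivs),
    N1_0_mM = donor_equiv * B2_0,
    B2_0_mM = B2_0,
    P_0_mM = phosphate_equivs * B2_0
  )
}

#' Simulate endpoint composition measurements
#'
#' Generates synthetic endpoint yield measurements from the full equilibrium
#' model: the true yield at each condition is computed with
#' [solve_equilibrium()] and perturbed by multiplicative lognormal noise with
#' the requested coefficient of variation (mean 1, so the noise is unbiased on
#' the natural scale), then clipped to `[0, 1]`. This emulates the relative
#' error structure of HPLC endpoint determinations.
#'
#' @param K1_true,K2_true True apparent equilibrium constants of
#'   phosphorolysis used to generate the data.
#' @param conditions Data frame with columns `N1_0_mM`, `B2_0_mM`, `P_0_mM`
#'   (and optionally `condition_id`); see [measurement_conditions()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 returns the exact model yields).
#' @param n_replicates Number of replicates per condition.
#' @param seed Integer seed; identical seeds give identical sets.
#' @param temperature_C,pH Condition metadata copied into the output.
#'
#' @return A measurement data frame with columns `condition_id`, `replicate`,
#'   `N1_0_mM`, `B2_0_mM`, `P_0_mM`, `yield_fraction`, `temperature_C`, `pH`.
#' @examples
#' simulate_measurements(0.16, 0.35, measurement_conditions(),
#'                       noise_cv = 0.05, n_replicates = 3, seed = 1)
#' @export
simulate_measurements <- function(K1_true, K2_true, conditions,
                                  noise_cv = 0, n_replicates = 1L,
                                  seed = NULL, temperature_C = 60, pH = 9) {
  check_number(K1_true, "K1_true", lower = 0, strict = TRUE)
  check_number(K2_true, "K2_true", lower = 0, strict = TRUE)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(as.numeric(n_replicates), "n_replicates", lower = 1)
  if (!is.data.frame(conditions) ||
      !all(c("N1_0_mM", "B2_0_mM", "P_0_mM") %in% names(conditions))) {
    stop_domain("`conditions` must be a data frame with columns N1_0_mM, B2_0_mM, P_0_mM")
  }
  if (is.null(conditions$condition_id)) {
    conditions$condition_id <- sprintf("cond%02d", seq_len(nrow(conditions)))
  }
  if (!is.null(seed)) set.seed(seed)
  truth <- yield_at(K1_true, K2_true, conditions$N1_0_mM,
                    conditions$B2_0_mM, conditions$P_0_mM)
  n_rep <- as.integer(n_replicates)
  out <- conditions[rep(seq_len(nrow(conditions)), each = n_rep),
                    c("condition_id", "N1_0_mM", "B2_0_mM", "P_0_mM"),
                    drop = FALSE]
  out$replicate <- rep(seq_len(n_rep), times = nrow(conditions))
  y <- rep(truth, each = n_rep)
  if (noise_cv > 0) {
    sdlog <- sqrt(log1p(noise_cv^2))
    fac <- stats::rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    y <- pmin(pmax(y * fac, 0), 1)
  }
  out$yield_fraction <- y
  out$temperature_C <- temperature_C
  out$pH <- pH
  rownames(out) <- NULL
  out[MEASUREMENT_COLUMNS]
}

# Weighted residual vector over (log K1, log K2); vectorized over records.
# Sum of squared residuals is the least-squares loss on yield fractions.
fit_residual_fn <- function(data, weights, fixed_logK1 = NULL) {
  y <- data$yield_fraction
  sw <- sqrt(weights)
  function(par) {
    lk1 <- if (is.null(fixed_logK1)) par[1] else fixed_logK1
    lk2 <- if (is.null(fixed_logK1)) par[2] else par[1]
    pred <- yield_at(exp(lk1), exp(lk2), data$N1_0_mM, data$B2_0_mM,
                     data$P_0_mM)
    sw * (pred - y)
  }
}

# Levenberg-Marquardt from one start, in log-K space with box bounds.
fit_one_start <- function(resid_fn, start, lb, ub) {
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn, lower = rep(lb, length(start)),
      upper = rep(ub, length(start)),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-15, ptol = 1e-15, gtol = 0, maxiter = 200)),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  list(par = res$par, value = res$deviance, info = res$info,
       message = res$message)
}

#' Fit apparent equilibrium constants to endpoint yields
#'
#' Estimates the apparent equilibrium constants of phosphorolysis of the
#' sugar donor (`K1`) and the product nucleoside (`K2`) by least squares on
#' the measured endpoint yields, with predictions from the full equilibrium
#' model. The fit is parametrized in `log K` (enforcing positivity) with box
#' bounds `K` in `[1e-6, 1e3]` and a multi-start over a 3 x 3 logarithmic
#' grid to avoid local basins; the best start is polished to high precision.
#'
#' Joint identifiability of `(K1, K2)` requires measurements at two or more
#' distinct phosphate levels: the ideal yield constrains only the ratio
#' `K_N = K1/K2`, and it is the phosphate response that separates the two
#' constants. With `fix_K1` supplied (donor constant known independently), a
#' single level suffices.
#'
#' @param data Measurement data frame with columns `N1_0_mM`, `B2_0_mM`,
#'   `P_0_mM`, `yield_fraction` (see [simulate_measurements()] for the full
#'   layout).
#' @param fix_K1 Optional known value of `K1`; when supplied only `K2` is
#'   estimated.
#' @param weights Optional non-negative per-record weights (default uniform).
#'
#' @return An object of class `"npyield_fit"`: a list with `K1_hat`,
#'   `K2_hat`, `loss` (residual sum of squares), `fitted`, `residuals`
#'   (observed minus fitted), `n_obs`, `fix_K1` and optimizer diagnostics.
#' @examples
#' set.seed(1)
#' d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
#'                            noise_cv = 0, n_replicates = 1)
#' fit_constants(d)
#' @export
fit_constants <- function(data, fix_K1 = NULL, weights = NULL) {
  validate_measurements(data)
  if (!is.null(fix_K1)) check_number(fix_K1, "fix_K1", lower = 0, strict = TRUE)
  if (is.null(weights)) {
    weights <- rep(1, nrow(data))
  } else {
    check_number(weights, "weights", lower = 0, len = nrow(data))
  }
  n_levels <- length(unique(data$P_0_mM))
  if (is.null(fix_K1) && n_levels < 2L) {
    stop_identifiability(paste0(
      "all measurements are at a single phosphate level: (K1, K2) are not ",
      "jointly identifiable (the ideal yield constrains only K_N = K1/K2). ",
      "Provide >= 2 phosphate levels or fix K1."))
  }

  lb <- log(1e-6)
  ub <- log(1e3)
  grid <- log(10^c(-4, -1, 2))
  starts <- if (is.null(fix_K1)) {
    as.matrix(expand.grid(lk1 = grid, lk2 = grid))
  } else {
    matrix(grid, ncol = 1, dimnames = list(NULL, "lk2"))
  }
  fixed_lk1 <- if (is.null(fix_K1)) NULL else log(fix_K1)
  resid_fn <- fit_residual_fn(data, weights, fixed_lk1)

  # rank the grid starts by loss, then run Levenberg-Marquardt from the
  # three most promising basins
  loss0 <- vapply(seq_len(nrow(starts)),
                  function(i) sum(resid_fn(starts[i, ])^2), numeric(1))
  best <- NULL
  for (i in order(loss0)[seq_len(min(3L, nrow(starts)))]) {
    res <- fit_one_start(resid_fn, starts[i, ], lb, ub)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    stop_convergence("optimizer failed from every start of the 3x3 log grid")
  }

  if (is.null(fix_K1)) {
    K1_hat <- exp(best$par[[1]])
    K2_hat <- exp(best$par[[2]])
  } else {
    K1_hat <- fix_K1
    K2_hat <- exp(best$par[[1]])
  }
  fitted <- yield_at(K1_hat, K2_hat, data$N1_0_mM, data$B2_0_mM, data$P_0_mM)
  structure(
    list(K1_hat = unname(K1_hat), K2_hat = unname(K2_hat),
         loss = best$value, fitted = fitted,
         residuals = data$yield_fraction - fitted,
         n_obs = nrow(data), n_phosphate_levels = n_levels,
         fix_K1 = fix_K1, convergence = best$info,
         message = best$message),
    class = "npyield_fit"
  )
}

#' @export
print.npyield_fit <- function(x, ...) {
  cat("<npyield_fit>\n")
  k1 <- if (is.null(x$fix_K1)) sprintf("%.6g", x$K1_hat)
        else sprintf("%.6g (fixed)", x$K1_hat)
  cat(sprintf("  K1 = %s, K2 = %.6g  (K_N = %.6g)\n",
              k1, x$K2_hat, x$K1_hat / x$K2_hat))
  cat(sprintf("  RSS = %.4g over %d records at %d phosphate level(s)\n",
              x$loss, x$n_obs, x$n_phosphate_levels))
  invisible(x)
}

#' Bootstrap confidence intervals for fitted equilibrium constants
#'
#' Case-resampling bootstrap over measurement records: each resample redraws
#' records with replacement, refits the model (started from the full-data
#' estimates), and the percentile interval of the resampled estimates is
#' reported. Resampling cases rather than residuals avoids asserting an error
#' model for the endpoint determinations.
#'
#' @inheritParams fit_constants
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param level Confidence level (default 0.95).
#'
#' @return A list with the point estimates, matrices of bootstrap draws, the
#'   `K1_interval` and `K2_interval` percentile intervals, and the number of
#'   resamples that failed to fit (resamples failing to fit are recorded and
#'   skipped; more than 20 % failures is an error).
#' @examples
#' d <- simulate_measurements(0.16, 0.35, measurement_conditions(),
#'                            noise_cv = 0.05, n_replicates = 3, seed = 7)
#' bootstrap_confidence(d, n_boot = 100, seed = 7)
#' @export
bootstrap_confidence <- function(data, n_boot = 200L, seed = NULL,
                                 level = 0.95, fix_K1 = NULL) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 100) {
    stop_domain("`n_boot` must be >= 100")
  }
  validate_measurements(data)
  full <- fit_constants(data, fix_K1 = fix_K1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                  dimnames = list(NULL, c("K1", "K2")))
  failures <- 0L
  start <- if (is.null(fix_K1)) {
    c(log(full$K1_hat), log(full$K2_hat))
  } else {
    log(full$K2_hat)
  }
  fixed_lk1 <- if (is.null(fix_K1)) NULL else log(fix_K1)
  lb <- log(1e-6); ub <- log(1e3)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- data[idx, , drop = FALSE]
    res <- tryCatch({
      if (is.null(fix_K1) && length(unique(d$P_0_mM)) < 2L) {
        stop("degenerate resample: a single phosphate level")
      }
      fit_one_start(fit_residual_fn(d, rep(1, n), fixed_lk1), start, lb, ub)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
    } else if (is.null(fix_K1)) {
      draws[b, ] <- exp(res$par)
    } else {
      draws[b, ] <- c(fix_K1, exp(res$par[[1]]))
    }
  }
  if (failures > 0.2 * n_boot) {
    stop_convergence(sprintf(
      "%d of %d bootstrap resamples failed to fit (> 20%%)",
      failures, n_boot))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ok <- stats::complete.cases(draws)
  list(
    K1_hat = full$K1_hat, K2_hat = full$K2_hat,
    K1_interval = stats::quantile(draws[ok, "K1"], probs, names = FALSE),
    K2_interval = stats::quantile(draws[ok, "K2"], probs, names = FALSE),
    draws = draws[ok, , drop = FALSE],
    n_boot = n_boot, n_failed = failures, level = level
  )
}
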