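# Condition classes used across the package.
#
# npyield_domain_error        invalid inputs (maps to CLI exit code 2)
#   npyield_parse_error         malformed files / flags
#   npyield_identifiability_error  fitting design cannot identify (K1, K2)
#   npyield_infeasible_error    design target unreachable at the given settings
# npyield_convergence_error   iteration budget exhausted (CLI exit code 1)

npyield_stop <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "npyield_error", "error", "condition"),
    list(message = message, call = sys.call(-2), ...)
  )
  stop(cond)
}

stop_domain <- function(message, ...) {
  npyield_stop(message, "npyield_domain_error", ...)
}

stop_parse <- function(message, ...) {
  npyield_stop(message, c("npyield_parse_error", "npyield_domain_error"), ...)
}

stop_identifiability <- function(message, ...) {
  npyield_stop(message, c("npyield_identifiability_error", "npyield_domain_error"), ...)
}

stop_infeasible <- function(message, ...) {
  npyield_stop(message, c("npyield_infeasible_error", "npyield_domain_error"), ...)
}

stop_convergence <- function(message, residuals = NULL, ...) {
  npyield_stop(message, "npyield_convergence_error", residuals = residuals, ...)
}

# Scalar numeric validators -------------------------------------------------

check_number <- function(x, name, lower = -Inf, strict = FALSE,
                         finite = TRUE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x)) {
    stop_domain(sprintf("`%s` must be a numeric value of length %d", name, len))
  }
  if (finite && any(!is.finite(x))) {
    stop_domain(sprintf("`%s` must be finite", name))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    op <- if (strict) ">" else ">="
    stop_domain(sprintf("`%s` must be %s %g (got %g)", name, op, lower, x[1]))
  }
  invisible(x)
}
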