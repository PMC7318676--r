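# File formats: constants tables (CSV), reaction configs (YAML), measurement
# sets (CSV) and result serialization (CSV/JSON).

#' Read a table of apparent equilibrium constants of phosphorolysis
#'
#' Reads a CSV table with header `species_id, K, temperature_C, pH, source`
#' (comma-separated, dot decimal, UTF-8) and validates every row. Because
#' apparent constants are condition-specific, the key of an entry is
#' `(species_id, temperature_C, pH)`; duplicate keys are an error.
#'
#' @param path Path to the CSV file.
#' @return A list of [phosphorolysis_entry()] objects (empty for a
#'   header-only file).
#' @examples
#' tab <- system.file("extdata", "phosphorolysis_constants.csv",
#'                    package = "npyield")
#' read_constants_table(tab)
#' @export
read_constants_table <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path,
                                           conditionMessage(e))))
  needed <- c("species_id", "K", "temperature_C", "pH", "source")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_parse(sprintf("constants table %s is missing column(s): %s",
                       path, paste(missing, collapse = ", ")))
  }
  entries <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row_no <- i + 1L  # file row, counting the header as row 1
    entries[[i]] <- tryCatch(
      phosphorolysis_entry(as.character(df$species_id[i]),
                           as.numeric(df$K[i]),
                           as.numeric(df$temperature_C[i]),
                           as.numeric(df$pH[i]),
                           as.character(df$source[i])),
      npyield_domain_error = function(e) {
        stop_parse(sprintf("row %d of %s: %s", row_no, path,
                           conditionMessage(e)))
      })
  }
  key <- sprintf("%s@%g@%g", df$species_id, df$temperature_C, df$pH)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop_parse(sprintf(
      "duplicate (species_id, temperature_C, pH) entries in %s: %s",
      path, paste(dup, collapse = "; ")))
  }
  entries
}

#' Read a transglycosylation reaction configuration
#'
#' Reads a YAML configuration (the package's documented config dialect) with
#' required keys `K1`, `K2`, `N1_0_mM`, `B2_0_mM`, `P_0_mM` and optional
#' `B1_0_mM`, `N2_0_mM`, `P1P_0_mM` (defaulting to 0, matching the usual
#' bench setup where only donor, acceptor base and phosphate are charged).
#' Unknown keys produce a warning, not an error, so configs may carry
#' free-form annotations.
#'
#' @param path Path to the YAML file.
#' @return A [transglycosylation_system()].
#' @export
read_reaction_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse(sprintf(
                    "cannot parse YAML config %s: %s", path,
                    conditionMessage(e))))
  if (!is.list(cfg)) stop_parse(sprintf("config %s is not a key-value map", path))
  required <- c("K1", "K2", "N1_0_mM", "B2_0_mM", "P_0_mM")
  optional <- c("B1_0_mM", "N2_0_mM", "P1P_0_mM")
  for (key in required) {
    if (is.null(cfg[[key]])) {
      stop_parse(sprintf("config %s: missing %s", path, key))
    }
  }
  unknown <- setdiff(names(cfg), c(required, optional))
  if (length(unknown)) {
    warning(sprintf("config %s: ignoring unknown key(s): %s", path,
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  get0_ <- function(key) if (is.null(cfg[[key]])) 0 else as.numeric(cfg[[key]])
  transglycosylation_system(
    K1 = as.numeric(cfg$K1), K2 = as.numeric(cfg$K2),
    N1_0 = as.numeric(cfg$N1_0_mM), B2_0 = as.numeric(cfg$B2_0_mM),
    P_0 = as.numeric(cfg$P_0_mM),
    B1_0 = get0_("B1_0_mM"), N2_0 = get0_("N2_0_mM"),
    P1P_0 = get0_("P1P_0_mM")
  )
}

#' Read endpoint measurements from CSV
#'
#' @param path CSV file with header `condition_id, replicate, N1_0_mM,
#'   B2_0_mM, P_0_mM, yield_fraction, temperature_C, pH`.
#' @return A validated measurement data frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing)) {
    stop_parse(sprintf("measurement file %s is missing column(s): %s",
                       path, paste(missing, collapse = ", ")))
  }
  validate_measurements(df)
  df
}

#' Write endpoint measurements to CSV
#'
#' @param data Measurement data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_measurements <- function(data, path) {
  validate_measurements(data)
  out <- data[intersect(MEASUREMENT_COLUMNS, names(data))]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write prediction or landscape results to CSV or JSON
#'
#' Serializes result records deterministically: columns in their input order
#' (inputs first, then ideal yield, then phosphate-adjusted yields, as
#' produced by the package's result objects), numeric values at 6 significant
#' digits, and the JSON form mirroring the CSV fields row by row. Writing the
#' same records twice yields byte-identical files.
#'
#' @param records A data frame, a `yield_prediction`, or a list of either
#'   (rows are bound in order).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, the path.
#' @export
write_results <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- results_frame(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  ok <- tryCatch({
    if (format == "csv") {
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           pretty = TRUE, na = "null")
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    npyield_stop(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                 c("npyield_io_error", "npyield_domain_error"))
  }
  invisible(path)
}

results_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  if (inherits(records, "yield_prediction")) return(as.data.frame(records))
  if (is.list(records)) {
    if (!length(records)) return(data.frame())
    parts <- lapply(records, results_frame)
    cols <- unique(unlist(lapply(parts, names)))
    parts <- lapply(parts, function(p) {
      for (cl in setdiff(cols, names(p))) p[[cl]] <- NA
      p[cols]
    })
    return(do.call(rbind, parts))
  }
  stop_domain("`records` must be a data frame, a yield_prediction, or a list of them")
}
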