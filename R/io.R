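#' Write a power curve to CSV
#'
#' PPE curves are written with columns `n,lambda,power,ci_low,ci_high`
#' (missing confidence columns filled with `NA`); MCPE curves with columns
#' `n,power,n_rejected,n_total`.
#'
#' @param curve a `"ppe_curve"` (from [predict.ppe()]) or `"mcpe_curve"`
#'   (from [mcpe_power_curve()]) data frame.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_power_curve <- function(curve, file) {
  if (inherits(curve, "ppe_curve")) {
    out <- data.frame(n = curve$n, lambda = curve$lambda, power = curve$power,
                      ci_low = curve$ci_low %||% NA_real_,
                      ci_high = curve$ci_high %||% NA_real_)
  } else if (inherits(curve, "mcpe_curve")) {
    out <- curve[c("n", "power", "n_rejected", "n_total")]
  } else {
    stop("'curve' must be a ppe_curve or mcpe_curve")
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Read a power curve written by [write_power_curve()]
#' @param file path to the CSV.
#' @return a data frame.
#' @export
read_power_curve <- function(file) {
  dat <- utils::read.csv(file)
  if (!"n" %in% names(dat) || !"power" %in% names(dat))
    stop("'", file, "' is not a power-curve CSV")
  dat
}

#' Write the diagnostic band to CSV (`t,band_low,band_high,ecdf`)
#'
#' The empirical CDF column is interpolated onto the band's grid (step
#' interpolation), so one file carries both curves.
#'
#' @param diag a `"ppe_diagnostic"` object.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_diagnostic <- function(diag, file) {
  stopifnot(inherits(diag, "ppe_diagnostic"))
  ec <- stats::stepfun(diag$statistics, c(0, diag$ecdf))(diag$t_grid)
  utils::write.csv(data.frame(t = diag$t_grid, band_low = diag$band_low,
                              band_high = diag$band_high, ecdf = ec),
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_diagnostic
#' @export
read_diagnostic <- function(file) {
  dat <- utils::read.csv(file)
  need <- c("t", "band_low", "band_high", "ecdf")
  if (!all(need %in% names(dat)))
    stop("'", file, "' is not a diagnostic CSV")
  dat
}

#' Read a flat TOML run configuration
#'
#' Parses the minimal TOML subset used for run configuration: a single
#' `[run]` table of `key = value` lines with string, number, boolean or flat
#' numeric/string array (`[a, b, c]`) values, plus comments.  No installed
#' package parses TOML, and nothing beyond this flat subset is accepted.
#'
#' @param file path to the TOML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  in_run <- TRUE  # values before any table header also count
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      in_run <- identical(ln, "[run]")
      next
    }
    if (!in_run) next
    if (!grepl("=", ln, fixed = TRUE))
      stop("cannot parse config line: '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_toml_value(val, key)
  }
  out
}

parse_toml_value <- function(val, key) {
  if (grepl("^\\[.*\\]$", val)) {
    parts <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", val), ",")[[1]])
    parts <- parts[nzchar(parts)]
    return(unlist(lapply(parts, parse_toml_value, key = key)))
  }
  if (grepl("^\".*\"$", val) || grepl("^'.*'$", val))
    return(substr(val, 2, nchar(val) - 1))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("cannot parse value for '", key, "': ", val)
  num
}

## Minimal logging: INFO to stderr, plus a machine-readable JSON sidecar.
ppe_log <- function(...) message("[ppestim] ", ...)

write_sidecar <- function(path, config, results) {
  jsonlite::write_json(list(config = config, results = results), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
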