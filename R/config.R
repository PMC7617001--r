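#' Read a flat TOML configuration file
#'
#' Lightweight reader for the flat TOML subset used by the package's
#' configuration files: `[section]` (and dotted `[a.b]`) headers with
#' `key = value` pairs, where values are numbers, booleans or
#' double-quoted strings. Comments (`#`) and blank lines are ignored.
#' Arrays, dates and multi-line strings are not supported.
#'
#' @param path File path.
#' @return Named list of sections, each a named list of values.
#' @export
read_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("(^|\\s)#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", ln)
      out[[cur]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(cur)) stop("key outside of a [section]: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[cur]][[key]] <- parse_toml_scalar(val)
    } else stop("unparseable TOML line: ", ln)
  }
  out
}

parse_toml_scalar <- function(val) {
  if (grepl('^".*"$', val)) return(sub('^"(.*)"$', "\\1", val))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("unsupported TOML value: ", val)
  num
}

#' Load device and modulator configuration from TOML
#'
#' Reads a file with `[magstim]` and `[ptms]` sections mirroring the
#' fields of [device_config()] and [pwm_config()]. Missing keys fall
#' back to the package defaults. A template lives in
#' `system.file("extdata", "device_config.toml", package = "pwmtms")`.
#'
#' @param path TOML file path.
#' @return List with elements `magstim` ([device_config()]) and `ptms`
#'   ([pwm_config()]).
#' @export
read_device_config <- function(path) {
  s <- read_flat_toml(path)
  m <- s$magstim %||% list()
  p <- s$ptms %||% list()
  list(
    magstim = do.call(device_config, m[names(m) %in%
      names(formals(device_config))]),
    ptms = do.call(pwm_config, p[names(p) %in% names(formals(pwm_config))])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
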