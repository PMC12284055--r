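# Flat key-value configuration files for scripted runs.

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment and blank lines
#' are ignored.  Values that parse as numbers are returned numeric.
#' Recognized keys include `frequency_hz`, `desired_current_ma`,
#' `samples_per_period`, `adc_bits`, `shunt_ohm` and `seed`.
#'
#' @param path Path to the configuration file.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config Named list of scalar values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, character(1))), path)
  invisible(path)
}
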