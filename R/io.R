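## Plain-text interfaces: key:value configuration files and delimited
## time-sweep tables (the rheometer-emulation format).

#' Read a key:value configuration file
#'
#' One `key: value` pair per line; blank lines and `#` comments are
#' ignored. Values are parsed as numeric where possible (comma-separated
#' values become numeric vectors), otherwise kept as strings. If `allowed`
#' is supplied, unknown keys are an error.
#'
#' @param path file path.
#' @param allowed optional character vector of permitted keys.
#' @return Named list.
#' @export
read_gel_config <- function(path, allowed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):(.*)$", lines))
  if (any(lengths(kv) != 3)) abort("malformed config line (expected key: value)")
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  if (!is.null(allowed)) {
    bad <- setdiff(keys, allowed)
    if (length(bad))
      abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  }
  parse1 <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else v
  }
  setNames(lapply(vals, parse1), keys)
}

#' Write a key:value configuration file
#'
#' @param config named list of scalars or numeric vectors.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gel_config <- function(config, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(format(v, digits = 15, scientific = NA,
                                    trim = TRUE), collapse = ", ")
    else as.character(v)
  }
  writeLines(paste0(names(config), ": ", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

#' Read a rheometer time-sweep table
#'
#' Delimited text with header columns `time_s`, `omega_rad_s`, `Gp_Pa`,
#' `Gpp_Pa` (additional columns are preserved).
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_time_sweep <- function(path) {
  out <- as_tibble(read.csv(path, check.names = TRUE))
  .check_profile(out, c("time_s", "omega_rad_s", "Gp_Pa", "Gpp_Pa"))
  out
}

#' Write a rheometer time-sweep table
#'
#' @param data data frame with at least `time_s`, `omega_rad_s`, `Gp_Pa`,
#'   `Gpp_Pa`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_time_sweep <- function(data, path) {
  .check_profile(data, c("time_s", "omega_rad_s", "Gp_Pa", "Gpp_Pa"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a binding trajectory as delimited text
#'
#' Columns `time_s`, `R`.
#'
#' @param trajectory a [solve_binding_ode()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(data.frame(time_s = trajectory$time_s, R = trajectory$R),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
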