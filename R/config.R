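#' Read a run configuration file
#'
#' The configuration dialect is flat key-value text with bracketed
#' sections:
#' ```
#' [chain]
#' n_angles: 1
#' inertias: 1.0
#' [potential]
#' kind: harmonic_spring
#' k: 1
#' half_k: true
#' [time]
#' t0: 0
#' t1: 4
#' n_steps: 800
#' ```
#' Values are parsed as numbers, `true`/`false` logicals, or
#' comma-separated numeric vectors; anything else stays a string. Unknown
#' sections or keys are rejected (typos must not pass silently). The parsed
#' structure round-trips losslessly through [write_run_config()].
#'
#' Recognized sections and keys:
#' \describe{
#'   \item{chain}{`n_angles`, `inertias`}
#'   \item{potential}{`kind`, `k`, `half_k`, `k_plus`, `k_minus`,
#'     `theta_ref`, `a`, `b`, `linear`}
#'   \item{time}{`t0`, `t1`, `n_steps`, `method`}
#'   \item{family}{`u_min`, `u_max`, `u_n`, `vary` (`velocity` or
#'     `position`), `q0`, `v0`}
#'   \item{detection}{`tol_first`, `tol_second`, `stationarity_tol`,
#'     `classify`}
#'   \item{output}{`out_dir`, `report`}
#'   \item{run}{`seed`, `log_level`}
#' }
#'
#' @param path path to the config file.
#' @return a nested list of sections, class `RunConfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  parse_run_config(lines)
}

config_schema <- function() {
  list(
    chain = c("n_angles", "inertias"),
    potential = c("kind", "k", "half_k", "k_plus", "k_minus", "theta_ref",
                  "a", "b", "linear"),
    time = c("t0", "t1", "n_steps", "method"),
    family = c("u_min", "u_max", "u_n", "vary", "q0", "v0"),
    detection = c("tol_first", "tol_second", "stationarity_tol",
                  "classify"),
    output = c("out_dir", "report"),
    run = c("seed", "log_level")
  )
}

parse_run_config <- function(lines) {
  schema <- config_schema()
  cfg <- list()
  section <- NULL
  for (ln_no in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[ln_no]))
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(schema))
        stop("unknown config section [", section, "] (line ", ln_no,
             "); known sections: ", paste(names(schema), collapse = ", "),
             call. = FALSE)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
      next
    }
    if (is.null(section))
      stop("config line ", ln_no, " appears before any [section]",
           call. = FALSE)
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line ", ln_no, ": '", ln, "'",
           call. = FALSE)
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% schema[[section]])
      stop("unknown key '", key, "' in section [", section, "] (line ",
           ln_no, "); allowed keys: ",
           paste(schema[[section]], collapse = ", "), call. = FALSE)
    cfg[[section]][[key]] <- parse_config_value(val)
  }
  structure(cfg, class = "RunConfig")
}

parse_config_value <- function(val) {
  if (tolower(val) %in% c("true", "false"))
    return(tolower(val) == "true")
  if (grepl(",", val)) {
    parts <- trimws(strsplit(val, ",")[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    if (!anyNA(nums)) return(nums)
    return(parts)
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' @rdname read_run_config
#' @param config a `RunConfig`.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, paste0("[", sec, "]"))
    for (key in names(config[[sec]])) {
      v <- config[[sec]][[key]]
      txt <- if (is.logical(v)) tolower(as.character(v)) else
        paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = ", ")
      lines <- c(lines, paste0(key, ": ", txt))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.RunConfig <- function(x, ...) {
  cat("<RunConfig> sections:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
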