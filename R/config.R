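# Flat key-value configuration files (a strict YAML-like dialect: one
# `key: value` pair per line, `#` comments, no nesting). Lists are
# comma-separated scalars. Unknown keys are rejected against a per-command
# schema.

sto_error <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

config_error <- function(...) stop(sto_error(paste0(...), "sto_config_error"))
format_error <- function(...) stop(sto_error(paste0(...), "sto_format_error"))

#' Parse a flat key-value configuration file
#'
#' @param path File of `key: value` lines; `#` starts a comment; blank
#'   lines ignored. Values are parsed as logical, numeric, comma-separated
#'   numeric vectors, or strings.
#' @return Named list.
#' @export
parse_flat_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr(":", ln, fixed = TRUE)
    if (m < 0) config_error("malformed config line (expected 'key: value'): ",
                            ln)
    key <- trimws(substr(ln, 1L, m - 1L))
    val <- trimws(substr(ln, m + 1L, nchar(ln)))
    if (!nzchar(key)) config_error("empty key in config line: ", ln)
    if (key %in% names(out)) config_error("duplicate config key: ", key)
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (val %in% c("true", "TRUE", "yes")) return(TRUE)
  if (val %in% c("false", "FALSE", "no")) return(FALSE)
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  nums <- suppressWarnings(as.numeric(parts))
  if (length(parts) && !anyNA(nums)) {
    if (length(nums) == 1L) return(nums)
    return(nums)
  }
  val
}

check_config_keys <- function(cfg, schema, command) {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    config_error("unknown key(s) for '", command, "': ",
                 paste(unknown, collapse = ", "),
                 "\n  known keys: ", paste(names(schema), collapse = ", "))
  cfg
}

config_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

write_provenance <- function(out_dir, command, params, inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(command = command,
              package = "stomap",
              version = as.character(utils::packageVersion("stomap")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              parameters = params,
              input_md5 = hashes)
  jsonlite::write_json(obj, file.path(out_dir, paste0(command, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
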