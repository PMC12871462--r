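# Minimal reader/writer for the flat TOML subset used by run configs:
# top-level tables, scalar and array values, comments. Field names mirror
# incubation_config()/true_state() exactly.

.parse_toml_value <- function(txt) {
  txt <- trimws(txt)
  if (grepl("^\\[", txt)) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    if (trimws(inner) == "") return(numeric(0))
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, .parse_toml_value), use.names = FALSE))
  }
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  if (txt %in% c("nan", "inf", "-inf")) {
    return(switch(txt, nan = NaN, inf = Inf, `-inf` = -Inf))
  }
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop(sprintf("cannot parse TOML value: %s", txt))
}

#' Read a run configuration file
#'
#' Parses the flat TOML subset used for run configs (top-level key/value
#' pairs plus `[incubation]`, `[truth]`, `[scenario]`-style tables with
#' scalar or array values). Keys mirror the field names of
#' [incubation_config()] and [true_state()].
#'
#' @param path Path to the TOML file.
#' @return A named list; each table becomes a named sub-list.
#' @export
read_config_toml <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("(^|[^\"])#.*$", "\\1", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[[A-Za-z0-9_.:-]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln,
                    regexec("^\"?([^=\"]+?)\"?\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) stop(sprintf("cannot parse TOML line: %s", ln))
    key <- m[2]; val <- .parse_toml_value(m[3])
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

.format_toml_value <- function(v) {
  one <- function(x) {
    if (is.character(x)) sprintf('"%s"', x)
    else if (is.logical(x)) tolower(as.character(x))
    else if (is.na(x)) "nan"
    else format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  if (length(v) == 1) one(v)
  else sprintf("[%s]", paste(vapply(v, one, character(1)), collapse = ", "))
}

#' Write a run configuration file
#'
#' Serializes a named list (optionally with one level of named sub-lists) to
#' the TOML subset read by [read_config_toml()]. Round-trips losslessly for
#' numeric, logical and character scalars and arrays.
#'
#' @param config Named list to serialize.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config_toml <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- character(0)
  scalars <- config[!vapply(config, function(x) is.list(x), logical(1))]
  tables <- config[vapply(config, is.list, logical(1))]
  for (k in names(scalars)) {
    v <- scalars[[k]]
    if (!is.null(names(v)) && length(v) > 1) {
      # named vector -> its own table
      tables[[k]] <- as.list(v)
      next
    }
    lines <- c(lines, sprintf("%s = %s", k, .format_toml_value(v)))
  }
  for (tk in names(tables)) {
    lines <- c(lines, "", sprintf("[%s]", tk))
    tb <- tables[[tk]]
    sub <- character(0)
    for (k in names(tb)) {
      v <- tb[[k]]
      if (!is.null(names(v)) && length(v) > 1) {
        # named vector inside a table -> dotted sub-table
        sub <- c(sub, "", sprintf("[%s.%s]", tk, k),
                 vapply(names(v), function(nm) {
                   sprintf('"%s" = %s', nm, .format_toml_value(v[[nm]]))
                 }, character(1)))
        next
      }
      lines <- c(lines, sprintf("%s = %s", k, .format_toml_value(v)))
    }
    lines <- c(lines, sub)
  }
  writeLines(lines, path)
  invisible(path)
}
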