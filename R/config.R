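#' Read a HomoDist run configuration file
#'
#' Parses a plain `key = value` file using the classic argument names of
#' the procedure — `autCen` (TRUE/FALSE automatic center search), `defCen`
#' (taxon label or 1-based position of the chosen center when `autCen` is
#' FALSE), `distmodel` (distance model, default F84) — plus `treemethods`
#' (comma-separated subset of `nj,upgma`) and `trim` (TRUE/FALSE). Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return A named list of arguments for [run_homodist()]:
#'   `auto_center`, `center`, `model`, `tree_methods`, `trim`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  known <- c("autCen", "defCen", "distmodel", "treemethods", "trim")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- setNames(as.list(vals), keys)
  as_flag <- function(x) toupper(x) %in% c("TRUE", "T", "1", "YES")
  out <- list(
    auto_center = if (is.null(cfg$autCen)) TRUE else as_flag(cfg$autCen),
    center = cfg$defCen %||% NULL,
    model = cfg$distmodel %||% "F84",
    tree_methods = if (is.null(cfg$treemethods)) c("nj", "upgma") else
      trimws(strsplit(cfg$treemethods, ",")[[1]]),
    trim = if (is.null(cfg$trim)) FALSE else as_flag(cfg$trim)
  )
  if (!is.null(out$center) && grepl("^[0-9]+$", out$center)) {
    out$center <- as.integer(out$center)
  }
  out
}
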