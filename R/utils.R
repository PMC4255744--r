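`%||%` <- function(x, y) if (is.null(x)) y else x

# Classed conditions so callers can distinguish format, validation, state and
# usage failures programmatically.
ps_abort <- function(message, class = "protsem_usage_error") {
  stop(structure(
    class = c(class, "protsem_error", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

assert_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    ps_abort(sprintf("`%s` must be a single non-missing string", what))
  }
  invisible(x)
}

# All character offsets in this package are 0-based half-open [start, end),
# matching the JSON output contract. R's substr() is 1-based inclusive.
ps_substr <- function(x, start, end) substr(x, start + 1L, end)

regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

ps_extdata <- function(file) {
  path <- system.file("extdata", file, package = "protsem")
  if (!nzchar(path)) ps_abort(sprintf("bundled file '%s' not found", file))
  path
}
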